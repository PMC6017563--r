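#' Readers, writers, configuration and the full pipeline
#'
#' Long-format delimited concentration tables are the interchange format:
#' columns `subject_id`, `group`, `species`, `route`, `formulation`,
#' `analyte`, `time_h`, `conc_ng_ml`, `bql_flag`. The pipeline reproduces
#' the modelling workflow: baseline turnover fit on the vehicle arm, then
#' solution PK, then the depot fit with solution disposition fixed, then
#' the drug-effect PD fit with baseline parameters fixed, plus NCA/AUEC
#' summaries and residual diagnostics.
#'
#' @name io_cli
NULL

.conc_cols <- c("subject_id", "group", "species", "route", "formulation",
                "analyte", "time_h", "conc_ng_ml", "bql_flag")

#' Read a long-format concentration table
#'
#' Validates the header, types, non-negative times and uniqueness of
#' `(subject, analyte, time)`, and returns rows sorted by subject, analyte
#' and time.
#'
#' @param path Delimited text file (comma separated) with the columns
#'   listed above (extra columns are kept). Lines starting with `#` are
#'   treated as comments.
#' @return A validated, sorted data.frame.
#' @export
read_conc_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(.conc_cols, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(df$time_h))
  cc <- suppressWarnings(as.numeric(df$conc_ng_ml))
  if (anyNA(tm)) {
    stop("non-numeric time_h at row ", which(is.na(tm))[1L], call. = FALSE)
  }
  if (anyNA(cc)) {
    stop("non-numeric conc_ng_ml at row ", which(is.na(cc))[1L],
         call. = FALSE)
  }
  if (any(tm < 0)) {
    stop("negative time_h at row ", which(tm < 0)[1L], call. = FALSE)
  }
  df$time_h <- tm; df$conc_ng_ml <- cc
  df$bql_flag <- as.logical(df$bql_flag)
  key <- paste(df$subject_id, df$analyte, df$time_h)
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1L, ]
    stop(sprintf("duplicated time point: subject %s, %s at t = %g h",
                 d$subject_id, d$analyte, d$time_h), call. = FALSE)
  }
  df[order(df$subject_id, df$analyte, df$time_h), , drop = FALSE]
}

#' Write a long-format concentration table
#'
#' @param df Data.frame with the standard columns.
#' @param path Output file.
#' @param seed Optional seed recorded in the header comment.
#' @param config_hash Optional configuration hash recorded in the header.
#' @return `path`, invisibly.
#' @export
write_conc_table <- function(df, path, seed = NULL, config_hash = NULL) {
  missing <- setdiff(.conc_cols, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# depotpkpd conc table%s%s",
                 if (!is.null(seed)) paste0("; seed=", seed) else "",
                 if (!is.null(config_hash)) paste0("; config=", config_hash)
                 else "")
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Export a NONMEM-flavoured dataset (ID/TIME/DV/AMT/CMT/MDV/EVID)
#'
#' Convenience writer: one dosing record per subject (AMT at time 0) and
#' one observation record per concentration row.
#'
#' @param df Long-format concentration table (single analyte).
#' @param dose_amount Dose amount (ng) for the dosing records.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nonmem_table <- function(df, dose_amount, path) {
  ids <- unique(df$subject_id)
  recs <- lapply(ids, function(id) {
    sub <- df[df$subject_id == id, ]
    rbind(data.frame(ID = id, TIME = 0, DV = NA_real_, AMT = dose_amount,
                     CMT = 1L, MDV = 1L, EVID = 1L),
          data.frame(ID = id, TIME = sub$time_h, DV = sub$conc_ng_ml,
                     AMT = 0, CMT = 2L, MDV = 0L, EVID = 0L))
  })
  out <- do.call(rbind, recs)
  utils::write.csv(out, path, row.names = FALSE, na = ".")
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated bag of the knobs shared across modules. Unknown keys are
#' rejected.
#'
#' @param ... Overrides of the defaults: `step` (solver step, h),
#'   `clamp_tol`, `weighting`, `starts`, `seed`, `terminal_points`,
#'   `auec_baseline` (`"per_subject"` or `"group_mean"`), `feedback_form`,
#'   `body_weight` (kg), `lloq` (fitting floor, ng/mL).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(step = 0.01, clamp_tol = 1e-9, weighting = "prop2",
              starts = 5L, seed = 1L, terminal_points = 3L,
              auec_baseline = "per_subject", feedback_form = "reciprocal",
              body_weight = 0.3, lloq = 1e-3)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$step > 0, cfg$starts >= 1,
            cfg$auec_baseline %in% c("per_subject", "group_mean"),
            cfg$feedback_form %in% c("reciprocal", "product"))
  structure(cfg, class = "pipeline_config")
}

.group_mean_series <- function(df, grp, analyte_) {
  sub <- df[df$group == grp & df$analyte == analyte_ & !df$bql_flag, ]
  if (!nrow(sub)) return(NULL)
  agg <- stats::aggregate(conc_ng_ml ~ time_h, data = sub, FUN = mean)
  agg <- agg[order(agg$time_h), ]
  conc_series(agg$time_h, agg$conc_ng_ml, analyte_)
}

#' Run the full modelling pipeline on a study dataset
#'
#' Stage order mirrors the modelling workflow: (1) baseline turnover fit on
#' the Wistar vehicle arm; (2) solution PK fits (IV arm, then SC arm);
#' (3) depot PK fit with the SC solution disposition fixed; (4) drug-effect
#' PD fit with the baseline parameters fixed; (5) NCA and AUEC summaries
#' per drug arm; (6) residual diagnostics per fit. Fitting uses group-mean
#' profiles. A stage failure aborts with the stage name; completed results
#' are returned in the error's `partial` attribute.
#'
#' @param data Long-format study data.frame (e.g. from [generate_study()]
#'   or [read_conc_table()]).
#' @param config A [pipeline_config()].
#' @param pd_groups Which drug groups get the PD fit (default 3: the SC
#'   solution arm; PD fits dominate runtime).
#' @param out_dir Optional directory: results are written as delimited
#'   tables plus a small run manifest.
#' @return List with elements `baseline`, `solution_iv`, `solution_sc`,
#'   `depot`, `pd`, `nca`, `auec`, `diagnostics`, `config`.
#' @export
run_full_pipeline <- function(data, config = pipeline_config(),
                              pd_groups = 3L, out_dir = NULL) {
  stopifnot(is.data.frame(data), inherits(config, "pipeline_config"))
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                 conditionMessage(e)))
      attr(err, "partial") <- res
      stop(err)
    })
  }

  # stage 1: baseline turnover on the vehicle arm
  res$baseline <- stage("baseline", {
    s <- .group_mean_series(data, 2L, "testosterone")
    if (is.null(s)) stop("no vehicle-group (group 2) testosterone data")
    fit_baseline_pd(s, starts = config$starts, seed = config$seed,
                    weighting = config$weighting)
  })

  dose_iv <- dose_spec(0.1, config$body_weight, "IV")
  dose_sc <- dose_spec(0.1, config$body_weight, "SC-solution")
  dose_dp <- dose_spec(0.1, config$body_weight, "SC-depot")

  # stage 2: solution PK
  res$solution_iv <- stage("solution_pk_iv", {
    s <- .group_mean_series(data, 1L, "leuprolide")
    if (is.null(s)) stop("no IV solution (group 1) leuprolide data")
    fit_solution_pk(s, "IV", dose_iv, weighting = config$weighting,
                    starts = config$starts, seed = config$seed,
                    lloq = config$lloq)
  })
  res$solution_sc <- stage("solution_pk_sc", {
    s <- .group_mean_series(data, 3L, "leuprolide")
    if (is.null(s)) stop("no SC solution (group 3) leuprolide data")
    fit_solution_pk(s, "SC-solution", dose_sc,
                    weighting = config$weighting, starts = config$starts,
                    seed = config$seed, lloq = config$lloq)
  })

  # stage 3: depot PK with solution disposition fixed
  sol <- solution_pk_params(res$solution_sc$params$k_a,
                            res$solution_sc$params$CL,
                            res$solution_sc$params$V_d)
  res$depot <- stage("depot_pk", {
    s <- .group_mean_series(data, 4L, "leuprolide")
    if (is.null(s)) stop("no depot (group 4) leuprolide data")
    fit_depot_pk(s, dose_dp, sol, weighting = config$weighting,
                 starts = config$starts, seed = config$seed,
                 lloq = config$lloq)
  })

  # stage 4: drug-effect PD with baseline parameters fixed
  res$pd <- stage("pd_fit", {
    out <- list()
    for (grp in pd_groups) {
      s <- .group_mean_series(data, grp, "testosterone")
      if (is.null(s)) stop("no testosterone data for group ", grp)
      drug <- if (grp == 1L) list(pk = solution_pk_params(
        NA, res$solution_iv$params$CL, res$solution_iv$params$V_d),
        dose = dose_iv)
      else if (grp == 3L) list(pk = sol, dose = dose_sc)
      else list(pk = sol, dose = dose_dp, depot = do.call(depot_params,
        res$depot$params[c("N_R", "D_R", "E_R", "k_d", "k_t", "t_lag_d",
                           "t_lag_e")]))
      out[[paste0("g", grp)]] <- fit_pd(
        s, drug, res$baseline$params, weighting = config$weighting,
        starts = config$starts, seed = config$seed,
        feedback_form = config$feedback_form)
    }
    out
  })

  # stage 5: NCA + AUEC per drug arm
  res$nca <- stage("nca", {
    iv <- .group_mean_series(data, 1L, "leuprolide")
    ref <- nca_summary(iv, dose_iv,
                       terminal_points = config$terminal_points)
    out <- list(g1 = ref)
    for (grp in c(3L, 4L, 6L)) {
      s <- .group_mean_series(data, grp, "leuprolide")
      if (is.null(s)) next
      d <- if (grp == 3L) dose_sc else dose_dp
      out[[paste0("g", grp)]] <- nca_summary(
        s, d, reference_auc = ref$AUC_0_inf,
        terminal_points = config$terminal_points)
    }
    out
  })
  res$auec <- stage("auec", {
    out <- list()
    for (grp in c(1L, 3L, 4L, 6L)) {
      sub <- data[data$group == grp & data$analyte == "testosterone", ]
      if (!nrow(sub)) next
      group_base <- if (grp == 6L) 4.094 else 4.353
      per_subj <- lapply(split(sub, sub$subject_id), function(d) {
        d <- d[order(d$time_h), ]
        base <- if (config$auec_baseline == "per_subject" &&
                    d$time_h[1L] == 0) d$conc_ng_ml[1L] else group_base
        auec_decompose(conc_series(d$time_h, d$conc_ng_ml, "testosterone"),
                       base)
      })
      out[[paste0("g", grp)]] <- per_subj
    }
    out
  })

  # stage 6: diagnostics
  res$diagnostics <- stage("diagnostics", {
    fits <- c(list(solution_iv = res$solution_iv,
                   solution_sc = res$solution_sc, depot = res$depot),
              res$pd)
    lapply(fits, fit_diagnostics)
  })

  if (!is.null(out_dir)) .write_pipeline(res, out_dir, data)
  res
}

.write_pipeline <- function(res, out_dir, data) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- res$config
  cfg_str <- paste(names(cfg), vapply(cfg, paste, "", collapse = ","),
                   sep = "=", collapse = ";")
  ints <- utf8ToInt(cfg_str)
  hash <- sprintf("%08x", sum(ints * seq_along(ints)) %% 2147483647)
  manifest <- c(sprintf("seed: %s", cfg$seed),
                sprintf("config_hash: %s", hash),
                sprintf("generated: %s rows", nrow(data)),
                sprintf("package: depotpkpd %s",
                        as.character(utils::packageVersion("depotpkpd"))))
  writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  for (nm in c("solution_iv", "solution_sc", "depot")) {
    f <- res[[nm]]
    tab <- data.frame(parameter = names(f$params),
                      estimate = unlist(f$params),
                      se = unlist(f$se)[names(f$params)])
    utils::write.csv(tab, file.path(out_dir, paste0("fit_", nm, ".csv")),
                     row.names = FALSE)
  }
  for (nm in names(res$pd)) {
    f <- res$pd[[nm]]
    tab <- data.frame(parameter = names(f$params),
                      estimate = unlist(f$params),
                      se = unlist(f$se)[names(f$params)])
    utils::write.csv(tab, file.path(out_dir, paste0("fit_pd_", nm, ".csv")),
                     row.names = FALSE)
  }
  nca_tab <- do.call(rbind, lapply(names(res$nca), function(g) {
    x <- res$nca[[g]]
    data.frame(group = g, metric = names(unclass(x)),
               value = unlist(unclass(x)))
  }))
  utils::write.csv(nca_tab, file.path(out_dir, "nca_summary.csv"),
                   row.names = FALSE)
  auec_tab <- do.call(rbind, lapply(names(res$auec), function(g) {
    do.call(rbind, lapply(names(res$auec[[g]]), function(sid) {
      x <- res$auec[[g]][[sid]]
      data.frame(group = g, subject_id = sid, baseline = x$baseline,
                 total_AUEC = x$total_AUEC,
                 positive_AUEC = x$positive_AUEC,
                 negative_AUEC = x$negative_AUEC)
    }))
  }))
  utils::write.csv(auec_tab, file.path(out_dir, "auec_summary.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
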