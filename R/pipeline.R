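#' Run configuration
#'
#' A plain-list configuration object for the pipeline commands, serializable
#' to YAML. Every artifact written by the commands embeds the seed and a hash
#' of the configuration, so identical configurations reproduce identical
#' outputs.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param cohort_csv path to a cohort CSV (input of [cmd_analyze()], output
#'   of [cmd_simulate()]).
#' @param dxx,dyy,dzz optional NIfTI paths for [cmd_alps()] (single subject),
#'   or `subjects_csv`, a table with columns `id`, `dxx`, `dyy`, `dzz`.
#' @param roi_yaml optional ROI configuration file (default ROI set if
#'   `NULL`).
#' @param model covariate model for marker associations (1 or 2).
#' @param n_boot mediation bootstrap replicates.
#' @param n number of amyloid-positive participants to simulate.
#' @param n_reference number of CN- reference participants to simulate.
#' @param phantom logical: should [cmd_simulate()] also write a phantom?
#' @param alps_truth ground-truth index of the simulated phantom.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = ".", seed = 1L, cohort_csv = NULL,
                       dxx = NULL, dyy = NULL, dzz = NULL,
                       subjects_csv = NULL, roi_yaml = NULL,
                       model = 2, n_boot = 5000L, n = 93L,
                       n_reference = 40L, phantom = FALSE,
                       alps_truth = 1.355) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort_csv = cohort_csv, dxx = dxx, dyy = dyy, dzz = dzz,
                 subjects_csv = subjects_csv, roi_yaml = roi_yaml,
                 model = as.integer(model), n_boot = as.integer(n_boot),
                 n = as.integer(n), n_reference = as.integer(n_reference),
                 phantom = phantom, alps_truth = alps_truth),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[!vapply(y, is.null, logical(1))])
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

write_manifest <- function(config, dir, files, stage) {
  manifest <- list(stage = stage, seed = config$seed,
                   config_hash = config_hash(config),
                   files = basename(files),
                   created = "run-time")
  path <- file.path(dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Read / write a cohort table
#'
#' @param cohort cohort data frame.
#' @param path CSV path.
#' @return `read_cohort_csv()` returns the cohort data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param required columns that must be present (error lists missing ones).
#' @export
read_cohort_csv <- function(path, required = c("id", "age", "sex", "suvr",
                                               "wmh_burden", "alps")) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols))
    stop("cohort schema error; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  cohort
}

#' Simulate pipeline inputs (cohort CSV, optionally a phantom)
#'
#' @param config a [run_config()].
#' @return Invisibly, a list of the files written (plus a JSON manifest
#'   embedding the seed and configuration hash).
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  params <- default_sem_params(n = config$n, n_reference = config$n_reference,
                               n_boot = config$n_boot, seed = config$seed)
  cohort <- generate_cohort(params)
  files <- file.path(dir, "cohort.csv")
  write_cohort_csv(cohort, files)
  write_sem_params(params, file.path(dir, "sem_params.yaml"))
  files <- c(files, file.path(dir, "sem_params.yaml"))
  if (isTRUE(config$phantom)) {
    ph <- generate_tensor_phantom(
      phantom_spec(alps_truth = config$alps_truth, seed = config$seed))
    files <- c(files, write_phantom(ph, dir))
  }
  files <- c(files, write_manifest(config, dir, files, "simulate"))
  invisible(files)
}

#' Compute ALPS indices for one or more subjects
#'
#' @param config a [run_config()] with either `dxx`/`dyy`/`dzz` (one subject)
#'   or `subjects_csv` (columns `id`, `dxx`, `dyy`, `dzz`).
#' @return Invisibly, the paths written: a per-subject CSV (5 shifts x
#'   left/right/average per subject) and a JSON audit of ROI means.
#' @export
cmd_alps <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rois <- if (is.null(config$roi_yaml)) default_roi_set() else
    read_roi_yaml(config$roi_yaml)
  subjects <- if (!is.null(config$subjects_csv)) {
    read.csv(config$subjects_csv, stringsAsFactors = FALSE)
  } else {
    if (is.null(config$dxx) || is.null(config$dyy) || is.null(config$dzz))
      stop("config needs dxx/dyy/dzz paths or a subjects_csv")
    data.frame(id = "subject", dxx = config$dxx, dyy = config$dyy,
               dzz = config$dzz, stringsAsFactors = FALSE)
  }
  audit <- list()
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    vol <- read_tensor_volume(subjects$dxx[i], subjects$dyy[i],
                              subjects$dzz[i])
    res <- alps_battery(vol, rois = rois)
    audit[[subjects$id[i]]] <<- attr(res, "roi_means")
    wide <- data.frame(id = subjects$id[i])
    for (k in seq_len(nrow(res))) {
      sh <- res$y_shift[k]
      tag <- paste0("shift_",
                    if (sh < 0) paste0("m", -sh) else
                      if (sh > 0) paste0("p", sh) else "0")
      wide[[paste0(tag, "_left")]] <- res$left[k]
      wide[[paste0(tag, "_right")]] <- res$right[k]
      wide[[paste0(tag, "_mean")]] <- res$average[k]
    }
    wide$alps <- alps_index(res)  # middle-ROI average, the analysis value
    wide
  })
  tab <- do.call(rbind, rows)
  csv <- file.path(dir, "alps_indices.csv")
  write.csv(tab, csv, row.names = FALSE)
  aud <- file.path(dir, "alps_roi_audit.json")
  jsonlite::write_json(list(seed = config$seed,
                            config_hash = config_hash(config),
                            roi_means = audit),
                       aud, auto_unbox = TRUE, digits = NA)
  files <- c(csv, aud, write_manifest(config, dir, c(csv, aud), "alps"))
  invisible(files)
}

#' Run the full statistical analysis on a cohort table
#'
#' Derives groups and QC exclusions, writes a filter report and group counts,
#' a demographics comparison table, W-score continuum summaries, the
#' marker-association table (partial correlations for ALPS/choroid, ordinal
#' fits for PVS grades), the marker-cognition correlation table with FDR
#' adjustment, and the mediation battery.
#'
#' @param config a [run_config()] whose `cohort_csv` points at a cohort
#'   table.
#' @return Invisibly, the report file paths.
#' @export
cmd_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- read_cohort_csv(config$cohort_csv, required = c(
    "id", "age", "sex", "education", "apoe4_carrier", "tiv", "suvr",
    "wmh_burden", "choroid_norm", "bg_pvs_grade", "wm_pvs_grade", "alps",
    "memory", "executive", "visuospatial", "language", "diagnosis",
    "fazekas", "gds", "acpc_angle_deg", "pet_dti_interval_months"))

  # QC exclusions, then group assignment
  qc <- apply_exclusions(cohort)
  filter_report <- qc[!qc$keep, ]
  cohort <- cohort[qc$keep, , drop = FALSE]
  grp <- assign_group(cohort$diagnosis, amyloid_positive(cohort$suvr),
                      cohort$fazekas)
  reasons <- attr(grp, "reason")
  excl <- grp == "excluded"
  if (any(excl))
    filter_report <- rbind(filter_report,
                           data.frame(id = cohort$id[excl], keep = FALSE,
                                      reasons = reasons[excl]))
  cohort$group <- as.character(grp)
  cohort <- cohort[!excl, , drop = FALSE]
  files <- character(0)

  f <- file.path(dir, "filter_report.tsv")
  write.table(filter_report, f, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "group_counts.json")
  jsonlite::write_json(c(as.list(table(cohort$group)),
                         list(seed = config$seed,
                              config_hash = config_hash(config))),
                       f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)

  f <- file.path(dir, "demographics.tsv")
  write.table(group_compare(cohort), f, sep = "\t", row.names = FALSE,
              quote = FALSE)
  files <- c(files, f)

  pos <- cohort[cohort$group != "CN-", , drop = FALSE]
  ref <- cohort[cohort$group == "CN-", , drop = FALSE]

  # W-scores against the CN- reference (ALPS sign-flipped) and the continuum
  # curve summary
  if (nrow(ref) >= 8 && all(table(cohort$group) >= 4)) {
    wtab <- data.frame(id = cohort$id, group = cohort$group)
    for (mk in c("suvr", "alps", "choroid_norm")) {
      wm <- fit_wscore_model(ref, mk, sign_flip = mk == "alps")
      wtab[[paste0("w_", mk)]] <- w_score(wm, cohort)
    }
    f <- file.path(dir, "wscores.tsv")
    write.table(wtab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    curves <- lapply(c("w_suvr", "w_alps", "w_choroid_norm"), function(cn)
      continuum_curve(wtab[[cn]], wtab$group, seed = config$seed))
    f <- file.path(dir, "continuum_fitted.tsv")
    fitted <- data.frame(stage = c("CN-", "CN+", "MCI+", "AD+"),
                         w_suvr = curves[[1]]$fitted_at_stage,
                         w_alps = curves[[2]]$fitted_at_stage,
                         w_choroid_norm = curves[[3]]$fitted_at_stage)
    write.table(fitted, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }

  # marker associations on amyloid-positive participants
  covs1 <- c("age", "sex", "tiv")
  covs2 <- c(covs1, "apoe4_carrier")
  covs <- if (config$model == 2) covs2 else covs1
  assoc <- do.call(rbind, lapply(c("alps", "choroid_norm"), function(mk) {
    do.call(rbind, lapply(c("suvr", "wmh_burden"), function(ex) {
      pc <- partial_corr(pos, ex, mk, covariates = covs)
      data.frame(marker = mk, exposure = ex, model = config$model,
                 estimate = pc$r, p = pc$p, n = pc$n,
                 method = "partial_pearson", stringsAsFactors = FALSE)
    }))
  }))
  pvs <- do.call(rbind, lapply(c("bg_pvs_grade", "wm_pvs_grade"),
                               function(oc) {
    of <- ordinal_fit(pos, oc, model = config$model)
    ct <- of$coefficients[of$coefficients$term %in% c("suvr", "wmh_burden"), ]
    data.frame(marker = oc, exposure = ct$term, model = config$model,
               estimate = ct$beta, p = ct$p, n = of$n,
               method = "cumulative_logit", stringsAsFactors = FALSE)
  }))
  assoc <- rbind(assoc, pvs)
  assoc$fdr_p <- fdr_adjust(assoc$p)
  f <- file.path(dir, "marker_associations.tsv")
  write.table(assoc, f, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  # marker-cognition correlations (Pearson for ALPS/choroid, Spearman for
  # the ordinal PVS grades), FDR within the battery
  cog_covs <- c("age", "sex", "education", "apoe4_carrier")
  cog <- do.call(rbind, lapply(
    c("alps", "choroid_norm", "bg_pvs_grade", "wm_pvs_grade"),
    function(mk) {
      method <- if (grepl("pvs", mk)) "spearman" else "pearson"
      do.call(rbind, lapply(c("memory", "executive", "visuospatial",
                              "language"), function(dom) {
        pc <- partial_corr(pos, mk, dom, covariates = cog_covs,
                           method = method)
        data.frame(marker = mk, domain = dom, r = pc$r, p = pc$p, n = pc$n,
                   method = method, stringsAsFactors = FALSE)
      }))
    }))
  cog$fdr_p <- NA_real_
  for (mk in unique(cog$marker))
    cog$fdr_p[cog$marker == mk] <- fdr_adjust(cog$p[cog$marker == mk])
  f <- file.path(dir, "cognition_correlations.tsv")
  write.table(cog, f, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  med <- mediation_battery(pos, n_boot = config$n_boot, seed = config$seed)
  f <- file.path(dir, "mediation.tsv")
  write.table(med, f, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  jsonlite::write_json(
    list(seed = config$seed, config_hash = config_hash(config),
         n_boot = config$n_boot,
         cells = nrow(med), mediators = unique(med$mediator)),
    file.path(dir, "mediation_manifest.json"), auto_unbox = TRUE,
    digits = NA)
  files <- c(files, file.path(dir, "mediation_manifest.json"))

  files <- c(files, write_manifest(config, dir, files, "analyze"))
  invisible(files)
}
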