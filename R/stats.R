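#' Covariate-adjusted partial correlation
#'
#' Product-moment (`"pearson"`) partial correlation is the correlation of the
#' OLS residuals of `x` and `y` on the covariates, with the p-value from the
#' t distribution on `n - k - 2` degrees of freedom (k covariates). The
#' rank-based (`"spearman"`) variant rank-transforms `x` and `y` first and
#' then applies the same residual procedure, leaving the covariates on their
#' numeric scale — the convention used when relating ordinal visual grades to
#' continuous covariate-adjusted outcomes.
#'
#' @param data data frame.
#' @param x,y column names of the two variables.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param method `"pearson"` or `"spearman"`.
#' @return An object of class `partial_corr`: list with `r`, `p`, `n`, `df`,
#'   `method`, `x`, `y`, `covariates`.
#' @export
partial_corr <- function(data, x, y, covariates = character(0),
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cols <- c(x, y, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  k <- length(covariates)
  if (n <= k + 2)
    stop("need n > ", k + 2, " complete cases; got ", n)
  xv <- d[[x]]; yv <- d[[y]]
  if (method == "spearman") {
    xv <- rank(xv); yv <- rank(yv)
  }
  X <- cbind(rep(1, n))
  if (k) X <- cbind(X, as.matrix(d[covariates]))
  rx <- lm.fit(X, xv)$residuals
  ry <- lm.fit(X, yv)$residuals
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12)
    stop("zero-variance residuals; partial correlation undefined")
  r <- cor(rx, ry)
  df <- n - k - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  structure(list(r = r, p = p, n = n, df = df, method = method,
                 x = x, y = y, covariates = covariates),
            class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("<partial_corr> %s ~ %s | %s (%s): r = %.3f, p = %.4g, n = %d\n",
              x$x, x$y,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(none)",
              x$method, x$r, x$p, x$n))
  invisible(x)
}

#' Proportional-odds cumulative-logit model for PVS grades
#'
#' Fits an ordinal (cumulative-logit, proportional odds) regression of a PVS
#' visual grade on the amyloid and WMH exposures plus covariates by maximum
#' likelihood. Model 1 adjusts for age, sex and TIV; model 2 additionally for
#' APOE e4 carrier status. Positive slopes mean higher exposure shifts mass
#' toward higher grades.
#'
#' @param data data frame.
#' @param outcome grade column name (values in 1..4, at least two distinct
#'   grades observed).
#' @param exposures exposure column names (default amyloid SUVR and WMH
#'   burden, entered jointly).
#' @param model 1 or 2 (covariate set), ignored when `covariates` is given.
#' @param covariates optional explicit covariate column names.
#' @return An object of class `ordinal_fit`: `coefficients` (data frame:
#'   term, beta, se, p for the exposures and covariates), `cutpoints`,
#'   `converged`, `n`.
#' @export
ordinal_fit <- function(data, outcome, exposures = c("suvr", "wmh_burden"),
                        model = 1, covariates = NULL) {
  if (is.null(covariates))
    covariates <- if (model == 2) c("age", "sex", "tiv", "apoe4_carrier")
      else c("age", "sex", "tiv")
  cols <- c(outcome, exposures, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  grades <- d[[outcome]]
  if (length(unique(grades)) < 2)
    stop("outcome '", outcome, "' has a single observed grade; ",
         "ordinal model undefined")
  d[[outcome]] <- factor(grades, ordered = TRUE)
  fml <- stats::reformulate(c(exposures, covariates), response = outcome)
  fit <- tryCatch(
    MASS::polr(fml, data = d, Hess = TRUE),
    error = function(e) stop("ordinal fit failed (possible complete ",
                             "separation): ", conditionMessage(e)))
  converged <- is.null(fit$convergence) || fit$convergence == 0
  ct <- coef(summary(fit))
  terms <- c(exposures, covariates)
  beta <- ct[terms, "Value"]
  se <- ct[terms, "Std. Error"]
  z <- beta / se
  structure(
    list(coefficients = data.frame(term = terms, beta = unname(beta),
                                   se = unname(se),
                                   p = unname(2 * pnorm(-abs(z))),
                                   stringsAsFactors = FALSE),
         cutpoints = fit$zeta, converged = converged, n = nrow(d),
         outcome = outcome),
    class = "ordinal_fit"
  )
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("<ordinal_fit> ", x$outcome, ", n = ", x$n,
      if (!x$converged) " [DID NOT CONVERGE]" else "", "\n", sep = "")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, input order preserved.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Group demographics comparison table
#'
#' One-way ANOVA p-values for continuous fields and chi-square p-values for
#' categorical fields across groups, with mean +/- SD or counts per group.
#'
#' @param cohort data frame with a `group` column.
#' @param continuous,categorical column names to compare; defaults cover the
#'   standard demographics/marker set (intersected with available columns).
#' @param group_col grouping column name.
#' @return A data frame: variable, type, one summary column per group,
#'   `statistic`, `p`.
#' @export
group_compare <- function(cohort,
                          continuous = c("age", "education", "tiv", "suvr",
                                         "wmh_burden", "choroid_norm",
                                         "alps"),
                          categorical = c("sex", "apoe4_carrier",
                                          "hypertension", "diabetes",
                                          "hyperlipidemia", "smoking",
                                          "heart_disease"),
                          group_col = "group") {
  if (!group_col %in% names(cohort)) stop("no '", group_col, "' column")
  g <- factor(cohort[[group_col]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) == 0)) stop("empty group level")
  continuous <- intersect(continuous, names(cohort))
  categorical <- intersect(categorical, names(cohort))

  rows <- list()
  for (v in continuous) {
    x <- cohort[[v]]
    fit <- aov(x ~ g)
    an <- summary(fit)[[1]]
    summ <- tapply(x, g, function(u)
      sprintf("%.2f ± %.2f", mean(u), sd(u)))
    rows[[v]] <- c(variable = v, type = "continuous", summ,
                   statistic = sprintf("F = %.2f", an[["F value"]][1]),
                   p = signif(an[["Pr(>F)"]][1], 3))
  }
  for (v in categorical) {
    x <- factor(cohort[[v]])
    tab <- table(x, g)
    ch <- suppressWarnings(chisq.test(tab))
    summ <- vapply(levels(g), function(lv) {
      n1 <- sum(cohort[[v]][g == lv] == levels(x)[nlevels(x)])
      sprintf("%d (%.1f%%)", n1, 100 * n1 / sum(g == lv))
    }, character(1))
    rows[[v]] <- c(variable = v, type = "categorical", summ,
                   statistic = sprintf("X2 = %.2f", unname(ch$statistic)),
                   p = signif(ch$p.value, 3))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$p <- as.numeric(out$p)
  rownames(out) <- NULL
  out
}

#' Smooth W-score trajectory across the AD continuum
#'
#' Fits a cubic smoothing spline of W-scores against the ordered stage axis
#' (CN- = 0, CN+ = 1, MCI+ = 2, AD+ = 3) with a seeded within-stage bootstrap
#' percentile band. The stage axis is an ordinal construct: curve shape
#' between stages is an interpolation device, not a time axis.
#'
#' @param w numeric W-scores.
#' @param stage factor/character of stages, levels `CN-`, `CN+`, `MCI+`,
#'   `AD+`; all four stages must be present with at least 4 points each.
#' @param df spline degrees of freedom (default 3).
#' @param n_boot bootstrap replicates for the band.
#' @param seed integer seed for the band.
#' @return An object of class `continuum_curve`: `grid` (data frame with
#'   `stage_axis`, `fit`, `lower`, `upper`), `stage_means`, `fitted_at_stage`,
#'   `method`, `seed`.
#' @export
continuum_curve <- function(w, stage, df = 3, n_boot = 200, seed = 1L) {
  levels4 <- c("CN-", "CN+", "MCI+", "AD+")
  stage <- factor(as.character(stage), levels = levels4)
  if (anyNA(stage)) stop("stage contains values outside ",
                         paste(levels4, collapse = ", "))
  counts <- table(stage)
  if (any(counts == 0))
    stop("all four stages must be present to fit the continuum curve")
  if (any(counts < 4)) stop("need at least 4 points per stage")
  xs <- as.integer(stage) - 1
  fit <- smooth.spline(xs, w, df = df)
  grid_x <- seq(0, 3, by = 0.05)
  pred <- predict(fit, grid_x)$y

  boot <- with_preserved_seed(seed, {
    idx_by_stage <- split(seq_along(w), stage)
    replicate(n_boot, {
      idx <- unlist(lapply(idx_by_stage, function(ii)
        ii[sample.int(length(ii), replace = TRUE)]))
      predict(smooth.spline(xs[idx], w[idx], df = df), grid_x)$y
    })
  })
  band <- apply(boot, 1, quantile, probs = c(0.025, 0.975))

  structure(
    list(grid = data.frame(stage_axis = grid_x, fit = pred,
                           lower = band[1, ], upper = band[2, ]),
         stage_means = tapply(w, stage, mean),
         fitted_at_stage = predict(fit, 0:3)$y,
         method = "cubic smoothing spline (ordinal stage axis)",
         df = df, seed = seed),
    class = "continuum_curve"
  )
}

#' @export
print.continuum_curve <- function(x, ...) {
  cat("<continuum_curve> ", x$method, "\n", sep = "")
  print(round(rbind(`stage mean` = x$stage_means,
                    fitted = x$fitted_at_stage), 3))
  invisible(x)
}

#' @export
plot.continuum_curve <- function(x, ...) {
  with(x$grid, {
    plot(stage_axis, fit, type = "n", ylim = range(c(lower, upper)),
         xaxt = "n", xlab = "AD continuum stage", ylab = "W-score", ...)
    graphics::polygon(c(stage_axis, rev(stage_axis)), c(lower, rev(upper)),
                      col = "grey85", border = NA)
    graphics::lines(stage_axis, fit, lwd = 2)
    graphics::axis(1, at = 0:3, labels = c("CN-", "CN+", "MCI+", "AD+"))
  })
  graphics::points(0:3, x$stage_means, pch = 19)
  invisible(x)
}
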