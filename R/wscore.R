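#' Fit a W-score normative model on a reference group
#'
#' Regresses a marker on covariates in the reference (CN-) records by least
#' squares and stores the coefficients and the residual SD (denominator
#' n - p - 1). With `sign_flip = TRUE` the marker is multiplied by -1 before
#' fitting, so that markers that decrease with pathology (like ALPS) yield
#' W-scores that increase with abnormality, on the same footing as markers
#' that increase.
#'
#' @param reference data frame of reference-group records.
#' @param marker marker column name.
#' @param covariates covariate column names (default age, sex, TIV).
#' @param sign_flip multiply the marker by -1 before fitting.
#' @return An object of class `wscore_model` with elements `marker`,
#'   `covariates`, `coefficients`, `residual_sd`, `sign_flip`, `n`,
#'   `degenerate` (TRUE when the residual SD is numerically 0).
#' @export
fit_wscore_model <- function(reference, marker,
                             covariates = c("age", "sex", "tiv"),
                             sign_flip = FALSE) {
  cols <- c(marker, covariates)
  missing_cols <- setdiff(cols, names(reference))
  if (length(missing_cols))
    stop("reference lacks column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(reference)
  p <- length(covariates)
  if (n < p + 3)
    stop("need at least ", p + 3, " reference records to fit ", p,
         " covariates")
  y <- reference[[marker]] * if (sign_flip) -1 else 1
  X <- cbind(`(Intercept)` = 1, as.matrix(reference[covariates]))
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient reference design (collinear covariates)")
  fit <- lm.fit(X, y)
  rsd <- sqrt(sum(fit$residuals^2) / (n - p - 1))
  structure(
    list(marker = marker, covariates = covariates,
         coefficients = setNames(fit$coefficients, colnames(X)),
         residual_sd = rsd, sign_flip = sign_flip, n = n,
         degenerate = rsd < 1e-12),
    class = "wscore_model"
  )
}

#' @export
print.wscore_model <- function(x, ...) {
  cat("<wscore_model> ", x$marker,
      if (x$sign_flip) " (sign-flipped)" else "",
      " ~ ", paste(x$covariates, collapse = " + "),
      "; reference n = ", x$n,
      ", residual SD = ", signif(x$residual_sd, 4),
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' W-score of new records under a normative model
#'
#' The W-score is the covariate-adjusted deviation from the reference
#' expectation in reference residual-SD units:
#' `(observed - predicted) / residual SD`, with the optional sign flip
#' applied to the observation first. By OLS construction the reference set
#' itself has mean W-score 0 and SD ~ 1.
#'
#' @param model a [fit_wscore_model()] result.
#' @param records data frame with the marker and covariate columns.
#' @return Numeric W-scores, one per row.
#' @export
w_score <- function(model, records) {
  stopifnot(inherits(model, "wscore_model"))
  if (model$degenerate)
    stop("degenerate W-score model (zero residual SD); W-scores undefined")
  cols <- c(model$marker, model$covariates)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  obs <- records[[model$marker]] * if (model$sign_flip) -1 else 1
  X <- cbind(1, as.matrix(records[model$covariates]))
  pred <- drop(X %*% model$coefficients)
  unname((obs - pred) / model$residual_sd)
}
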