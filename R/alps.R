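#' One-sided ALPS index from ROI-mean diffusivities
#'
#' The ALPS index of one hemisphere is the ratio of the diffusivities along
#' the perivascular (x) direction in the projection- and association-fiber
#' ROIs to the diffusivities perpendicular to the respective fibers:
#' `(Dxx_proj + Dxx_assoc) / (Dyy_proj + Dzz_assoc)`. Values near 1 indicate
#' no preferential diffusion along the perivascular axis; healthy adults
#' typically sit around 1.3-1.5.
#'
#' @param dxx_proj,dxx_assoc mean x-diffusivity in the projection and
#'   association ROIs.
#' @param dyy_proj mean y-diffusivity in the projection ROI.
#' @param dzz_assoc mean z-diffusivity in the association ROI.
#' @return The dimensionless index (vectorized over inputs).
#' @export
compute_alps_side <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc) {
  vals <- cbind(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("mean diffusivities must be finite")
  if (any(vals < 0))
    stop("mean diffusivities must be non-negative")
  denom <- dyy_proj + dzz_assoc
  if (any(denom <= 0))
    stop("degenerate ROI content: Dyy_proj + Dzz_assoc must be > 0")
  (dxx_proj + dxx_assoc) / denom
}

#' ALPS index battery over the five anterior-posterior ROI shifts
#'
#' Computes the left, right and average ALPS index for every ROI shift in
#' `shifts` (default the five-position battery: 2 and 1 voxels anterior, the
#' middle placement, 1 and 2 voxels posterior). The middle placement
#' (`y_shift = 0`) is the default index used for analysis; the battery exists
#' to probe the anterior-posterior stability of the measurement.
#'
#' @param vol a [tensor_volume()].
#' @param rois ROI configuration data frame (see [default_roi_set()]).
#' @param shifts integer vector of y shifts in template voxels.
#' @return An object of class `alps_result`: a data frame with columns
#'   `y_shift`, `left`, `right`, `average`, plus attributes `roi_means`
#'   (audit list of per-ROI mean diffusivities) and `qc` (per-ROI flags).
#' @examples
#' ph <- generate_tensor_phantom(phantom_spec(alps_truth = 1.3))
#' res <- alps_battery(ph$volume)
#' alps_index(res)  # middle-ROI average index
#' @export
alps_battery <- function(vol, rois = default_roi_set(), shifts = -2:2) {
  stopifnot(inherits(vol, "tensor_volume"))
  validate_roi_set(rois)
  shifts <- sort(unique(as.integer(shifts)))

  audit <- list()
  qc <- list()
  rows <- lapply(shifts, function(sh) {
    means <- lapply(c("left", "right"), function(side) {
      out <- list()
      for (ft in c("projection", "association")) {
        r <- rois[rois$side == side & rois$fiber_type == ft, ]
        spec <- roi_spec(side, ft, c(r$x, r$y, r$z), r$diameter, sh)
        mask <- tryCatch(roi_mask(spec, vol), error = function(e)
          stop(roi_label(spec), ": ", conditionMessage(e), call. = FALSE))
        mns <- c(dxx = mean(vol$dxx[mask]), dyy = mean(vol$dyy[mask]),
                 dzz = mean(vol$dzz[mask]))
        key <- sprintf("shift%+d_%s_%s", sh, side, ft)
        audit[[key]] <<- c(mns, n_voxels = sum(mask))
        qc[[key]] <<- data.frame(
          roi = key,
          anisotropy = roi_anisotropy(mns),
          low_anisotropy = roi_anisotropy(mns) < 0.05,
          negative_diffusivity = any(mns < 0),
          stringsAsFactors = FALSE)
        out[[ft]] <- mns
      }
      tryCatch(
        compute_alps_side(out$projection["dxx"], out$association["dxx"],
                          out$projection["dyy"], out$association["dzz"]),
        error = function(e)
          stop(sprintf("shift %+d, %s side: %s", sh, side,
                       conditionMessage(e)), call. = FALSE))
    })
    left <- unname(means[[1]]); right <- unname(means[[2]])
    data.frame(y_shift = sh, left = left, right = right,
               average = (left + right) / 2)
  })
  res <- do.call(rbind, rows)
  structure(res, roi_means = audit, qc = do.call(rbind, unname(qc)),
            class = c("alps_result", "data.frame"))
}

# FA-like anisotropy proxy from the three diagonal diffusivities; used only
# as a placement plausibility flag (a sphere sitting in CSF or gray matter
# shows near-zero diagonal anisotropy).
roi_anisotropy <- function(mns) {
  m <- mean(mns)
  denom <- sum(mns^2)
  if (denom <= 0) return(0)
  sqrt(1.5 * sum((mns - m)^2) / denom)
}

#' Extract a single index from an ALPS battery result
#'
#' @param result an `alps_result` from [alps_battery()].
#' @param shift which y shift to read (default 0, the middle ROIs).
#' @param what `"average"`, `"left"` or `"right"`.
#' @return The requested index value.
#' @export
alps_index <- function(result, shift = 0L, what = "average") {
  what <- match.arg(what, c("average", "left", "right"))
  row <- result[result$y_shift == shift, ]
  if (nrow(row) != 1L) stop("shift ", shift, " not present in result")
  row[[what]]
}

#' Chin-up exclusion flag
#'
#' Head positioning with the AC-PC line tilted more than 20 degrees above the
#' horizontal distorts the ALPS geometry; such scans are excluded.
#'
#' @param acpc_angle_deg AC-PC line angle over the horizontal, degrees.
#' @return Logical: `TRUE` when the angle is strictly greater than 20.
#' @export
chin_up_excluded <- function(acpc_angle_deg) {
  if (anyNA(acpc_angle_deg) || any(!is.finite(acpc_angle_deg)))
    stop("acpc_angle_deg must be finite")
  acpc_angle_deg > 20
}
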