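#' Spherical ROI specification for the ALPS index
#'
#' Defines one of the four spheres (left/right x projection/association
#' fiber area) used by the ALPS calculation. Centers are given in template mm
#' coordinates; the default diameter is 6 mm. `y_shift` moves the center
#' along the template y axis by whole voxels, implementing the
#' anterior/posterior ROI-shift battery (+2, +1, 0, -1, -2 voxels).
#'
#' @param side `"left"` or `"right"`.
#' @param fiber_type `"projection"` or `"association"`.
#' @param center numeric length-3, template mm coordinates.
#' @param diameter sphere diameter in mm (> 0).
#' @param y_shift integer in `-2:2`, anterior (+) / posterior (-) shift in
#'   template voxels.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(side, fiber_type, center, diameter = 6, y_shift = 0L) {
  side <- match.arg(side, c("left", "right"))
  fiber_type <- match.arg(fiber_type, c("projection", "association"))
  if (length(center) != 3L || !is.numeric(center) || anyNA(center))
    stop("center must be 3 finite mm coordinates")
  if (!is.numeric(diameter) || diameter <= 0)
    stop("diameter must be > 0")
  if (!y_shift %in% -2:2)
    stop("y_shift must be an integer in -2..2")
  structure(
    list(side = side, fiber_type = fiber_type, center = as.numeric(center),
         diameter = as.numeric(diameter), y_shift = as.integer(y_shift)),
    class = "roi_spec"
  )
}

#' Default ALPS ROI configuration
#'
#' Ships the package's default sphere centers: 6-mm spheres lateral to the
#' body of the lateral ventricle, in the projection-fiber (corona radiata)
#' and association-fiber (superior longitudinal fasciculus) areas of each
#' hemisphere. The centers are a documented configuration, not a fixed
#' anatomical truth: studies place them manually on the fiber-direction map,
#' so they are fully overridable (see [read_roi_yaml()]).
#'
#' @return A data frame with columns `side`, `fiber_type`, `x`, `y`, `z`
#'   (template mm) and `diameter` (mm), one row per sphere.
#' @export
default_roi_set <- function() {
  data.frame(
    side = c("left", "left", "right", "right"),
    fiber_type = rep(c("projection", "association"), 2),
    x = c(-26, -36, 26, 36),
    y = rep(-22, 4),
    z = rep(26, 4),
    diameter = rep(6, 4),
    stringsAsFactors = FALSE
  )
}

roi_set_to_specs <- function(rois, y_shift = 0L) {
  lapply(seq_len(nrow(rois)), function(i)
    roi_spec(rois$side[i], rois$fiber_type[i],
             c(rois$x[i], rois$y[i], rois$z[i]),
             diameter = rois$diameter[i], y_shift = y_shift))
}

#' Read / write an ROI configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_roi_yaml()` returns the ROI data frame (see
#'   [default_roi_set()]); `write_roi_yaml()` returns `path` invisibly.
#' @export
read_roi_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  rois <- do.call(rbind, lapply(y$rois, function(r)
    data.frame(side = r$side, fiber_type = r$fiber_type,
               x = r$center[[1]], y = r$center[[2]], z = r$center[[3]],
               diameter = if (is.null(r$diameter)) 6 else r$diameter,
               stringsAsFactors = FALSE)))
  validate_roi_set(rois)
  rois
}

#' @rdname read_roi_yaml
#' @param rois ROI data frame as returned by [default_roi_set()].
#' @export
write_roi_yaml <- function(rois, path) {
  validate_roi_set(rois)
  y <- list(rois = lapply(seq_len(nrow(rois)), function(i) list(
    side = rois$side[i], fiber_type = rois$fiber_type[i],
    center = c(rois$x[i], rois$y[i], rois$z[i]),
    diameter = rois$diameter[i])))
  yaml::write_yaml(y, path)
  invisible(path)
}

validate_roi_set <- function(rois) {
  needed <- c("side", "fiber_type", "x", "y", "z", "diameter")
  if (!all(needed %in% names(rois)))
    stop("ROI set must have columns ", paste(needed, collapse = ", "))
  combos <- paste(rois$side, rois$fiber_type)
  expect <- c("left projection", "left association",
              "right projection", "right association")
  if (!setequal(combos, expect) || nrow(rois) != 4)
    stop("ROI set must contain exactly the four side x fiber-type spheres")
  invisible(rois)
}

#' Voxel mask of a (possibly y-shifted) spherical ROI
#'
#' A voxel belongs to the mask when its center lies within `diameter/2` of
#' the sphere center; the y shift displaces the center by
#' `y_shift * voxel_size_y` mm along the template y axis before the test.
#'
#' @param spec an [roi_spec()].
#' @param vol a [tensor_volume()] (only its grid geometry is used).
#' @return A logical array with the volume's dimensions.
#' @export
roi_mask <- function(spec, vol) {
  stopifnot(inherits(spec, "roi_spec"), inherits(vol, "tensor_volume"))
  vs <- voxel_size(vol)
  center <- spec$center + c(0, spec$y_shift * vs[2], 0)
  r <- spec$diameter / 2
  dims <- vol$dim

  # bounding box in voxel indices to avoid scanning the full grid
  cv <- mm_to_voxel(vol$affine, center)
  lo <- pmax(1L, floor(cv - r / vs - 1))
  hi <- pmin(dims, ceiling(cv + r / vs + 1))
  if (any(lo > hi))
    stop(roi_label(spec), ": sphere does not intersect the volume grid")

  ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2])
  kk <- seq.int(lo[3], hi[3])
  grid <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  mm <- voxel_to_mm(vol$affine, grid)
  inside <- rowSums(sweep(mm, 2, center)^2) <= r^2 + 1e-9
  if (!any(inside))
    stop(roi_label(spec), ": empty ROI mask (no voxel center within ",
         r, " mm of its center)")

  mask <- array(FALSE, dim = dims)
  sel <- grid[inside, , drop = FALSE]
  mask[sel[, 1] + (sel[, 2] - 1) * dims[1] +
         (sel[, 3] - 1) * dims[1] * dims[2]] <- TRUE
  mask
}

roi_label <- function(spec) {
  sprintf("ROI %s/%s (shift %+d)", spec$side, spec$fiber_type, spec$y_shift)
}
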