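#' Specification of a tensor phantom with known ground-truth ALPS
#'
#' The phantom places two axis-aligned slabs per hemisphere on the template
#' grid: a projection-fiber slab (fibers along z) and an association-fiber
#' slab (fibers along y). Inside the slabs, the perpendicular diffusivities
#' are `d_perp` and the x diffusivity is `alps_truth * d_perp`, so the ALPS
#' ratio `(Dxx_proj + Dxx_assoc) / (Dyy_proj + Dzz_assoc)` evaluates exactly
#' to `alps_truth` in the noiseless case; the background is isotropic. Slabs
#' (not curved tracts) suffice because the index only reads mean
#' diffusivities inside spherical ROIs.
#'
#' @param alps_truth target noiseless index (> 0, dimensionless).
#' @param d_perp fiber-perpendicular diffusivity (10^-3 mm^2/s, > 0).
#' @param d_parallel fiber-parallel diffusivity (10^-3 mm^2/s).
#' @param background isotropic background diffusivity.
#' @param dims grid dimensions (default the 91 x 109 x 91 2-mm template).
#' @param affine 4x4 voxel-to-mm affine; `NULL` for the template default.
#' @param proj_x,assoc_x absolute-x mm ranges of the projection and
#'   association slabs (mirrored across the midline).
#' @param slab_y,slab_z mm ranges of both slabs along y and z.
#' @param noise_sd additive Gaussian SD on each diffusivity map (>= 0).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(alps_truth = 1.355, d_perp = 0.5, d_parallel = 1.2,
                         background = 0.8, dims = c(91L, 109L, 91L),
                         affine = NULL,
                         proj_x = c(20, 32), assoc_x = c(32, 44),
                         slab_y = c(-34, -10), slab_z = c(18, 34),
                         noise_sd = 0, seed = 1L) {
  if (!is.numeric(alps_truth) || alps_truth <= 0)
    stop("alps_truth must be > 0")
  if (d_perp <= 0) stop("d_perp must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(affine)) affine <- default_template_affine(dims)
  structure(
    list(alps_truth = alps_truth, d_perp = d_perp, d_parallel = d_parallel,
         background = background, dims = as.integer(dims),
         affine = as.matrix(affine),
         proj_x = sort(proj_x), assoc_x = sort(assoc_x),
         slab_y = sort(slab_y), slab_z = sort(slab_z),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a tensor phantom
#'
#' Builds the diffusivity volumes described by a [phantom_spec()] and returns
#' them together with the exact noiseless ground truth. With `noise_sd = 0`
#' the index computed by [alps_battery()] equals `alps_truth` to machine
#' precision for every ROI shift, because the slabs are homogeneous.
#'
#' @param spec a [phantom_spec()].
#' @param rois ROI configuration the phantom must accommodate; every sphere
#'   (including the full +/-2-voxel shift range) must fit inside its slab,
#'   otherwise an error names the offending ROI.
#' @return A list with elements `volume` (a [tensor_volume()]) and `truth`
#'   (list: `alps_truth`, `left`, `right`, `d_perp`, `noise_sd`, `seed`).
#' @export
generate_tensor_phantom <- function(spec, rois = default_roi_set()) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_roi_set(rois)
  vs <- sqrt(colSums(spec$affine[1:3, 1:3]^2))

  # every ROI sphere, over the whole shift battery, must fit in its slab
  for (i in seq_len(nrow(rois))) {
    r <- rois$diameter[i] / 2
    xr <- if (rois$fiber_type[i] == "projection") spec$proj_x else spec$assoc_x
    ax <- abs(rois$x[i])
    yr <- rois$y[i] + c(-1, 1) * (r + 2 * vs[2])  # +/-2 voxel shifts
    zr <- rois$z[i] + c(-1, 1) * r
    if (ax - r < xr[1] || ax + r > xr[2] ||
        yr[1] < spec$slab_y[1] || yr[2] > spec$slab_y[2] ||
        zr[1] < spec$slab_z[1] || zr[2] > spec$slab_z[2])
      stop("slab does not contain ROI ", rois$side[i], "/",
           rois$fiber_type[i], " over the full shift range")
  }

  dims <- spec$dims
  # mm coordinates of every voxel center, one axis at a time
  ax_x <- spec$affine[1, 1] * (seq_len(dims[1]) - 1) + spec$affine[1, 4]
  ax_y <- spec$affine[2, 2] * (seq_len(dims[2]) - 1) + spec$affine[2, 4]
  ax_z <- spec$affine[3, 3] * (seq_len(dims[3]) - 1) + spec$affine[3, 4]
  if (any(spec$affine[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] != 0))
    stop("phantom generation requires an axis-aligned affine")

  in_rng <- function(v, rng) v >= rng[1] & v <= rng[2]
  inx_p <- in_rng(abs(ax_x), spec$proj_x)
  inx_a <- in_rng(abs(ax_x), spec$assoc_x) & !inx_p
  iny <- in_rng(ax_y, spec$slab_y)
  inz <- in_rng(ax_z, spec$slab_z)
  proj <- array(outer(outer(inx_p, iny, "&"), inz, "&"), dim = dims)
  assoc <- array(outer(outer(inx_a, iny, "&"), inz, "&"), dim = dims)

  dxx <- array(spec$background, dim = dims)
  dyy <- array(spec$background, dim = dims)
  dzz <- array(spec$background, dim = dims)
  dx_fiber <- spec$alps_truth * spec$d_perp
  dxx[proj] <- dx_fiber;  dyy[proj] <- spec$d_perp;  dzz[proj] <- spec$d_parallel
  dxx[assoc] <- dx_fiber; dyy[assoc] <- spec$d_parallel; dzz[assoc] <- spec$d_perp

  if (spec$noise_sd > 0) {
    with_preserved_seed(spec$seed, {
      n <- prod(dims)
      dxx <- dxx + array(rnorm(n, 0, spec$noise_sd), dim = dims)
      dyy <- dyy + array(rnorm(n, 0, spec$noise_sd), dim = dims)
      dzz <- dzz + array(rnorm(n, 0, spec$noise_sd), dim = dims)
    })
  }

  list(
    volume = tensor_volume(dxx, dyy, dzz, affine = spec$affine),
    truth = list(alps_truth = spec$alps_truth, left = spec$alps_truth,
                 right = spec$alps_truth, d_perp = spec$d_perp,
                 noise_sd = spec$noise_sd, seed = spec$seed)
  )
}

#' Write a phantom to disk (NIfTI maps + JSON ground-truth sidecar)
#'
#' @param phantom result of [generate_tensor_phantom()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written (three NIfTI files and one JSON).
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  paths <- write_tensor_volume(phantom$volume, dir, prefix)
  sidecar <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(phantom$truth, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}

# evaluate expr with a fixed seed, then restore the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
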