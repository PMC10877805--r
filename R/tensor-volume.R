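#' Template-space diffusivity volumes
#'
#' A `tensor_volume` bundles the three diagonal diffusivity maps (Dxx, Dyy,
#' Dzz, in 10^-3 mm^2/s) already co-registered to a common template grid,
#' together with the voxel-to-mm affine. The x axis is left-right, y
#' anterior-posterior, z inferior-superior (RAS template orientation); at the
#' level of the lateral-ventricle body, projection fibers run along z,
#' association fibers along y, and perivascular flow along the deep medullary
#' veins runs along x — the geometry the ALPS index exploits.
#'
#' @param dxx,dyy,dzz 3-D numeric arrays of identical dimension.
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices, RAS mm).
#'   Defaults to the standard 2-mm MNI grid affine when the arrays have the
#'   91 x 109 x 91 template dimension, otherwise a centered 2-mm grid.
#' @return An object of class `tensor_volume`.
#' @seealso [read_tensor_volume()], [write_tensor_volume()], [alps_battery()]
#' @export
tensor_volume <- function(dxx, dyy, dzz, affine = NULL) {
  dims <- dim(dxx)
  if (length(dims) != 3L)
    stop("diffusivity maps must be 3-D arrays")
  if (!identical(dims, dim(dyy)) || !identical(dims, dim(dzz)))
    stop("Dxx, Dyy and Dzz must share dimensions")
  if (is.null(affine)) affine <- default_template_affine(dims)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  structure(
    list(dxx = dxx, dyy = dyy, dzz = dzz, affine = affine, dim = dims),
    class = "tensor_volume"
  )
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat("<tensor_volume> ", paste(x$dim, collapse = " x "),
      " voxels, voxel size ", paste(signif(voxel_size(x), 3), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

# Standard MNI152 2-mm affine for the 91x109x91 grid; otherwise a 2-mm grid
# centered on the origin so that small test grids still carry mm coordinates.
default_template_affine <- function(dims) {
  if (identical(as.integer(dims), c(91L, 109L, 91L))) {
    rbind(c(-2, 0, 0, 90),
          c(0, 2, 0, -126),
          c(0, 0, 2, -72),
          c(0, 0, 0, 1))
  } else {
    rbind(c(2, 0, 0, -dims[1]),
          c(0, 2, 0, -dims[2]),
          c(0, 0, 2, -dims[3]),
          c(0, 0, 0, 1))
  }
}

#' Voxel size of a tensor volume (mm)
#' @param vol a [tensor_volume()].
#' @return Numeric length-3 vector of voxel edge lengths in mm.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

# map 1-based voxel indices (n x 3) to template mm coordinates
voxel_to_mm <- function(affine, ijk1) {
  ijk0 <- cbind(as.matrix(ijk1) - 1, 1)
  t(affine %*% t(ijk0))[, 1:3, drop = FALSE]
}

# map mm coordinates to (fractional) 1-based voxel indices
mm_to_voxel <- function(affine, xyz) {
  inv <- solve(affine)
  xyz1 <- cbind(matrix(xyz, ncol = 3), 1)
  t(inv %*% t(xyz1))[, 1:3, drop = FALSE] + 1
}

#' Read a tensor volume from three NIfTI files
#'
#' @param dxx_file,dyy_file,dzz_file paths to the Dxx, Dyy and Dzz NIfTI
#'   images (same grid and affine).
#' @return A [tensor_volume()].
#' @export
read_tensor_volume <- function(dxx_file, dyy_file, dzz_file) {
  files <- c(dxx_file, dyy_file, dzz_file)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("diffusivity file(s) not found: ", paste(missing, collapse = ", "))
  imgs <- lapply(files, RNifti::readNifti)
  affs <- lapply(imgs, function(i) unclass(RNifti::xform(i)))
  if (max(abs(affs[[1]] - affs[[2]])) > 1e-4 ||
      max(abs(affs[[1]] - affs[[3]])) > 1e-4)
    stop("Dxx/Dyy/Dzz affines disagree; volumes must be co-registered")
  aff <- matrix(as.numeric(affs[[1]]), 4, 4)
  tensor_volume(array(as.numeric(imgs[[1]]), dim = dim(imgs[[1]])),
                array(as.numeric(imgs[[2]]), dim = dim(imgs[[2]])),
                array(as.numeric(imgs[[3]]), dim = dim(imgs[[3]])),
                affine = aff)
}

#' Write a tensor volume as three NIfTI files
#'
#' @param vol a [tensor_volume()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are `<prefix>_Dxx.nii` etc.
#' @return Invisibly, the three file paths written.
#' @export
write_tensor_volume <- function(vol, dir, prefix = "subject") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_D", c("xx", "yy", "zz"), ".nii"))
  maps <- list(vol$dxx, vol$dyy, vol$dzz)
  for (k in 1:3) {
    img <- RNifti::asNifti(maps[[k]])
    img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
    RNifti::writeNifti(img, paths[k])
  }
  invisible(paths)
}
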