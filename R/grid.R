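#' Define the common analysis grid
#'
#' A `brain_grid` is the voxel space every map in an analysis lives on: an
#' array shape, a 4x4 affine mapping 0-based voxel indices to MNI mm (RAS),
#' and a boolean analysis mask. The default is a 2 mm isotropic grid covering
#' the MNI bounding box with a coarse gray-matter ellipsoid mask; any NIfTI
#' mask can be supplied instead via [read_mask_nifti()].
#'
#' @param voxel_mm isotropic voxel size in mm (default 2).
#' @param bbox 3x2 matrix of mm bounds per axis (rows x, y, z). Defaults to
#'   the usual MNI bounding box, x -90..90, y -126..90, z -72..108.
#' @param mask either `"ellipsoid"` (default; see [gm_ellipsoid_mask()]),
#'   `"all"` (every voxel in-mask), or a logical array matching the grid
#'   shape.
#' @return An object of class `brain_grid` with elements `shape` (integer
#'   triple), `affine` (4x4), `voxel_mm`, `mask` (logical array), and cached
#'   in-mask voxel coordinates.
#' @examples
#' g <- brain_grid(voxel_mm = 4)
#' sum(g$mask)
#' @export
brain_grid <- function(voxel_mm = 2,
                       bbox = cbind(c(-90, -126, -72), c(90, 90, 108)),
                       mask = "ellipsoid") {
  stopifnot(is.numeric(voxel_mm), length(voxel_mm) == 1L, voxel_mm > 0)
  bbox <- matrix(as.numeric(bbox), nrow = 3L)
  if (any(bbox[, 2] <= bbox[, 1])) stop("bbox upper bounds must exceed lower bounds")
  shape <- as.integer(floor((bbox[, 2] - bbox[, 1]) / voxel_mm)) + 1L
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- bbox[, 1]
  g <- structure(
    list(shape = shape, affine = affine, voxel_mm = voxel_mm, mask = NULL),
    class = "brain_grid"
  )
  if (is.character(mask)) {
    mask <- match.arg(mask, c("ellipsoid", "all"))
    m <- if (mask == "all") array(TRUE, dim = shape) else gm_ellipsoid_mask(g)
  } else {
    m <- mask
    if (!is.logical(m) || !identical(dim(m), as.integer(shape)))
      stop("mask must be a logical array with the grid's shape")
  }
  if (!any(m)) stop("analysis mask is empty")
  g$mask <- m
  g$mask_idx <- which(m)                      # linear indices of in-mask voxels
  g$mask_mm <- voxel_to_mm(g, g$mask_idx)     # V x 3 mm coordinates
  g
}

#' @export
print.brain_grid <- function(x, ...) {
  cat(sprintf("brain_grid: %d x %d x %d voxels at %g mm, %d in mask\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_mm, length(x$mask_idx)))
  invisible(x)
}

#' Coarse gray-matter ellipsoid mask
#'
#' A deterministic stand-in analysis mask: the ellipsoid centred at
#' MNI (0, -18, 8) with semi-axes (70, 85, 75) mm, roughly the extent of
#' cerebral gray matter. It is synthetic — an explicit geometric proxy, not
#' derived from any template — and is meant to be replaced by a real
#' gray-matter mask when one is available.
#'
#' @param grid a [brain_grid()] (mask slot may be unset).
#' @param center,semiaxes ellipsoid centre and semi-axes in mm.
#' @return logical array over the grid shape.
#' @export
gm_ellipsoid_mask <- function(grid, center = c(0, -18, 8),
                              semiaxes = c(70, 85, 75)) {
  mm <- voxel_to_mm(grid, seq_len(prod(grid$shape)))
  d2 <- ((mm[, 1] - center[1]) / semiaxes[1])^2 +
        ((mm[, 2] - center[2]) / semiaxes[2])^2 +
        ((mm[, 3] - center[3]) / semiaxes[3])^2
  array(d2 <= 1, dim = grid$shape)
}

#' Convert linear voxel indices to MNI mm coordinates
#'
#' @param grid a [brain_grid()].
#' @param idx vector of 1-based linear indices into the grid array.
#' @return numeric matrix, one row per index, columns x/y/z in mm.
#' @export
voxel_to_mm <- function(grid, idx) {
  ijk <- arrayInd(idx, grid$shape) - 1L      # 0-based voxel indices
  sweep(ijk %*% t(grid$affine[1:3, 1:3]), 2, grid$affine[1:3, 4], "+")
}

#' Convert MNI mm coordinates to the nearest voxel linear index
#'
#' @param grid a [brain_grid()].
#' @param mm numeric vector of length 3 or matrix with 3 columns.
#' @param clamp clip out-of-grid coordinates to the grid edge (default TRUE).
#' @return vector of 1-based linear indices.
#' @export
mm_to_voxel <- function(grid, mm, clamp = TRUE) {
  if (is.null(dim(mm))) mm <- matrix(mm, ncol = 3L, byrow = TRUE)
  inv <- solve(grid$affine)
  ijk <- sweep(mm, 2, grid$affine[1:3, 4], "-") %*% t(inv[1:3, 1:3])
  ijk <- round(ijk)
  if (clamp) for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 0), grid$shape[a] - 1L)
  if (any(ijk < 0) || any(sweep(ijk, 2, grid$shape - 1L, ">")))
    stop("coordinate outside the grid")
  as.integer(1L + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3]))
}

#' Scalar field on a brain grid
#'
#' A `volume_map` stores one value per in-mask voxel together with its role
#' (effect size `d`, variance `v`, `Z`, `p`, or heterogeneity `Q`).
#'
#' @param grid a [brain_grid()].
#' @param values numeric vector, one value per in-mask voxel (in
#'   `grid$mask_idx` order).
#' @param role one of `"d"`, `"v"`, `"z"`, `"p"`, `"q"`.
#' @return object of class `volume_map`.
#' @export
volume_map <- function(grid, values, role = c("d", "v", "z", "p", "q")) {
  role <- match.arg(role)
  values <- as.numeric(values)
  if (length(values) != length(grid$mask_idx))
    stop("values must have one entry per in-mask voxel")
  if (any(!is.finite(values)))
    stop("volume_map values must be finite inside the mask")
  if (role == "v" && any(values <= 0)) stop("variance map must be strictly positive")
  if (role == "p" && (any(values <= 0) || any(values > 1))) stop("p map must lie in (0,1]")
  structure(list(grid = grid, values = values, role = role), class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf("volume_map [%s]: %d voxels, range %.4g .. %.4g\n",
              x$role, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Expand a volume_map to a full 3-D array
#'
#' Out-of-mask voxels are filled with `fill` (default 0).
#' @param map a [volume_map()].
#' @param fill value for voxels outside the mask.
#' @return numeric array with the grid's shape.
#' @export
map_as_array <- function(map, fill = 0) {
  a <- array(fill, dim = map$grid$shape)
  a[map$grid$mask_idx] <- map$values
  a
}

#' Write a volume_map as a NIfTI-1 volume
#'
#' The grid affine is stored in the sform/qform so the volume overlays MNI
#' templates correctly.
#' @param map a [volume_map()].
#' @param path output filename (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path) {
  arr <- map_as_array(map, fill = 0)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(map$grid$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI mask onto a matching brain grid
#'
#' @param path NIfTI file with nonzero voxels marking the analysis mask.
#' @param voxel_mm voxel size of the resulting grid; must match the file.
#' @return a [brain_grid()] whose affine and mask come from the file.
#' @export
read_mask_nifti <- function(path, voxel_mm = NULL) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), dim = c(4L, 4L))
  arr <- as.array(img) != 0
  vm <- abs(aff[1, 1])
  if (!is.null(voxel_mm) && abs(vm - voxel_mm) > 1e-6)
    stop("mask voxel size does not match the requested grid")
  g <- structure(list(shape = dim(arr), affine = aff, voxel_mm = vm, mask = arr),
                 class = "brain_grid")
  if (!any(arr)) stop("analysis mask is empty")
  g$mask_idx <- which(arr)
  g$mask_mm <- voxel_to_mm(g, g$mask_idx)
  g
}

# shared check: all maps on one grid
same_grid <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$affine, b$affine)) &&
    identical(a$mask_idx, b$mask_idx)
}
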