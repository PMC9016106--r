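#' 3D scalar volume with physical geometry
#'
#' `volume_image()` is the common currency of the pipeline: a 3D numeric array
#' together with its physical voxel spacing (mm per axis) and the world-space
#' position of the first voxel's center. The package uses one fixed
#' right-handed convention throughout: array axes (i, j, k) map to world axes
#' (x, y, z), voxel `[i, j, k]` (1-based) has its center at
#' `origin + (c(i, j, k) - 1) * spacing`, and all spacings are positive.
#'
#' @param values 3D numeric array; all values must be finite.
#' @param spacing numeric length 3, voxel size in mm per axis; all > 0.
#' @param origin numeric length 3, world coordinates (mm) of the center of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `volume_image` with fields `values`, `spacing`
#'   and `origin`.
#' @examples
#' img <- volume_image(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(img)
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ",
         if (is.array(values)) paste0(length(dim(values)), " dimensions") else class(values)[1])
  if (any(dim(values) < 1L)) stop("every axis must have at least one voxel")
  storage.mode(values) <- "double"
  n_bad <- sum(!is.finite(values))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite voxel(s)")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
dim.volume_image <- function(x) dim(x$values)

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Test for volume_image objects
#' @param x object to test.
#' @return `TRUE` if `x` is a `volume_image`.
#' @export
is_volume_image <- function(x) inherits(x, "volume_image")

#' SUV map: a volume in standardized-uptake-value units
#'
#' Wraps a [volume_image()] whose voxel values are standardized uptake values
#' (dimensionless under the g/mL convention), together with the normalization
#' provenance: the injected activity (MBq, already decay-corrected to scan
#' time) and the patient body weight (kg).
#'
#' @param image a [volume_image()] with all values >= 0.
#' @param injected_activity injected activity in MBq, decay-corrected; > 0.
#' @param body_weight body weight in kg; > 0.
#' @return An object of class `suv_map` with fields `image`,
#'   `injected_activity` and `body_weight`.
#' @seealso [compute_suv()] to build one from an activity-concentration volume.
#' @export
suv_map <- function(image, injected_activity, body_weight) {
  if (!is_volume_image(image)) stop("`image` must be a volume_image")
  if (any(image$values < 0))
    stop("SUV values must be >= 0; found ", sum(image$values < 0), " negative voxel(s)")
  if (!is.numeric(injected_activity) || length(injected_activity) != 1L || injected_activity <= 0)
    stop("`injected_activity` must be a single positive number (MBq)")
  if (!is.numeric(body_weight) || length(body_weight) != 1L || body_weight <= 0)
    stop("`body_weight` must be a single positive number (kg)")
  structure(list(image = image,
                 injected_activity = as.numeric(injected_activity),
                 body_weight = as.numeric(body_weight)),
            class = "suv_map")
}

#' @export
print.suv_map <- function(x, ...) {
  cat(sprintf("<suv_map> injected activity %.1f MBq, body weight %.1f kg\n",
              x$injected_activity, x$body_weight))
  print(x$image)
  invisible(x)
}

# Accept either an suv_map or a bare volume_image where only the grid matters.
as_suv_image <- function(suv) {
  if (inherits(suv, "suv_map")) suv$image
  else if (is_volume_image(suv)) suv
  else stop("expected an suv_map or volume_image")
}

#' Affine transform between world frames
#'
#' Maps world coordinates of a moving image into the world frame of a
#' reference image: `x_ref = linear %*% x_mov + translation`. The transform is
#' an input to [resample_to()]; estimating a registration is out of scope.
#'
#' @param linear 3x3 invertible matrix.
#' @param translation numeric length 3 (mm).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stop("`translation` must have length 3")
  if (abs(det(linear)) < 1e-12)
    stop("singular transform: linear part is not invertible")
  structure(list(linear = linear, translation = translation),
            class = "affine_transform")
}

#' Identity affine transform
#' @return An `affine_transform` that leaves coordinates unchanged.
#' @export
identity_affine <- function() affine_transform()

is_identity_affine <- function(tf, tol = 1e-10) {
  max(abs(tf$linear - diag(3))) < tol && max(abs(tf$translation)) < tol
}

# ---- grid geometry helpers (internal) --------------------------------------

# world coordinates of voxel centers; ijk is an n x 3 matrix of 1-based indices
vox_to_world <- function(image, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(sweep(ijk - 1, 2, image$spacing, `*`), 2, image$origin, `+`)
}

# continuous 1-based voxel coordinates of world points (n x 3)
world_to_vox <- function(image, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  sweep(sweep(xyz, 2, image$origin, `-`), 2, image$spacing, `/`) + 1
}

# nearest voxel index of a world point; errors if outside the grid
seed_voxel <- function(image, seed_world, what = "seed") {
  v <- round(world_to_vox(image, seed_world))
  d <- dim(image$values)
  if (any(v < 1) || any(v > matrix(d, 1)))
    stop(what, " point (", paste(signif(seed_world, 4), collapse = ", "),
         ") mm lies outside the image grid")
  as.integer(v)
}

grid_compatible <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!grid_compatible(a, b))
    stop(what, " are not on the same grid (shape/spacing/origin differ)")
  invisible(TRUE)
}

# linear indices (and optionally distances) of voxels whose centers lie within
# `radius` mm of `center`, computed on the sphere's bounding box only
sphere_voxel_indices <- function(dim3, spacing, origin, center, radius,
                                 return_dist = FALSE) {
  lo <- pmax(1L, as.integer(ceiling((center - radius - origin) / spacing)) + 1L)
  hi <- pmin(as.integer(dim3), as.integer(floor((center + radius - origin) / spacing)) + 1L)
  if (any(lo > hi)) {
    return(if (return_dist) list(idx = integer(0), dist = numeric(0)) else integer(0))
  }
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  dx2 <- (origin[1] + (ii - 1) * spacing[1] - center[1])^2
  dy2 <- (origin[2] + (jj - 1) * spacing[2] - center[2])^2
  dz2 <- (origin[3] + (kk - 1) * spacing[3] - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  keep <- which(d2 <= radius^2)
  if (length(keep) == 0L) {
    return(if (return_dist) list(idx = integer(0), dist = numeric(0)) else integer(0))
  }
  sub <- arrayInd(keep, dim(d2))
  idx <- (lo[1] - 1L + sub[, 1]) +
    as.integer(dim3[1]) * (lo[2] - 2L + sub[, 2]) +
    as.integer(dim3[1]) * as.integer(dim3[2]) * (lo[3] - 2L + sub[, 3])
  if (return_dist) list(idx = idx, dist = sqrt(d2[keep])) else idx
}
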