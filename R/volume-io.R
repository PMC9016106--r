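#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads a NIfTI-1 file into a [volume_image()]. Only 3D, axis-aligned volumes
#' are supported: the sform/qform linear part must be diagonal with positive
#' entries equal to the voxel spacing (the convention [write_volume()] emits).
#' The world origin is taken from the translation column of the xform.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions in ", path)
  vals <- array(as.numeric(img), dim = d)
  n_bad <- sum(!is.finite(vals))
  if (n_bad > 0L)
    stop("volume ", path, " contains ", n_bad, " non-finite voxel(s); refusing to load")
  xf <- RNifti::xform(img)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  lin <- xf[1:3, 1:3]
  if (max(abs(lin - diag(spacing))) > 1e-3 * max(spacing))
    stop("volume ", path, " is not axis-aligned with positive voxel axes; ",
         "reorient it before loading (only diagonal xforms are supported)")
  volume_image(vals, spacing = spacing, origin = xf[1:3, 4])
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' Intensity volumes are stored as 32-bit float; binary masks as 8-bit
#' unsigned integers holding exactly 0/1. The world convention of
#' [volume_image()] is stored in both the sform and qform.
#'
#' @param image a [volume_image()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype on-disk datatype; default `"float"` for images and
#'   `"uint8"` for masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path, datatype = NULL) {
  if (inherits(image, "binary_mask")) {
    vals <- array(as.integer(image$values), dim = dim(image$values))
    if (is.null(datatype)) datatype <- "uint8"
    geo <- image
  } else if (is_volume_image(image)) {
    vals <- image$values
    if (is.null(datatype)) datatype <- "float"
    geo <- image
  } else stop("`image` must be a volume_image or binary_mask")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ni <- RNifti::asNifti(vals)
  RNifti::pixdim(ni) <- geo$spacing
  m <- rbind(cbind(diag(geo$spacing), geo$origin), c(0, 0, 0, 1))
  RNifti::sform(ni) <- structure(m, code = 2L)
  RNifti::qform(ni) <- structure(m, code = 2L)
  RNifti::writeNifti(ni, path, datatype = datatype)
  invisible(path)
}

#' Convert an activity-concentration volume to an SUV map
#'
#' Standardized uptake value: voxel activity concentration divided by injected
#' activity per gram of body weight. With activity in kBq/mL, injected
#' activity in MBq (decay-corrected to scan time, upstream of this call) and
#' weight in kg, the units cancel to `SUV = activity * body_weight /
#' injected_activity`, so a concentration numerically equal to the injected
#' dose per gram of body gives SUV = 1.
#'
#' @param activity a [volume_image()] of activity concentration in kBq/mL;
#'   all values must be >= 0.
#' @param injected_activity injected activity in MBq, decay-corrected; > 0.
#' @param body_weight body weight in kg; > 0.
#' @return An [suv_map()].
#' @examples
#' act <- volume_image(array(3.7, c(2, 2, 2)))
#' compute_suv(act, injected_activity = 259, body_weight = 70)$image$values[1]
#' @export
compute_suv <- function(activity, injected_activity, body_weight) {
  if (!is_volume_image(activity)) stop("`activity` must be a volume_image")
  if (!is.numeric(injected_activity) || length(injected_activity) != 1L ||
      !is.finite(injected_activity) || injected_activity <= 0)
    stop("`injected_activity` must be a single positive number (MBq)")
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("`body_weight` must be a single positive number (kg)")
  if (any(activity$values < 0))
    stop("activity concentrations must be >= 0")
  suv_vals <- activity$values * (body_weight / injected_activity)
  suv_map(volume_image(suv_vals, activity$spacing, activity$origin),
          injected_activity = injected_activity, body_weight = body_weight)
}

# linear interpolation of a 3D array along its first axis onto the 2x fine
# grid (cell-centered halving, clamped at the ends)
halve_first_axis <- function(a) {
  d <- dim(a)
  n <- d[1]
  if (n == 1L) {
    out <- a[rep(1L, 2L), , , drop = FALSE]
    dim(out) <- c(2L, d[2], d[3])
    return(out)
  }
  s <- (seq_len(2L * n) - 1) / 2 - 0.25      # 0-based source coordinate
  s <- pmin(pmax(s, 0), n - 1)
  i0 <- pmin(floor(s), n - 2)
  w <- s - i0
  m <- matrix(a, nrow = n)
  out <- m[i0 + 1, , drop = FALSE] * (1 - w) + m[i0 + 2, , drop = FALSE] * w
  array(out, dim = c(2L * n, d[2], d[3]))
}

#' Double the grid resolution of a volume
#'
#' Resamples a volume onto a grid with half the voxel size on every axis
#' (mirroring the standard console interpolation step applied to PET images).
#' The output has exactly twice the voxels per axis; fine voxel centers are
#' placed cell-centered so the physical extent of the image is preserved. The
#' kernel is separable linear interpolation, clamped at the boundary
#' (quarter-voxel edge positions replicate the edge value), so constant images
#' stay constant and no output value leaves the input range.
#'
#' @param image a [volume_image()].
#' @return A [volume_image()] with `spacing/2` and doubled dimensions.
#' @export
interpolate_halve <- function(image) {
  if (!is_volume_image(image)) stop("`image` must be a volume_image")
  v <- image$values
  for (ax in 1:3) {
    v <- halve_first_axis(v)
    v <- aperm(v, c(2, 3, 1))
  }
  volume_image(v, spacing = image$spacing / 2,
               origin = image$origin - image$spacing / 4)
}

#' Resample a volume onto a reference grid
#'
#' Pulls the moving image onto the reference image's grid through an affine
#' transform mapping moving world coordinates into the reference frame.
#' Intensities use trilinear interpolation; masks use nearest-neighbor and
#' return strictly 0/1 values. Voxels mapping outside the moving image get 0.
#'
#' @param moving a [volume_image()] or [binary_mask()] to resample.
#' @param reference a [volume_image()] (or [binary_mask()]) defining the
#'   output grid.
#' @param transform an [affine_transform()]; identity by default.
#' @param mode `"intensity"` (trilinear) or `"mask"` (nearest-neighbor).
#'   Defaults to `"mask"` when `moving` is a [binary_mask()].
#' @return A [volume_image()] on the reference grid, or a [binary_mask()]
#'   when `moving` is one.
#' @export
resample_to <- function(moving, reference, transform = identity_affine(),
                        mode = c("intensity", "mask")) {
  is_mask <- inherits(moving, "binary_mask")
  if (is_mask) {
    mode <- "mask"
    mov_img <- volume_image(array(as.numeric(moving$values), dim(moving$values)),
                            moving$spacing, moving$origin)
  } else {
    if (!is_volume_image(moving)) stop("`moving` must be a volume_image or binary_mask")
    mode <- match.arg(mode)
    mov_img <- moving
  }
  if (inherits(reference, "binary_mask"))
    reference <- volume_image(array(as.numeric(reference$values), dim(reference$values)),
                              reference$spacing, reference$origin)
  if (!inherits(transform, "affine_transform"))
    stop("`transform` must be an affine_transform")

  if (is_identity_affine(transform) && grid_compatible(mov_img, reference)) {
    out <- volume_image(mov_img$values, reference$spacing, reference$origin)
    return(if (is_mask) binary_mask(out$values, reference) else out)
  }

  inv <- solve(transform$linear)
  d <- dim(reference$values)
  dm <- dim(mov_img$values)
  i <- seq_len(d[1]); j <- seq_len(d[2]); k <- seq_len(d[3])
  wx <- reference$origin[1] + (i - 1) * reference$spacing[1]
  wy <- reference$origin[2] + (j - 1) * reference$spacing[2]
  wz <- reference$origin[3] + (k - 1) * reference$spacing[3]
  X <- rep(wx, times = d[2] * d[3]) - transform$translation[1]
  Y <- rep(rep(wy, each = d[1]), times = d[3]) - transform$translation[2]
  Z <- rep(wz, each = d[1] * d[2]) - transform$translation[3]
  mx <- inv[1, 1] * X + inv[1, 2] * Y + inv[1, 3] * Z
  my <- inv[2, 1] * X + inv[2, 2] * Y + inv[2, 3] * Z
  mz <- inv[3, 1] * X + inv[3, 2] * Y + inv[3, 3] * Z
  vx <- (mx - mov_img$origin[1]) / mov_img$spacing[1] + 1
  vy <- (my - mov_img$origin[2]) / mov_img$spacing[2] + 1
  vz <- (mz - mov_img$origin[3]) / mov_img$spacing[3] + 1
  mv <- mov_img$values
  n12 <- dm[1] * dm[2]
  out <- numeric(prod(d))

  if (mode == "mask") {
    ix <- round(vx); iy <- round(vy); iz <- round(vz)
    ok <- ix >= 1 & ix <= dm[1] & iy >= 1 & iy <= dm[2] & iz >= 1 & iz <= dm[3]
    lin <- ix[ok] + dm[1] * (iy[ok] - 1) + n12 * (iz[ok] - 1)
    out[ok] <- mv[lin]
    out <- as.numeric(out > 0.5)
  } else {
    x0 <- floor(vx); y0 <- floor(vy); z0 <- floor(vz)
    fx <- vx - x0; fy <- vy - y0; fz <- vz - z0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      cx <- x0 + dx; cy <- y0 + dy; cz <- z0 + dz
      w <- (if (dx == 1) fx else 1 - fx) *
           (if (dy == 1) fy else 1 - fy) *
           (if (dz == 1) fz else 1 - fz)
      ok <- cx >= 1 & cx <= dm[1] & cy >= 1 & cy <= dm[2] & cz >= 1 & cz <= dm[3] & w > 0
      if (any(ok)) {
        lin <- cx[ok] + dm[1] * (cy[ok] - 1) + n12 * (cz[ok] - 1)
        out[ok] <- out[ok] + w[ok] * mv[lin]
      }
    }
  }
  dim(out) <- d
  res <- volume_image(out, reference$spacing, reference$origin)
  if (is_mask) binary_mask(res$values, reference) else res
}
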