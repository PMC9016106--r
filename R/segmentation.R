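#' Binary voxel mask aligned to a reference grid
#'
#' A `{0,1}` voxel mask carrying the grid geometry (shape, spacing, origin) of
#' the volume it is aligned to. All region-of-interest outputs of the
#' segmentation stage — reference spheres, contrast-enhancement mask,
#' metabolic mask, exclusions, margin differences — are `binary_mask` objects.
#'
#' @param values logical or 0/1 numeric 3D array.
#' @param reference a [volume_image()], [suv_map()] or another `binary_mask`
#'   providing the grid; `values` must match its shape.
#' @return An object of class `binary_mask` with integer `values` and the
#'   reference `spacing`/`origin`.
#' @export
binary_mask <- function(values, reference) {
  if (inherits(reference, "suv_map")) reference <- reference$image
  if (!is_volume_image(reference) && !inherits(reference, "binary_mask"))
    stop("`reference` must be a volume_image, suv_map or binary_mask")
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!identical(dim(values), dim(reference$values)))
    stop("mask shape ", paste(dim(values), collapse = "x"),
         " does not match reference grid ",
         paste(dim(reference$values), collapse = "x"))
  if (is.logical(values)) {
    if (anyNA(values)) stop("mask values must be strictly 0/1")
    storage.mode(values) <- "integer"
  } else {
    if (anyNA(values)) stop("mask values must be strictly 0/1")
    rng <- range(values)
    if (rng[1] < 0 || rng[2] > 1 ||
        (is.double(values) && any(values != floor(values))))
      stop("mask values must be strictly 0/1")
    storage.mode(values) <- "integer"
  }
  structure(list(values = values,
                 spacing = reference$spacing,
                 origin = reference$origin),
            class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$values)

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d set (%.2f mL)\n",
              d[1], d[2], d[3], sum(x$values), mask_volume_ml(x)))
  invisible(x)
}

#' Number of set voxels in a mask
#' @param mask a [binary_mask()].
#' @return Integer count of voxels equal to 1.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values)
}

#' Segmentation parameters
#'
#' Free parameters of the three-ROI segmentation. `fby_threshold_multiple` is
#' the reference-normalized PET threshold: a voxel belongs to the metabolic
#' candidate set when `SUV > fby_threshold_multiple * Nmax` (strict
#' inequality), with the conventional value 3.0 used for biologic target
#' delineation. `mri_k` sets the contrast-enhancement threshold at
#' `mean + mri_k * sd` of the normal-tissue intensity. `connectivity` governs
#' foreground connected components (background cavity filling is always
#' 6-connected, the complementary pair). `sphere_radius_mm` is the radius of
#' the three contralateral reference spheres.
#'
#' @param fby_threshold_multiple positive scalar; default 3.0.
#' @param mri_k positive scalar; default 3.0.
#' @param connectivity one of 6, 18, 26; default 26.
#' @param sphere_radius_mm positive scalar (mm); default 5.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(fby_threshold_multiple = 3.0,
                                mri_k = 3.0,
                                connectivity = 26L,
                                sphere_radius_mm = 5.0) {
  if (!is.numeric(fby_threshold_multiple) || fby_threshold_multiple <= 0)
    stop("`fby_threshold_multiple` must be > 0")
  if (!is.numeric(mri_k) || mri_k < 0) stop("`mri_k` must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("`connectivity` must be 6, 18 or 26")
  if (!is.numeric(sphere_radius_mm) || sphere_radius_mm <= 0)
    stop("`sphere_radius_mm` must be > 0")
  structure(list(fby_threshold_multiple = as.numeric(fby_threshold_multiple),
                 mri_k = as.numeric(mri_k),
                 connectivity = as.integer(connectivity),
                 sphere_radius_mm = as.numeric(sphere_radius_mm)),
            class = "segmentation_config")
}

#' Midline plane specification
#'
#' The interhemispheric plane used to mirror the tumor position onto the
#' contralateral side. Defaults to the sagittal plane x = 0 (the phantom
#' grids are centered so that their midline is x = 0).
#'
#' @param point a point on the plane (mm).
#' @param normal plane normal; need not be unit length.
#' @return An object of class `midline_plane`.
#' @export
midline_plane <- function(point = c(0, 0, 0), normal = c(1, 0, 0)) {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn == 0) stop("`normal` must be a nonzero vector")
  structure(list(point = as.numeric(point), normal = normal / nn),
            class = "midline_plane")
}

plane_signed_distance <- function(plane, p) sum((p - plane$point) * plane$normal)

reflect_point <- function(plane, p) {
  p - 2 * plane_signed_distance(plane, p) * plane$normal
}

# ---- internal morphology wrappers ------------------------------------------

component_of_seed <- function(values, seed_ijk, connectivity) {
  d <- dim(values)
  lin <- seed_ijk[1] + d[1] * (seed_ijk[2] - 1L) + d[1] * d[2] * (seed_ijk[3] - 1L)
  comp <- .seed_component3d(as.logical(values), as.integer(d), as.integer(lin),
                            as.integer(connectivity))
  array(comp, dim = d)
}

# cavity filling on the bounding box of the foreground (plus a 1-voxel pad),
# equivalent to filling on the full grid but independent of grid size
fill_enclosed_cavities <- function(values) {
  d <- dim(values)
  idx <- which(values != 0)
  if (length(idx) == 0L) return(values)
  sub <- arrayInd(idx, d)
  lo <- pmax(1L, apply(sub, 2, min) - 1L)
  hi <- pmin(d, apply(sub, 2, max) + 1L)
  box <- values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  filled <- .fill_holes3d(as.logical(box), as.integer(dim(box)))
  out <- values
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- array(filled * 1L, dim(box))
  out
}

#' Place contralateral reference spheres and measure normal-brain SUV
#'
#' Mirrors the tumor center across the midline plane and places three
#' non-overlapping spheres of radius `sphere_radius_mm` on the contralateral
#' side: one at the mirrored center and two offset along the
#' superior-inferior (z) axis at multiples of two radii (falling back to
#' farther offsets when a position would leave the grid or cross the
#' midline). `Nmax` and `Nmean` are the maximum and mean SUV pooled over the
#' union of the three spheres.
#'
#' @param suv an [suv_map()] (or [volume_image()] in SUV units).
#' @param tumor_center world coordinates (mm) of the tumor, strictly off the
#'   midline.
#' @param midline a [midline_plane()].
#' @param config a [segmentation_config()].
#' @return A list with `mask` (the union [binary_mask()]) and `stats` (class
#'   `reference_stats`: `n_max`, `n_mean`, `sphere_centers` (3 x 3 matrix of
#'   world points), `sphere_radius`).
#' @export
place_reference_rois <- function(suv, tumor_center,
                                 midline = midline_plane(),
                                 config = segmentation_config()) {
  img <- as_suv_image(suv)
  r <- config$sphere_radius_mm
  sd0 <- plane_signed_distance(midline, tumor_center)
  if (abs(sd0) < 1e-9)
    stop("tumor center lies on the midline plane; it must be strictly lateral")
  mirrored <- reflect_point(midline, tumor_center)

  d <- dim(img$values)
  wmin <- img$origin
  wmax <- img$origin + (d - 1) * img$spacing
  inside_grid <- function(ctr) all(ctr - r >= wmin) && all(ctr + r <= wmax)
  opposite_side <- function(ctr) {
    sdc <- plane_signed_distance(midline, ctr)
    sign(sdc) == -sign(sd0) && abs(sdc) >= r
  }

  centers <- list()
  for (mult in c(0, 2, -2, 4, -4, 6, -6)) {
    ctr <- mirrored + c(0, 0, mult * r)
    if (inside_grid(ctr) && opposite_side(ctr)) centers[[length(centers) + 1L]] <- ctr
    if (length(centers) == 3L) break
  }
  if (length(centers) < 3L)
    stop("could not place three reference spheres: mirrored positions fall ",
         "outside the image or cross the midline")

  vals <- array(0L, d)
  for (ctr in centers)
    vals[sphere_voxel_indices(d, img$spacing, img$origin, ctr, r)] <- 1L
  idx <- which(vals == 1L)
  if (length(idx) == 0L)
    stop("reference spheres contain no voxels at this grid resolution")
  suv_in <- img$values[idx]
  stats <- structure(list(n_max = max(suv_in),
                          n_mean = mean(suv_in),
                          sphere_centers = do.call(rbind, centers),
                          sphere_radius = r),
                     class = "reference_stats")
  list(mask = binary_mask(vals, img), stats = stats)
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats> Nmax = %.4f, Nmean = %.4f (3 spheres, r = %.1f mm)\n",
              x$n_max, x$n_mean, x$sphere_radius))
  invisible(x)
}

#' Segment the contrast-enhanced tumor on T1-weighted MRI
#'
#' Reproducible stand-in for the semiautomatic contrast-enhancement
#' delineation: the threshold is `mean + mri_k * sd` of the intensities
#' inside `normal_mask` (normal-appearing tissue, e.g. the contralateral
#' reference spheres); the mask is the above-threshold connected component
#' containing `seed`, with fully enclosed cavities filled.
#'
#' @param t1c contrast-enhanced T1-weighted [volume_image()].
#' @param seed world point (mm) inside the enhancing tumor.
#' @param normal_mask nonempty [binary_mask()] of normal tissue on the same
#'   grid.
#' @param config a [segmentation_config()].
#' @return A [binary_mask()] with attribute `"threshold"` recording the
#'   intensity threshold used.
#' @export
segment_mri <- function(t1c, seed, normal_mask,
                        config = segmentation_config()) {
  if (!is_volume_image(t1c)) stop("`t1c` must be a volume_image")
  stop_if_grid_mismatch(t1c, normal_mask, "t1c and normal_mask")
  idx <- which(normal_mask$values == 1L)
  if (length(idx) == 0L) stop("`normal_mask` is empty")
  ref_vals <- t1c$values[idx]
  thr <- mean(ref_vals) + config$mri_k * stats::sd(ref_vals)
  sv <- seed_voxel(t1c, seed)
  seed_val <- t1c$values[sv[1], sv[2], sv[3]]
  if (!(seed_val > thr))
    stop(sprintf("seed voxel intensity %.4g is not above the enhancement threshold %.4g",
                 seed_val, thr))
  cand <- (t1c$values > thr) * 1L
  comp <- component_of_seed(cand, sv, config$connectivity)
  out <- fill_enclosed_cavities(comp * 1L)
  m <- binary_mask(out, t1c)
  attr(m, "threshold") <- thr
  m
}

#' Segment the metabolic tumor volume on the SUV map
#'
#' Voxels with `SUV > fby_threshold_multiple * Nmax` (strict inequality) form
#' the candidate set; voxels under any exclusion mask (physiological uptake
#' such as venous sinus or choroid plexus) are removed; the result is the
#' candidate connected component containing `seed` with enclosed cavities
#' filled. Exclusions are re-applied after cavity filling, so the output
#' never intersects an exclusion mask.
#'
#' @param suv an [suv_map()].
#' @param ref `reference_stats` from [place_reference_rois()] (or a single
#'   positive number taken as Nmax).
#' @param seed world point (mm) inside the metabolic tumor.
#' @param exclusions list of [binary_mask()]s to remove.
#' @param config a [segmentation_config()].
#' @return A [binary_mask()] with attribute `"threshold"` (the absolute SUV
#'   threshold used).
#' @export
segment_fby <- function(suv, ref, seed, exclusions = list(),
                        config = segmentation_config()) {
  img <- as_suv_image(suv)
  n_max <- if (inherits(ref, "reference_stats")) ref$n_max else as.numeric(ref)
  if (!is.finite(n_max) || n_max <= 0) stop("reference Nmax must be > 0")
  thr <- config$fby_threshold_multiple * n_max
  cand <- img$values > thr
  if (length(exclusions) > 0) {
    for (ex in exclusions) {
      stop_if_grid_mismatch(img, ex, "suv and exclusion mask")
      cand[ex$values == 1L] <- FALSE
    }
  }
  if (!any(cand))
    stop(sprintf("no voxel exceeds the SUV threshold %.4g (%.1f x Nmax %.4g)",
                 thr, config$fby_threshold_multiple, n_max))
  sv <- seed_voxel(img, seed)
  if (!cand[sv[1], sv[2], sv[3]])
    stop(sprintf("seed voxel SUV %.4g does not exceed the threshold %.4g",
                 img$values[sv[1], sv[2], sv[3]], thr))
  comp <- component_of_seed(cand * 1L, sv, config$connectivity)
  out <- fill_enclosed_cavities(comp * 1L)
  for (ex in exclusions) out[ex$values == 1L] <- 0L
  m <- binary_mask(out, img)
  attr(m, "threshold") <- thr
  m
}

#' Enforce spatial continuity of a mask
#'
#' Keeps the connected component containing `seed` and fills all fully
#' enclosed 3D cavities (the automated analog of manual ROI editing that
#' removes discontinuous areas and fills the inside of the tumor core).
#' Idempotent: cleaning a cleaned mask changes nothing.
#'
#' @param mask a [binary_mask()].
#' @param seed world point (mm); its voxel must be set in `mask`.
#' @param connectivity foreground connectivity, one of 6, 18, 26.
#' @return A [binary_mask()].
#' @export
clean_mask <- function(mask, seed, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  geo <- volume_image(array(0, dim(mask$values)), mask$spacing, mask$origin)
  sv <- seed_voxel(geo, seed)
  if (mask$values[sv[1], sv[2], sv[3]] != 1L)
    stop("seed voxel is not set in the mask")
  comp <- component_of_seed(mask$values, sv, connectivity)
  binary_mask(fill_enclosed_cavities(comp * 1L), mask)
}
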