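#' Physical volume of a mask in milliliters
#'
#' @param mask a [binary_mask()].
#' @return Volume in mL: set voxel count times voxel volume (mm^3) / 1000.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * prod(mask$spacing) / 1000
}

#' Overlap volume of two masks
#'
#' `|A intersect B| / min(|A|, |B|)`, computed on voxel counts of the shared
#' grid. Equals 1 exactly when one mask is contained in the other, and 0 when
#' they are disjoint. Symmetric in its arguments.
#'
#' @param a,b nonempty [binary_mask()]s on the same grid.
#' @return A number in `[0, 1]`.
#' @export
overlap_volume <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$values); nb <- sum(b$values)
  if (na == 0L || nb == 0L)
    stop("overlap volume is undefined for an empty mask")
  sum(a$values == 1L & b$values == 1L) / min(na, nb)
}

#' DICE score of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, computed on voxel counts of the shared
#' grid. Symmetric; never exceeds the overlap volume.
#'
#' @param a,b [binary_mask()]s on the same grid; at least one nonempty.
#' @return A number in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L) stop("DICE score is undefined when both masks are empty")
  2 * sum(a$values == 1L & b$values == 1L) / (na + nb)
}

#' SUV statistics over a region of interest
#'
#' @param suv an [suv_map()] (or [volume_image()] in SUV units).
#' @param mask a nonempty [binary_mask()] on the SUV grid.
#' @return A list with `suv_max` and `suv_mean` over the set voxels.
#' @export
suv_stats <- function(suv, mask) {
  img <- as_suv_image(suv)
  stop_if_grid_mismatch(img, mask, "suv and mask")
  idx <- which(mask$values == 1L)
  if (length(idx) == 0L) stop("cannot compute SUV statistics over an empty mask")
  vals <- img$values[idx]
  list(suv_max = max(vals), suv_mean = mean(vals))
}

#' Tumor-to-normal ratio
#'
#' @param suv_max lesion maximum SUV.
#' @param n_max normal-brain maximum SUV (Nmax); must be > 0.
#' @return `suv_max / n_max`.
#' @export
tn_ratio <- function(suv_max, n_max) {
  if (!is.numeric(n_max) || n_max <= 0) stop("`n_max` must be > 0")
  suv_max / n_max
}

#' Margin region: metabolic activity beyond contrast enhancement
#'
#' Voxelwise set difference `fby \ mri` — the region with suprathreshold PET
#' uptake but no MRI contrast enhancement.
#'
#' @param fby metabolic-tumor [binary_mask()].
#' @param mri contrast-enhancement [binary_mask()] on the same grid.
#' @return A [binary_mask()] (possibly empty).
#' @export
margin_region <- function(fby, mri) {
  stopifnot(inherits(fby, "binary_mask"), inherits(mri, "binary_mask"))
  stop_if_grid_mismatch(fby, mri, "masks")
  binary_mask((fby$values == 1L & mri$values == 0L) * 1L, fby)
}

#' Per-lesion metric bundle
#'
#' Computes the full per-lesion row behind the cohort tables: ROI volumes,
#' overlap volume and DICE score, SUVmax and T/N ratio (the maximum over the
#' union of the two ROIs and its ratio to Nmax), SUVmean under each ROI, and
#' the margin-region statistics. When the margin `fby \ mri` is empty its
#' SUVmean is reported as `NA` and flagged via `margin_defined = FALSE`
#' rather than as 0, so that group means are not corrupted.
#'
#' @param suv an [suv_map()].
#' @param mri contrast-enhancement [binary_mask()].
#' @param fby nonempty metabolic-tumor [binary_mask()] on the same grid.
#' @param ref `reference_stats` from [place_reference_rois()].
#' @return A one-row [tibble::tibble()] with columns `volume_mri`,
#'   `volume_fby` (mL), `overlap_volume`, `dice`, `suv_max`, `tn_ratio`,
#'   `suv_mean_mri`, `suv_mean_fby`, `suv_mean_margin`, `margin_over_nmax`,
#'   `margin_defined`, `n_margin_voxels`, `n_max`, `n_mean`.
#' @export
lesion_metrics <- function(suv, mri, fby, ref) {
  img <- as_suv_image(suv)
  stopifnot(inherits(ref, "reference_stats"))
  if (sum(fby$values) == 0L) stop("`fby` mask is empty")
  s_m <- suv_stats(img, mri)
  s_f <- suv_stats(img, fby)
  margin <- margin_region(fby, mri)
  n_margin <- sum(margin$values)
  suv_mean_margin <- if (n_margin > 0L) suv_stats(img, margin)$suv_mean else NA_real_
  suv_max <- max(s_m$suv_max, s_f$suv_max)
  tibble::tibble(
    volume_mri = mask_volume_ml(mri),
    volume_fby = mask_volume_ml(fby),
    overlap_volume = overlap_volume(mri, fby),
    dice = dice_score(mri, fby),
    suv_max = suv_max,
    tn_ratio = tn_ratio(suv_max, ref$n_max),
    suv_mean_mri = s_m$suv_mean,
    suv_mean_fby = s_f$suv_mean,
    suv_mean_margin = suv_mean_margin,
    margin_over_nmax = suv_mean_margin / ref$n_max,
    margin_defined = n_margin > 0L,
    n_margin_voxels = as.integer(n_margin),
    n_max = ref$n_max,
    n_mean = ref$n_mean
  )
}
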