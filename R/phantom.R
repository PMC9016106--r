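# cache for geometry shared across a cohort (brain sphere, tumor distances)
.phantom_cache <- new.env(parent = emptyenv())

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rough expected maximum of the background SUV over the reference spheres
expected_background_max <- function(spec, sphere_radius_mm = 5) {
  n <- max(2, round(3 * (4 / 3) * pi * sphere_radius_mm^3 / prod(spec$spacing)))
  spec$background_suv_mean + spec$background_suv_sd * sqrt(2 * log(n))
}

#' Digital brain-tumor phantom specification
#'
#' Parameters of the paired MRI/PET phantom. The defaults emulate the
#' imaging conditions the pipeline targets: a 96^3 grid at 1.5 mm isotropic
#' spacing centered on the midline (x = 0); a spherical "brain" of low
#' background uptake (SUV ~ Normal(0.037, 0.022) truncated at 0, so the
#' maximum over the contralateral reference spheres lands near 0.116); a
#' contrast-enhancing tumor core of radius 10 mm at SUV 2.5; and, for
#' diffuse geometry, a concentric non-enhancing infiltration shell whose SUV
#' tapers linearly from `margin_suv` at the core edge down to
#' `margin_floor_suv` at the outer edge — always above 3x the expected
#' background maximum so the shell stays above the metabolic threshold.
#' An optional hot blob emulates physiological uptake (venous sinus) for
#' testing exclusion masks.
#'
#' @param grid_shape integer length 3; default `c(96, 96, 96)`.
#' @param spacing mm per axis; default 1.5 isotropic.
#' @param brain_radius brain sphere radius, mm.
#' @param tumor_center world coordinates (mm), strictly off the midline x=0.
#' @param core_radius contrast-enhancing core radius, mm.
#' @param margin_width infiltration shell width, mm; 0 for circumscribed
#'   geometry.
#' @param core_suv SUV of the tumor core.
#' @param margin_suv SUV at the inner edge of the infiltration shell.
#' @param margin_floor_suv SUV at the outer edge of the shell; must stay
#'   above 3x the expected background maximum.
#' @param background_suv_mean,background_suv_sd background SUV distribution
#'   (truncated at 0).
#' @param mri_background,noise_sd_mri normal-tissue MRI intensity and noise
#'   (arbitrary units).
#' @param enhancement_intensity MRI intensity added inside the core.
#' @param sinus optional `list(center=, radius=, suv=)` hot blob.
#' @param body_weight,injected_activity patient metadata (kg, MBq
#'   decay-corrected) used to convert between SUV and activity maps.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         spacing = c(1.5, 1.5, 1.5),
                         brain_radius = 60,
                         tumor_center = c(25, 5, 0),
                         core_radius = 10,
                         margin_width = 0,
                         core_suv = 2.5,
                         margin_suv = 1.0,
                         margin_floor_suv = 0.45,
                         background_suv_mean = 0.037,
                         background_suv_sd = 0.022,
                         mri_background = 100,
                         noise_sd_mri = 5,
                         enhancement_intensity = 100,
                         sinus = NULL,
                         body_weight = 70,
                         injected_activity = 259,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
               brain_radius = brain_radius, tumor_center = as.numeric(tumor_center),
               core_radius = core_radius, margin_width = margin_width,
               core_suv = core_suv, margin_suv = margin_suv,
               margin_floor_suv = margin_floor_suv,
               background_suv_mean = background_suv_mean,
               background_suv_sd = background_suv_sd,
               mri_background = mri_background, noise_sd_mri = noise_sd_mri,
               enhancement_intensity = enhancement_intensity, sinus = sinus,
               body_weight = body_weight, injected_activity = injected_activity,
               seed = as.integer(seed))
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 8L))
    stop("`grid_shape` must be 3 integers >= 8")
  if (any(spec$spacing <= 0)) stop("`spacing` must be positive")
  if (spec$core_radius <= 0) stop("`core_radius` must be > 0")
  if (spec$margin_width < 0) stop("`margin_width` must be >= 0")
  if (abs(spec$tumor_center[1]) < 1e-9)
    stop("`tumor_center` must be strictly off the midline plane x = 0")
  tumor_extent <- sqrt(sum(spec$tumor_center^2)) + spec$core_radius + spec$margin_width
  if (tumor_extent > spec$brain_radius)
    stop("tumor (core + margin) exceeds the brain support: extent ",
         signif(tumor_extent, 4), " mm > brain radius ", spec$brain_radius, " mm")
  if (spec$margin_width > 0) {
    bg_max <- expected_background_max(spec)
    if (spec$margin_floor_suv <= 3 * bg_max)
      stop("`margin_floor_suv` (", spec$margin_floor_suv,
           ") must exceed 3x the expected background maximum (",
           signif(3 * bg_max, 4), ") so the shell stays above the threshold")
    if (spec$margin_suv < spec$margin_floor_suv || spec$margin_suv > spec$core_suv)
      stop("`margin_suv` must lie in [margin_floor_suv, core_suv]")
  }
  if (!is.null(spec$sinus)) {
    if (!all(c("center", "radius", "suv") %in% names(spec$sinus)))
      stop("`sinus` must be a list(center=, radius=, suv=)")
  }
  structure(spec, class = "phantom_spec")
}

phantom_grid <- function(spec) {
  origin <- -(spec$grid_shape - 1) / 2 * spec$spacing
  list(dim = spec$grid_shape, spacing = spec$spacing, origin = origin)
}

.cached_sphere <- function(g, center, radius, with_dist = FALSE) {
  key <- paste(c(g$dim, signif(g$spacing, 10), signif(center, 10),
                 signif(radius, 10), with_dist), collapse = "_")
  if (!is.null(.phantom_cache[[key]])) return(.phantom_cache[[key]])
  res <- sphere_voxel_indices(g$dim, g$spacing, g$origin, center, radius,
                              return_dist = with_dist)
  .phantom_cache[[key]] <- res
  res
}

#' Generate one paired MRI/PET phantom
#'
#' Draws the background noise fields and assembles the contrast-enhanced
#' T1-like volume, the SUV map and the ground-truth masks described by a
#' [phantom_spec()]. Deterministic given the spec (bit-identical volumes for
#' the same seed).
#'
#' @param spec a [phantom_spec()].
#' @return A list with `t1c` ([volume_image()]), `suv` ([suv_map()]),
#'   `truth` (list of [binary_mask()]s: `enhancement`, `fby_positive`,
#'   `margin`, `exclusion`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_grid(spec)
  d <- g$dim
  brain_idx <- .cached_sphere(g, c(0, 0, 0), spec$brain_radius)
  tumor <- .cached_sphere(g, spec$tumor_center,
                          spec$core_radius + spec$margin_width, with_dist = TRUE)
  core_sel <- tumor$dist <= spec$core_radius
  core_idx <- tumor$idx[core_sel]
  margin_idx <- tumor$idx[!core_sel]
  margin_dist <- tumor$dist[!core_sel]

  vols <- .with_seed(spec$seed, {
    suv <- array(0, d)
    nb <- length(brain_idx)
    suv[brain_idx] <- pmax(spec$background_suv_mean +
                             spec$background_suv_sd * stats::rnorm(nb), 0)
    t1c <- array(0, d)
    t1c[brain_idx] <- spec$mri_background + spec$noise_sd_mri * stats::rnorm(nb)
    list(suv = suv, t1c = t1c)
  })
  suv <- vols$suv; t1c <- vols$t1c

  suv[core_idx] <- spec$core_suv
  if (spec$margin_width > 0 && length(margin_idx) > 0) {
    frac <- (margin_dist - spec$core_radius) / spec$margin_width
    suv[margin_idx] <- spec$margin_suv +
      (spec$margin_floor_suv - spec$margin_suv) * frac
  }
  t1c[core_idx] <- t1c[core_idx] + spec$enhancement_intensity

  excl <- array(0L, d)
  if (!is.null(spec$sinus)) {
    sidx <- .cached_sphere(g, spec$sinus$center, spec$sinus$radius)
    suv[sidx] <- spec$sinus$suv
    t1c[sidx] <- t1c[sidx] + spec$enhancement_intensity
    excl[sidx] <- 1L
  }

  t1c_img <- volume_image(t1c, g$spacing, g$origin)
  suv_img <- volume_image(suv, g$spacing, g$origin)

  mk <- function(idx) {
    v <- array(0L, d); v[idx] <- 1L
    binary_mask(v, t1c_img)
  }
  truth <- list(enhancement = mk(core_idx),
                fby_positive = mk(tumor$idx),
                margin = mk(margin_idx),
                exclusion = binary_mask(excl, t1c_img))

  list(t1c = t1c_img,
       suv = suv_map(suv_img, spec$injected_activity, spec$body_weight),
       truth = truth,
       spec = spec)
}

#' Generate a synthetic two-group cohort manifest
#'
#' Builds per-patient phantom specifications for a diffuse vs circumscribed
#' cohort: margin widths drawn uniformly from each group's range, per-patient
#' seeds derived as `seed + patient index`, and light demographic metadata
#' (age, sex, body weight, injected dose at 3.7 MBq/kg). Defaults follow the
#' target study design: 16 diffuse lesions with margin widths U(3, 9) mm and
#' 7 circumscribed lesions with U(0, 1) mm. Phantoms are materialized lazily
#' with [generate_phantom()] on each row's `spec`.
#'
#' @param n_diffuse,n_circumscribed patients per group.
#' @param margin_width_range_diffuse,margin_width_range_circ length-2
#'   intervals (mm) for the uniform margin-width draws.
#' @param base_spec a [phantom_spec()] supplying every other parameter.
#' @param seed master seed; all randomness derives from it.
#' @return A tibble with one row per patient: `id`, `group`, `age`, `sex`,
#'   `margin_width`, `body_weight`, `injected_activity`, `seed` and a `spec`
#'   list-column of [phantom_spec()] objects.
#' @export
generate_cohort <- function(n_diffuse = 16L, n_circumscribed = 7L,
                            margin_width_range_diffuse = c(3, 9),
                            margin_width_range_circ = c(0, 1),
                            base_spec = phantom_spec(),
                            seed = 1L) {
  check_range <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] < 0 || r[2] < r[1])
      stop("`", nm, "` must be a valid nonnegative interval c(lo, hi)")
  }
  check_range(margin_width_range_diffuse, "margin_width_range_diffuse")
  check_range(margin_width_range_circ, "margin_width_range_circ")
  n_diffuse <- as.integer(n_diffuse); n_circumscribed <- as.integer(n_circumscribed)
  if (n_diffuse < 0L || n_circumscribed < 0L) stop("group sizes must be >= 0")
  n <- n_diffuse + n_circumscribed
  if (n == 0L) stop("cohort is empty")
  group <- c(rep("diffuse", n_diffuse), rep("circumscribed", n_circumscribed))

  meta <- .with_seed(seed, {
    widths <- c(stats::runif(n_diffuse, margin_width_range_diffuse[1],
                             margin_width_range_diffuse[2]),
                stats::runif(n_circumscribed, margin_width_range_circ[1],
                             margin_width_range_circ[2]))
    age <- round(c(stats::rnorm(n_diffuse, 40, 9),
                   stats::rnorm(n_circumscribed, 58, 16)))
    age <- pmin(pmax(age, 18), 85)
    sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.6, 0.4))
    weight <- round(pmin(pmax(stats::rnorm(n, 70, 10), 45), 120), 1)
    list(widths = widths, age = age, sex = sex, weight = weight)
  })

  specs <- purrr::map(seq_len(n), function(i) {
    s <- unclass(base_spec)
    s$margin_width <- meta$widths[i]
    s$body_weight <- meta$weight[i]
    s$injected_activity <- round(3.7 * meta$weight[i], 1)
    s$seed <- as.integer(seed + i)
    do.call(phantom_spec, s[setdiff(names(s), character(0))])
  })

  tibble::tibble(id = sprintf("P%02d", seq_len(n)),
                 group = group,
                 age = meta$age,
                 sex = meta$sex,
                 margin_width = meta$widths,
                 body_weight = meta$weight,
                 injected_activity = purrr::map_dbl(specs, "injected_activity"),
                 seed = purrr::map_int(specs, "seed"),
                 spec = specs)
}
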