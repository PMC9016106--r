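# shared per-lesion analysis core: reference ROIs -> ROI_MRI -> ROI_FBY -> metrics
analyze_volumes <- function(t1c, suv, tumor_center,
                            midline = midline_plane(),
                            exclusions = list(),
                            config = segmentation_config(),
                            verbose = FALSE) {
  stop_if_grid_mismatch(t1c, as_suv_image(suv), "t1c and suv")
  rr <- place_reference_rois(suv, tumor_center, midline, config)
  mri <- segment_mri(t1c, tumor_center, rr$mask, config)
  fby <- segment_fby(suv, rr$stats, tumor_center, exclusions, config)
  if (verbose)
    message(sprintf("  MRI threshold %.4g; FBY threshold %.4g (%.1f x Nmax %.4g)",
                    attr(mri, "threshold"), attr(fby, "threshold"),
                    config$fby_threshold_multiple, rr$stats$n_max))
  metrics <- lesion_metrics(suv, mri, fby, rr$stats)
  list(metrics = metrics,
       masks = list(reference = rr$mask, mri = mri, fby = fby,
                    margin = margin_region(fby, mri)),
       stats = rr$stats)
}

#' Analyze a single phantom in memory
#'
#' Runs the full segmentation and metric pipeline on a generated phantom:
#' contralateral reference spheres, contrast-enhancement ROI, metabolic ROI
#' (with the phantom's ground-truth exclusion mask applied when present) and
#' the per-lesion metric bundle.
#'
#' @param phantom output of [generate_phantom()].
#' @param config a [segmentation_config()].
#' @param verbose log the thresholds used.
#' @return A list with `metrics` (one-row tibble from [lesion_metrics()]),
#'   `masks` (reference/mri/fby/margin [binary_mask()]s) and `stats`
#'   (`reference_stats`).
#' @export
analyze_phantom <- function(phantom, config = segmentation_config(),
                            verbose = FALSE) {
  excl <- if (sum(phantom$truth$exclusion$values) > 0)
    list(phantom$truth$exclusion) else list()
  analyze_volumes(phantom$t1c, phantom$suv, phantom$spec$tumor_center,
                  midline = midline_plane(), exclusions = excl,
                  config = config, verbose = verbose)
}

#' Analyze a synthetic cohort in memory
#'
#' Materializes each phantom of a [generate_cohort()] manifest, analyzes it
#' with [analyze_phantom()] and binds the per-patient metric rows.
#'
#' @param cohort manifest tibble from [generate_cohort()].
#' @param config a [segmentation_config()].
#' @param verbose log per-patient thresholds.
#' @return A tibble of per-patient records: manifest metadata columns plus
#'   the [lesion_metrics()] columns; ready for [build_cohort_tables()].
#' @export
analyze_cohort <- function(cohort, config = segmentation_config(),
                           verbose = FALSE) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    ph <- generate_phantom(cohort$spec[[i]])
    res <- analyze_phantom(ph, config, verbose = verbose)
    dplyr::bind_cols(cohort[i, setdiff(names(cohort), "spec")], res$metrics)
  })
  dplyr::bind_rows(rows)
}

# ---- file-based pipeline ----------------------------------------------------

sidecar_path <- function(dir) file.path(dir, "sidecar.json")

write_sidecar <- function(dir, x) {
  jsonlite::write_json(x, sidecar_path(dir), auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

read_sidecar <- function(dir) {
  p <- sidecar_path(dir)
  if (!file.exists(p)) stop("missing patient sidecar: ", p)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

#' Write a synthetic cohort to disk
#'
#' Generates every phantom of a cohort manifest and writes, per patient, the
#' contrast-enhanced T1-like volume (`t1c.nii`), the PET volume as activity
#' concentration in kBq/mL (`pet.nii`, recovered from the SUV map through the
#' patient's injected dose and weight, so that the reading pipeline exercises
#' the SUV normalization), the ground-truth exclusion mask when present
#' (`exclusion.nii`), and a JSON sidecar with group, seeds, tumor position,
#' midline, weight and decay-corrected dose. A `manifest.csv` at the root
#' lists the patients. Deterministic: rerunning with the same seed rewrites
#' byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort manifest from [generate_cohort()].
#' @param compress write `.nii.gz` instead of plain `.nii`.
#' @return The manifest tibble (with a `dir` column), invisibly.
#' @export
run_simulate <- function(out_dir, cohort = generate_cohort(), compress = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (compress) ".nii.gz" else ".nii"
  dirs <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    pdir <- file.path(out_dir, row$id)
    dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
    ph <- generate_phantom(row$spec[[1]])
    write_volume(ph$t1c, file.path(pdir, paste0("t1c", ext)))
    act <- volume_image(ph$suv$image$values *
                          (ph$suv$injected_activity / ph$suv$body_weight),
                        ph$suv$image$spacing, ph$suv$image$origin)
    write_volume(act, file.path(pdir, paste0("pet", ext)))
    has_excl <- sum(ph$truth$exclusion$values) > 0
    if (has_excl)
      write_volume(ph$truth$exclusion, file.path(pdir, paste0("exclusion", ext)))
    write_sidecar(pdir, list(
      id = row$id, group = row$group, age = row$age, sex = row$sex,
      body_weight_kg = row$body_weight,
      injected_activity_mbq = row$injected_activity,
      pet_units = "kBq/mL",
      tumor_center_mm = row$spec[[1]]$tumor_center,
      midline = list(point = c(0, 0, 0), normal = c(1, 0, 0)),
      margin_width_mm = row$margin_width,
      seed = row$seed,
      files = list(t1c = paste0("t1c", ext), pet = paste0("pet", ext),
                   exclusion = if (has_excl) paste0("exclusion", ext) else NULL)))
    dirs[i] <- pdir
  }
  manifest <- dplyr::mutate(cohort[, setdiff(names(cohort), "spec")],
                            dir = cohort$id)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Analyze one patient directory
#'
#' Reads the T1 and PET volumes and the JSON sidecar from a patient
#' directory, converts the PET volume to SUV when it is stored as activity
#' concentration, resamples PET (and any exclusion mask) onto the T1 grid
#' through the sidecar's affine (identity when absent), runs the
#' reference-ROI / ROI_MRI / ROI_FBY segmentation, writes the masks and a
#' per-patient metrics row, and logs the thresholds used.
#'
#' @param patient_dir directory with `t1c.nii`, `pet.nii` and
#'   `sidecar.json` (as written by [run_simulate()]).
#' @param config a [segmentation_config()].
#' @param out_dir where to write masks and metrics; defaults to
#'   `patient_dir`.
#' @param write_masks write the four ROI masks as NIfTI files.
#' @param verbose log thresholds to the console.
#' @return The one-row metrics tibble (metadata + [lesion_metrics()]
#'   columns), invisibly.
#' @export
run_patient <- function(patient_dir, config = segmentation_config(),
                        out_dir = patient_dir, write_masks = TRUE,
                        verbose = TRUE) {
  sc <- read_sidecar(patient_dir)
  t1c_path <- file.path(patient_dir, sc$files$t1c)
  pet_path <- file.path(patient_dir, sc$files$pet)
  for (p in c(t1c_path, pet_path))
    if (!file.exists(p)) stop("missing input volume: ", p)
  t1c <- read_volume(t1c_path)
  pet <- read_volume(pet_path)

  if (identical(sc$pet_units, "kBq/mL")) {
    suv <- compute_suv(pet, sc$injected_activity_mbq, sc$body_weight_kg)
  } else {
    suv <- suv_map(pet, sc$injected_activity_mbq, sc$body_weight_kg)
  }
  tf <- if (!is.null(sc$affine)) {
    affine_transform(matrix(unlist(sc$affine$linear), 3, 3, byrow = TRUE),
                     unlist(sc$affine$translation))
  } else identity_affine()
  suv_img <- resample_to(suv$image, t1c, tf, mode = "intensity")
  suv <- suv_map(suv_img, suv$injected_activity, suv$body_weight)

  exclusions <- list()
  if (!is.null(sc$files$exclusion)) {
    ex <- read_volume(file.path(patient_dir, sc$files$exclusion))
    ex <- binary_mask((ex$values > 0.5) * 1L, ex)
    exclusions <- list(resample_to(ex, t1c, tf))
  }
  midline <- if (!is.null(sc$midline))
    midline_plane(unlist(sc$midline$point), unlist(sc$midline$normal))
  else midline_plane()

  if (verbose) message("patient ", sc$id)
  res <- analyze_volumes(t1c, suv, unlist(sc$tumor_center_mm),
                         midline = midline, exclusions = exclusions,
                         config = config, verbose = verbose)
  if (write_masks) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res$masks))
      write_volume(res$masks[[nm]], file.path(out_dir, paste0("roi_", nm, ".nii")))
  }
  meta <- tibble::tibble(id = sc$id, group = sc$group,
                         age = if (!is.null(sc$age)) sc$age else NA_real_,
                         sex = if (!is.null(sc$sex)) sc$sex else NA_character_)
  row <- dplyr::bind_cols(meta, res$metrics)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(row, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(row), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(row)
}

#' Analyze a cohort directory and build the group-comparison tables
#'
#' Runs [run_patient()] for every entry of `manifest.csv` under `data_dir`,
#' binds the per-patient rows, builds the cohort tables and writes
#' `metrics.csv` (all per-patient rows), `cohort_table.csv` (per-variable
#' summaries, concordance scores rounded to 3 decimals and volumes to 1) and
#' `tests.json` (test names, statistics, p-values, group sizes). Every
#' number in the cohort report is recomputable from `metrics.csv` alone.
#'
#' @param data_dir directory written by [run_simulate()] (or following the
#'   same layout).
#' @param config a [segmentation_config()].
#' @param out_dir report directory; defaults to `data_dir`.
#' @param verbose log per-patient thresholds.
#' @return The [build_cohort_tables()] result, invisibly.
#' @export
run_cohort <- function(data_dir, config = segmentation_config(),
                       out_dir = data_dir, verbose = TRUE) {
  mpath <- file.path(data_dir, "manifest.csv")
  if (!file.exists(mpath)) stop("missing cohort manifest: ", mpath)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  rows <- purrr::map(manifest$dir, function(d) {
    pd <- file.path(data_dir, d)
    if (!dir.exists(pd)) pd <- d   # manifests may carry absolute paths
    run_patient(pd, config, verbose = verbose)
  })
  records <- dplyr::bind_rows(rows)
  tabs <- build_cohort_tables(records)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(records, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  report <- tabs$summary
  score_vars <- c("overlap_volume", "dice")
  vol_vars <- c("volume_mri", "volume_fby")
  num_cols <- c("group1_mean", "group1_sd", "group2_mean", "group2_sd")
  for (cc in num_cols) {
    report[[cc]] <- ifelse(report$variable %in% vol_vars,
                           round(report[[cc]], 1),
                           round(report[[cc]], 3))
  }
  report$p_value <- round(report$p_value, 4)
  utils::write.csv(report, file.path(out_dir, "cohort_table.csv"),
                   row.names = FALSE)
  tests <- list(groups = tabs$groups, n = tabs$n,
                between_group = tabs$summary,
                paired = tabs$paired,
                sex = if (!is.null(tabs$sex))
                  list(p_value = tabs$sex$p_value,
                       counts = unclass(attr(tabs$sex, "counts"))) else NULL)
  jsonlite::write_json(tests, file.path(out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(tabs)
}
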