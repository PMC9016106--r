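test_that("reference spheres mirror the tumor across the midline and pool SUV", {
  img <- flat_image(0.04, c(41, 41, 41), spacing = c(2, 2, 2),
                    origin = c(-40, -40, -40))
  s <- suv_map(img, 259, 70)
  rr <- place_reference_rois(s, tumor_center = c(20, 10, 10))
  expect_equal(rr$stats$sphere_centers[1, ], c(-20, 10, 10))
  # constant field: Nmax = Nmean = the constant
  expect_equal(rr$stats$n_max, 0.04)
  expect_equal(rr$stats$n_mean, 0.04)
  expect_s3_class(rr$mask, "binary_mask")
  expect_gt(mask_count(rr$mask), 0)
  # all sphere centers on the opposite side of the midline
  expect_true(all(rr$stats$sphere_centers[, 1] < 0))

  # tumor on the midline is rejected
  expect_error(place_reference_rois(s, c(0, 10, 10)), "midline")
  # mirrored spheres outside the image are rejected
  expect_error(place_reference_rois(s, c(200, 0, 0)), "outside")
})

test_that("pooled Nmean recovers the background mean within Monte-Carlo error", {
  set.seed(42)
  d <- c(41, 41, 41)
  vals <- array(pmax(rnorm(prod(d), 0.037, 0.01), 0), d)
  img <- volume_image(vals, spacing = c(2, 2, 2), origin = c(-40, -40, -40))
  rr <- place_reference_rois(suv_map(img, 259, 70), c(20, 5, 0))
  n <- mask_count(rr$mask)
  se <- 0.01 / sqrt(n)
  expect_lt(abs(rr$stats$n_mean - 0.037), 3 * se)
  expect_gte(rr$stats$n_max, rr$stats$n_mean)
})

test_that("segment_mri matches a brute-force threshold + component oracle", {
  set.seed(5)
  d <- c(24, 24, 24)
  img <- volume_image(array(50 + rnorm(prod(d)), d))
  # enhancing sphere ~10 background sds above the mean
  ctr <- c(8, 12, 12)
  for (i in 1:24) for (j in 1:24) for (k in 1:24)
    if (sum((c(i, j, k) - ctr)^2) <= 9) img$values[i, j, k] <- 60
  normal <- binary_mask(
    (outer(outer((seq_len(24) - 18)^2, (seq_len(24) - 12)^2, `+`),
           (seq_len(24) - 12)^2, `+`) <= 16) * 1L, img)
  cfg <- segmentation_config()
  got <- segment_mri(img, seed = ctr - 1, normal_mask = normal, config = cfg)

  ref_vals <- img$values[normal$values == 1]
  thr <- mean(ref_vals) + 3 * sd(ref_vals)
  cand <- (img$values > thr) * 1L
  want <- oracle_fill_holes(oracle_component(cand, ctr, 26) * 1L)
  expect_identical(got$values, want)
  expect_equal(attr(got, "threshold"), thr)

  # seed in background is below the threshold
  expect_error(segment_mri(img, c(1, 1, 1), normal, cfg), "not above")
  expect_error(segment_mri(img, ctr - 1,
                           binary_mask(array(0L, d), img), cfg), "empty")
})

test_that("segment_mri with two bright blobs returns only the seeded one", {
  d <- c(20, 20, 20)
  img <- volume_image(array(10, d))
  img$values[3:5, 3:5, 3:5] <- 50       # blob A
  img$values[14:16, 14:16, 14:16] <- 50 # blob B
  normal <- binary_mask({
    m <- array(0L, d); m[8:12, 8:12, 8:12] <- 1L; m
  }, img)
  img$values[normal$values == 1] <- 10 + rnorm(sum(normal$values), 0, 0.1)
  got <- segment_mri(img, seed = c(3, 3, 3), normal_mask = normal)
  expect_true(all(got$values[3:5, 3:5, 3:5] == 1))
  expect_true(all(got$values[14:16, 14:16, 14:16] == 0))
})

test_that("segment_fby thresholds at the Nmax multiple and honors exclusions", {
  ph <- generate_phantom(small_spec(background_suv_sd = 0, noise_sd_mri = 0,
                                    seed = 3))
  ref <- structure(list(n_max = 0.116, n_mean = 0.037), class = "reference_stats")
  seed <- ph$spec$tumor_center

  got <- segment_fby(ph$suv, ref, seed)
  # brute-force oracle: threshold 0.348, strictly above, seeded component
  cand <- (ph$suv$image$values > 3 * 0.116) * 1L
  sv <- round((seed - ph$suv$image$origin) / ph$suv$image$spacing) + 1
  want <- oracle_fill_holes(oracle_component(cand, sv, 26) * 1L)
  expect_identical(got$values, want)
  expect_identical(got$values, ph$truth$enhancement$values)  # core at SUV 2.5

  # uniform low-uptake map: candidate set empty
  low <- suv_map(flat_image(0.05, c(8, 8, 8)), 259, 70)
  expect_error(segment_fby(low, ref, c(4, 4, 4)), "no voxel exceeds")

  # disconnected hot blob marked as exclusion never appears in the output
  ph2 <- generate_phantom(small_spec(background_suv_sd = 0, noise_sd_mri = 0,
                                     sinus = list(center = c(-10, -20, 0),
                                                  radius = 5, suv = 1.2),
                                     seed = 3))
  got2 <- segment_fby(ph2$suv, ref, seed,
                      exclusions = list(ph2$truth$exclusion))
  expect_identical(sum(got2$values & ph2$truth$exclusion$values), 0L)
  expect_identical(got2$values, ph2$truth$enhancement$values)
})

test_that("segment_fby output never intersects an exclusion inside the tumor", {
  ph <- generate_phantom(small_spec(background_suv_sd = 0, noise_sd_mri = 0,
                                    seed = 9))
  img <- ph$suv$image
  inner <- array(0L, dim(img$values))
  sv <- round((ph$spec$tumor_center - img$origin) / img$spacing) + 1
  inner[sv[1], sv[2], sv[3]] <- 1L   # exclusion at the tumor center voxel
  excl <- binary_mask(inner, img)
  seed_off <- ph$spec$tumor_center + c(4, 0, 0)  # seed elsewhere in the core
  got <- segment_fby(ph$suv, 0.116, seed_off, exclusions = list(excl))
  expect_identical(sum(got$values & excl$values), 0L)
})

test_that("segment_fby is scale invariant and monotone in the threshold multiple", {
  ph <- generate_phantom(small_spec(margin_width = 4, seed = 21))
  rr <- place_reference_rois(ph$suv, ph$spec$tumor_center)
  seed <- ph$spec$tumor_center
  base <- segment_fby(ph$suv, rr$stats, seed)

  # rescale the SUV map by 3: Nmax measured on the same map scales with it
  scaled_img <- volume_image(ph$suv$image$values * 3, ph$suv$image$spacing,
                             ph$suv$image$origin)
  scaled <- suv_map(scaled_img, ph$suv$injected_activity, ph$suv$body_weight)
  rr2 <- place_reference_rois(scaled, seed)
  expect_equal(rr2$stats$n_max, 3 * rr$stats$n_max)
  expect_identical(segment_fby(scaled, rr2$stats, seed)$values, base$values)

  # lowering the multiple never shrinks the mask
  lower <- segment_fby(ph$suv, rr$stats, seed,
                       config = segmentation_config(fby_threshold_multiple = 2.5))
  expect_true(all(lower$values >= base$values))
})

test_that("clean_mask keeps the seeded component and fills cavities", {
  ref <- flat_image(0, c(9, 9, 9))

  solid <- array(0L, c(9, 9, 9)); solid[3:7, 3:7, 3:7] <- 1L
  m <- binary_mask(solid, ref)
  out <- clean_mask(m, c(4, 4, 4))
  expect_identical(out$values, solid)

  # hollow 5x5x5 shell -> solid cube: the 27 interior voxels are filled
  shell <- solid
  shell[4:6, 4:6, 4:6] <- 0L
  out <- clean_mask(binary_mask(shell, ref), c(2, 2, 2))  # seed on the shell
  expect_identical(out$values, solid)
  expect_identical(sum(out$values) - sum(shell), 27L)
  expect_identical(out$values, oracle_fill_holes(shell))

  # two disjoint cubes, seed in A -> only A
  two <- array(0L, c(9, 9, 9))
  two[2:3, 2:3, 2:3] <- 1L
  two[6:8, 6:8, 6:8] <- 1L
  out <- clean_mask(binary_mask(two, ref), c(1, 1, 1))
  expect_identical(sum(out$values), 8L)
  expect_true(all(out$values[6:8, 6:8, 6:8] == 0))

  # idempotence on random masks
  set.seed(13)
  for (i in 1:5) {
    rm <- random_mask(ref, p = 0.4)
    seed_idx <- arrayInd(which(rm$values == 1)[1], dim(rm$values))
    once <- clean_mask(rm, as.numeric(seed_idx) - 1)
    twice <- clean_mask(once, as.numeric(seed_idx) - 1)
    expect_identical(twice$values, once$values)
  }

  expect_error(clean_mask(m, c(0, 0, 0)), "not set")
})

test_that("component extraction matches the oracle across connectivities", {
  set.seed(23)
  ref <- flat_image(0, c(10, 10, 10))
  for (conn in c(6L, 18L, 26L)) {
    rm <- random_mask(ref, p = 0.35)
    seed_idx <- arrayInd(which(rm$values == 1)[1], dim(rm$values))
    got <- clean_mask(rm, as.numeric(seed_idx) - 1, connectivity = conn)
    want <- oracle_fill_holes(oracle_component(rm$values, seed_idx, conn) * 1L)
    expect_identical(got$values, want)
  }
})
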