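test_that("summarize_mean_sd uses the n-1 denominator", {
  expect_equal(summarize_mean_sd(c(1, 1, 1))[c("mean", "sd")],
               list(mean = 1, sd = 0))
  s <- summarize_mean_sd(c(1, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-12)   # 1.4142, n-1 denominator
  s <- summarize_mean_sd(c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(s$mean, 5)
  expect_equal(round(s$sd, 4), 2.1381)
  expect_error(summarize_mean_sd(3), "at least 2")
})

test_that("rank-sum test is exact for small tie-free samples", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)                     # 2/20 enumerated layouts
  expect_equal(r$method, "exact")
  # symmetric under swapping the samples
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))$p_value, 0.1)
  # identical multisets: no location shift
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")

  set.seed(4)
  for (i in 1:10) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- round(runif(nx), 6); y <- round(runif(ny, 0.3, 1.3), 6)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_ranksum_p(x, y))
  }
})

test_that("normal approximation tracks the exact rank-sum p at n = 8 + 8", {
  set.seed(6)
  x <- rnorm(8); y <- rnorm(8, 0.8)
  p_exact <- wilcoxon_rank_sum(x, y, exact = TRUE)$p_value
  p_appr <- wilcoxon_rank_sum(x, y, exact = FALSE)$p_value
  expect_lt(abs(p_exact - p_appr), 0.02)
  expect_equal(p_exact, oracle_ranksum_p(x, y))
})

test_that("rank-sum p decreases with increasing separation", {
  set.seed(8)
  x <- rnorm(8)
  y0 <- x + abs(rnorm(8, 0.2, 0.1))   # already shifted upward
  ps <- vapply(c(0, 0.5, 1, 2, 4),
               function(dl) wilcoxon_rank_sum(x, y0 + dl)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("signed-rank test drops zeros and is exact for small samples", {
  x <- c(1.2, 2.1, 0.4, 3.3, 5.0, 2.2)
  r <- wilcoxon_signed_rank(x + 1, x)          # all differences +1
  expect_equal(r$p_value, 0.03125)             # 2 / 2^6 sign patterns
  expect_equal(r$method, "exact")

  # antisymmetric differences: p near 1
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  expect_gte(wilcoxon_signed_rank(x, y)$p_value, 0.8)

  set.seed(10)
  x <- rnorm(10); y <- x + rnorm(10, 0.3)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value, oracle_signedrank_p(x, y))

  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_error(wilcoxon_signed_rank(1:3, 1:2), "equal length")
})

test_that("Welch t-test matches the closed-form computation", {
  expect_equal(t_test_independent(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_lt(t_test_independent(c(1, 2, 3), c(101, 102, 103))$p_value, 0.001)

  set.seed(12)
  x <- rnorm(9, 0, 1); y <- rnorm(14, 0.7, 2)
  got <- t_test_independent(x, y)
  want <- oracle_welch(x, y)
  expect_equal(got$statistic, want$statistic)
  expect_equal(got$df, want$df)
  expect_equal(got$p_value, want$p_value)
  expect_error(t_test_independent(c(1, 2, 3), 2), "at least 2")
  expect_error(t_test_independent(c(1, 1, 1), c(2, 2, 2)), "degenerate")
})

test_that("Fisher exact test sums hypergeometric probabilities", {
  # the 10/6 vs 4/3 sex distribution
  expect_equal(fisher_exact(matrix(c(10, 6, 4, 3), 2))$p_value, 1.0)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / choose(10, 5))
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2))$p_value, 1)  # zero margin
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")

  set.seed(14)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 5), 2)
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-7)
  }
})

make_records <- function(n1 = 8, n2 = 6, seed = 1, shift = 0) {
  set.seed(seed)
  n <- n1 + n2
  tibble::tibble(
    id = sprintf("P%02d", 1:n),
    group = c(rep("diffuse", n1), rep("circumscribed", n2)),
    age = round(c(rnorm(n1, 40, 9), rnorm(n2, 58, 16))),
    sex = sample(c("male", "female"), n, TRUE),
    suv_max = rnorm(n, 2.5, 0.4),
    tn_ratio = rnorm(n, 22, 5),
    n_max = rnorm(n, 0.116, 0.02),
    n_mean = rnorm(n, 0.037, 0.008),
    suv_mean_mri = rnorm(n, 1.2, 0.2),
    suv_mean_fby = rnorm(n, 1.2, 0.2) - c(rep(shift, n1), rep(shift / 3, n2)),
    volume_mri = runif(n, 5, 40),
    volume_fby = runif(n, 5, 60),
    overlap_volume = runif(n, 0.98, 1),
    dice = c(runif(n1, 0.4, 0.8 + shift), runif(n2, 0.85, 0.95)),
    suv_mean_margin = rnorm(n, 0.65, 0.15),
    margin_over_nmax = rnorm(n, 5.5, 1.5),
    margin_defined = TRUE
  )
}

test_that("build_cohort_tables pairs each variable with its test", {
  rec <- make_records(shift = 0.25)
  tabs <- build_cohort_tables(rec)
  expect_s3_class(tabs, "cohort_tables")
  s <- tabs$summary
  expect_setequal(
    s$test[s$variable %in% c("dice", "overlap_volume",
                             "suv_mean_margin", "margin_over_nmax")],
    "Wilcoxon rank-sum")
  expect_setequal(
    s$test[s$variable %in% c("age", "suv_max", "volume_mri")],
    "Welch t-test")
  expect_true(all(s$p_value >= 0 & s$p_value <= 1))
  expect_equal(tabs$n, c(8L, 6L))
  expect_equal(tabs$groups, c("diffuse", "circumscribed"))
  expect_equal(nrow(tabs$paired), 2L)
  expect_false(is.null(tabs$sex))

  # summaries and tests equal a straight recomputation from the records
  d <- rec$dice[rec$group == "diffuse"]; c2 <- rec$dice[rec$group == "circumscribed"]
  row <- s[s$variable == "dice", ]
  expect_equal(row$group1_mean, mean(d))
  expect_equal(row$group1_sd, sd(d))
  expect_equal(row$p_value, wilcoxon_rank_sum(d, c2)$p_value)
  row <- s[s$variable == "age", ]
  expect_equal(row$p_value,
               t_test_independent(rec$age[rec$group == "diffuse"],
                                  rec$age[rec$group == "circumscribed"])$p_value)

  # tidy/glance interfaces
  td <- generics::tidy(tabs)
  expect_true(all(c("variable", "comparison", "p.value") %in% names(td)))
  gl <- generics::glance(tabs)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$dice_p, row_p <- s$p_value[s$variable == "dice"])
})

test_that("two identical groups give p-values at the null everywhere", {
  one <- make_records(n1 = 7, n2 = 0)[, ]
  one <- one[one$group == "diffuse", ]
  dup <- dplyr::bind_rows(dplyr::mutate(one, group = "diffuse"),
                          dplyr::mutate(one, group = "circumscribed",
                                        id = paste0(id, "b")))
  dup$suv_mean_fby <- dup$suv_mean_mri - 0.2   # keep the paired test defined
  tabs <- build_cohort_tables(dup)
  expect_true(all(tabs$summary$p_value >= 0.95, na.rm = TRUE))
})

test_that("degenerate cohorts surface clear errors", {
  rec <- make_records()
  # identical ROIs for every patient: no nonzero paired differences
  rec$suv_mean_fby <- rec$suv_mean_mri
  expect_error(build_cohort_tables(rec), "zero")
  # a group entirely absent
  rec2 <- make_records()
  rec2$group <- "diffuse"
  expect_error(build_cohort_tables(rec2), "both groups")
})
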