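#' Mean and sample standard deviation
#'
#' The `mean ± sd` summary used throughout the cohort tables; the standard
#' deviation uses the n-1 denominator.
#'
#' @param values numeric vector; `NA`s are dropped; at least 2 values needed.
#' @return A list with `mean`, `sd` and `n`.
#' @export
summarize_mean_sd <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("at least 2 values are required for a mean ± sd summary")
  list(mean = mean(values), sd = stats::sd(values), n = n)
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration when the combined sample size is at most 25 and there
#' are no ties; continuity-corrected normal approximation with tie correction
#' otherwise.
#'
#' @param x,y nonempty numeric vectors.
#' @param exact override the automatic exact/approximate choice (logical), or
#'   `NULL` for the default rule.
#' @return A list with `statistic` (the Mann-Whitney W for `x`), `p_value`
#'   and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (length(x) + length(y) <= 25L) && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic),
       p_value = min(1, ht$p.value),
       method = if (exact) "exact" else "normal approximation")
}

#' Wilcoxon signed-rank test for paired samples (two-sided)
#'
#' Zero differences are dropped before ranking (Wilcoxon's original
#' treatment). Small samples are handled exactly: for up to 16 nonzero
#' differences all sign patterns are enumerated directly (tied absolute
#' differences get average ranks, so ties are permitted); between 17 and 25
#' tie-free differences the exact signed-rank distribution is used. Larger or
#' tied samples beyond that fall back to the continuity-corrected normal
#' approximation.
#'
#' @param x,y paired numeric vectors of equal length; at least one nonzero
#'   difference required.
#' @param exact override the automatic choice, or `NULL` for the default.
#' @return A list with `statistic` (V), `p_value`, `n_nonzero` and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  dn <- d[d != 0]
  n <- length(dn)
  if (n == 0L) stop("all paired differences are zero")
  ties <- anyDuplicated(abs(dn)) > 0L
  if (is.null(exact)) exact <- n <= 25L && (!ties || n <= 16L)
  r <- rank(abs(dn))
  v_obs <- sum(r[dn > 0])
  if (exact && n <= 16L) {
    # direct enumeration of all 2^n sign assignments (tie-aware ranks)
    vs <- 0
    for (i in seq_len(n)) vs <- c(vs, vs + r[i])
    p <- min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
    method <- "exact"
  } else if (exact && !ties) {
    ht <- suppressWarnings(stats::wilcox.test(dn, exact = TRUE))
    p <- min(1, ht$p.value)
    method <- "exact"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(dn, exact = FALSE, correct = TRUE))
    p <- min(1, ht$p.value)
    method <- "normal approximation"
  }
  list(statistic = v_obs, p_value = p, n_nonzero = n, method = method)
}

#' Welch two-sample t-test (two-sided)
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
t_test_independent <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("degenerate variance in both groups")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value summing hypergeometric probabilities no larger than the
#' observed table's.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A list with `p_value`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("`table` must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  list(p_value = min(1, stats::fisher.test(table)$p.value))
}

# variable -> test pairing used by the cohort tables
.ttest_vars <- c("age", "suv_max", "tn_ratio", "n_max", "n_mean",
                 "suv_mean_mri", "suv_mean_fby", "volume_mri", "volume_fby")
.ranksum_vars <- c("overlap_volume", "dice", "suv_mean_margin", "margin_over_nmax")

#' Cohort-level group comparison tables
#'
#' Builds the machine-readable analog of the cohort characteristic tables:
#' per-variable `mean ± sd` by group with the matching two-group test
#' (Welch t-test for age, SUV metrics, reference values and volumes; Wilcoxon
#' rank-sum for the concordance scores and margin-region statistics; Fisher's
#' exact test for the sex distribution), plus the paired within-group
#' comparison of SUVmean under the contrast-enhancement ROI vs the metabolic
#' ROI by Wilcoxon signed-rank. Margin variables are summarized over patients
#' with a nonempty margin only. No multiple-testing correction is applied.
#'
#' @param records tibble of per-patient rows: a `group` column with exactly
#'   two levels represented, metric columns as produced by
#'   [lesion_metrics()], and optionally `age` and `sex`.
#' @param groups character vector of length 2 fixing the group order;
#'   defaults to putting `"diffuse"` first when present.
#' @return An object of class `cohort_tables`: a list with `summary` (one row
#'   per variable: group means/sds/ns, test name, statistic, p-value),
#'   `paired` (signed-rank rows per group), `sex` (Fisher row, when a `sex`
#'   column exists) and `records`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
build_cohort_tables <- function(records, groups = NULL) {
  records <- tibble::as_tibble(records)
  if (!"group" %in% names(records)) stop("`records` must have a `group` column")
  present <- unique(as.character(records$group))
  if (is.null(groups)) {
    groups <- if ("diffuse" %in% present)
      c("diffuse", setdiff(present, "diffuse")) else sort(present)
  }
  if (length(groups) != 2L || !all(groups %in% present))
    stop("both groups must be represented in `records`; found: ",
         paste(present, collapse = ", "))
  g1 <- records[records$group == groups[1], , drop = FALSE]
  g2 <- records[records$group == groups[2], , drop = FALSE]

  vars <- intersect(c(.ttest_vars, .ranksum_vars), names(records))
  rows <- purrr::map(vars, function(v) {
    x <- g1[[v]][!is.na(g1[[v]])]
    y <- g2[[v]][!is.na(g2[[v]])]
    if (length(x) < 2L || length(y) < 2L) {
      # e.g. margin statistics when a group has (almost) no nonempty margins
      return(tibble::tibble(variable = v,
                            group1_mean = if (length(x)) mean(x) else NA_real_,
                            group1_sd = NA_real_, group1_n = length(x),
                            group2_mean = if (length(y)) mean(y) else NA_real_,
                            group2_sd = NA_real_, group2_n = length(y),
                            test = NA_character_, statistic = NA_real_,
                            p_value = NA_real_))
    }
    s1 <- summarize_mean_sd(x); s2 <- summarize_mean_sd(y)
    if (v %in% .ranksum_vars) {
      tst <- wilcoxon_rank_sum(x, y)
      test_name <- "Wilcoxon rank-sum"
    } else {
      # a variable can be degenerate (e.g. constant in both groups on
      # noise-free phantoms); report the summary with an undefined test
      tst <- tryCatch(t_test_independent(x, y),
                      error = function(e) list(statistic = NA_real_,
                                               p_value = NA_real_))
      test_name <- "Welch t-test"
    }
    tibble::tibble(variable = v,
                   group1_mean = s1$mean, group1_sd = s1$sd, group1_n = s1$n,
                   group2_mean = s2$mean, group2_sd = s2$sd, group2_n = s2$n,
                   test = test_name,
                   statistic = tst$statistic,
                   p_value = tst$p_value)
  })
  summary_tbl <- dplyr::bind_rows(rows)

  paired_tbl <- NULL
  if (all(c("suv_mean_mri", "suv_mean_fby") %in% names(records))) {
    paired_tbl <- purrr::map(groups, function(g) {
      sub <- records[records$group == g, , drop = FALSE]
      tst <- tryCatch(
        wilcoxon_signed_rank(sub$suv_mean_mri, sub$suv_mean_fby),
        error = function(e) stop("signed-rank test (suv_mean_mri vs suv_mean_fby, group '",
                                 g, "'): ", conditionMessage(e), call. = FALSE))
      tibble::tibble(group = g, comparison = "suv_mean_mri vs suv_mean_fby",
                     n = nrow(sub), statistic = tst$statistic,
                     p_value = tst$p_value)
    })
    paired_tbl <- dplyr::bind_rows(paired_tbl)
  }

  sex_tbl <- NULL
  if ("sex" %in% names(records)) {
    counts <- table(factor(as.character(records$sex)),
                    factor(as.character(records$group), levels = groups))
    if (nrow(counts) == 2L) {
      ft <- fisher_exact(as.matrix(counts))
      sex_tbl <- tibble::tibble(variable = "sex", test = "Fisher exact",
                                p_value = ft$p_value)
      attr(sex_tbl, "counts") <- as.matrix(counts)
    }
  }

  structure(list(summary = summary_tbl, paired = paired_tbl, sex = sex_tbl,
                 records = records, groups = groups,
                 n = c(nrow(g1), nrow(g2))),
            class = "cohort_tables")
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat(sprintf("<cohort_tables> %s (n = %d) vs %s (n = %d)\n",
              x$groups[1], x$n[1], x$groups[2], x$n[2]))
  print(x$summary, n = Inf)
  if (!is.null(x$paired)) {
    cat("\nPaired comparisons (Wilcoxon signed-rank):\n")
    print(x$paired)
  }
  if (!is.null(x$sex)) {
    cat("\nSex distribution (Fisher exact): p =",
        format(x$sex$p_value, digits = 4), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort_tables object
#'
#' @param x a `cohort_tables` object.
#' @param ... unused.
#' @return A tibble with one row per comparison (between-group, paired and
#'   categorical), with columns `variable`, `comparison`, `test`,
#'   `statistic`, `p.value` and the group summaries where applicable.
#' @export
tidy.cohort_tables <- function(x, ...) {
  out <- dplyr::mutate(x$summary, comparison = "between-group",
                       .after = "variable")
  out <- dplyr::rename(out, p.value = "p_value")
  if (!is.null(x$paired)) {
    p <- tibble::tibble(variable = "suv_mean", comparison = paste0("paired (", x$paired$group, ")"),
                        test = "Wilcoxon signed-rank",
                        statistic = x$paired$statistic,
                        p.value = x$paired$p_value)
    out <- dplyr::bind_rows(out, p)
  }
  if (!is.null(x$sex)) {
    out <- dplyr::bind_rows(out,
      tibble::tibble(variable = "sex", comparison = "between-group",
                     test = "Fisher exact", statistic = NA_real_,
                     p.value = x$sex$p_value))
  }
  out
}

#' One-row summary of a cohort comparison
#'
#' @param x a `cohort_tables` object.
#' @param ... unused.
#' @return A one-row tibble: group sizes, mean DICE and overlap volume per
#'   group, and the rank-sum p-values for both concordance scores.
#' @export
glance.cohort_tables <- function(x, ...) {
  pick <- function(v, col) {
    r <- x$summary[x$summary$variable == v, ]
    if (nrow(r) == 1L) r[[col]] else NA_real_
  }
  tibble::tibble(
    group1 = x$groups[1], group2 = x$groups[2],
    n_group1 = x$n[1], n_group2 = x$n[2],
    dice_group1 = pick("dice", "group1_mean"),
    dice_group2 = pick("dice", "group2_mean"),
    dice_p = pick("dice", "p_value"),
    overlap_group1 = pick("overlap_volume", "group1_mean"),
    overlap_group2 = pick("overlap_volume", "group2_mean"),
    overlap_p = pick("overlap_volume", "p_value")
  )
}
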