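# Independent oracles used to cross-check the package implementations.
# Everything here is deliberately brute-force and shares no code with R/.

# connected component of `values` (0/1 array) containing seed (i,j,k),
# by repeated neighbor growth until a fixed point
oracle_component <- function(values, seed_ijk, connectivity = 26) {
  d <- dim(values)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(offs))
  lim <- c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)]
  offs <- offs[s > 0 & s <= lim, , drop = FALSE]
  comp <- array(FALSE, d)
  comp[seed_ijk[1], seed_ijk[2], seed_ijk[3]] <- TRUE
  repeat {
    grown <- comp
    sub <- arrayInd(which(comp), d)
    for (r in seq_len(nrow(offs))) {
      nb <- sweep(sub, 2, offs[r, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      grown[lin[values[lin] == 1]] <- TRUE
    }
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# fill enclosed cavities: flood the 6-connected background from the border
oracle_fill_holes <- function(values) {
  d <- dim(values)
  outside <- array(FALSE, d)
  sub <- arrayInd(which(values == 0), d)
  on_border <- sub[, 1] == 1 | sub[, 1] == d[1] | sub[, 2] == 1 |
    sub[, 2] == d[2] | sub[, 3] == 1 | sub[, 3] == d[3]
  start <- sub[on_border, , drop = FALSE]
  outside[start[, 1] + d[1] * (start[, 2] - 1) + d[1] * d[2] * (start[, 3] - 1)] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  repeat {
    grown <- outside
    sub <- arrayInd(which(outside), d)
    for (r in 1:6) {
      nb <- sweep(sub, 2, offs[r, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      grown[lin[values[lin] == 0]] <- TRUE
    }
    if (identical(grown, outside)) break
    outside <- grown
  }
  (values == 1 | !outside) * 1L
}

# exact two-sided rank-sum p by enumerating all choose(nx+ny, nx) assignments
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  N <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(N, nx)
  ws <- apply(combs, 2, function(ix) sum(r[ix])) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_signedrank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# two-sided Fisher p: sum of hypergeometric probabilities <= observed
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Welch t-test from the closed-form expressions
oracle_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# random binary mask on a reference grid, with a guaranteed set-voxel count
random_mask <- function(ref, p = 0.3, min_set = 1L) {
  d <- dim(ref$values)
  v <- array(as.integer(stats::runif(prod(d)) < p), d)
  while (sum(v) < min_set) v[sample(prod(d), 1)] <- 1L
  binary_mask(v, ref)
}

# small uniform image for grid-level tests
flat_image <- function(value = 0, d = c(8, 8, 8), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  volume_image(array(value, d), spacing, origin)
}

# compact phantom spec used by unit tests (the full-size defaults are
# exercised in the acceptance tests)
small_spec <- function(...) {
  args <- list(grid_shape = c(48L, 48L, 48L), spacing = c(2, 2, 2),
               brain_radius = 36, tumor_center = c(15, 3, 0),
               core_radius = 7)
  args <- utils::modifyList(args, list(...))
  do.call(phantom_spec, args)
}
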