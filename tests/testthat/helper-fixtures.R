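# Small in-code fixtures and independent oracles used across test files.

# beta matrix from a plain matrix, generating probe/sample ids as needed
make_bm <- function(b, dp = NULL) {
  if (is.null(rownames(b))) rownames(b) <- sprintf("cg%08d", seq_len(nrow(b)))
  if (is.null(colnames(b))) colnames(b) <- sprintf("s%03d", seq_len(ncol(b)))
  if (!is.null(dp)) dimnames(dp) <- dimnames(b)
  beta_matrix(b, dp)
}

# metadata with n_strict strict rows and n_relaxed - n_strict relaxed-only
make_tiered_meta <- function(n_strict = 31, n_relaxed = 48) {
  n <- n_relaxed
  sample_metadata(
    sample_id = sprintf("d%03d", seq_len(n)),
    age_years = seq(0.25, 20, length.out = n),
    confidence_tier = rep(c("strict", "relaxed_only"),
                          c(n_strict, n - n_strict)))
}

# brute-force Pearson r via the covariance formula, no stats::cor
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force two-sided rank-sum p by enumerating group assignments
oracle_ranksum <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  rk <- rank(c(x, y))
  u_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * (n - nx) / 2
  sets <- combn(n, nx)
  u_all <- apply(sets, 2, function(ix) sum(rk[ix]) - nx * (nx + 1) / 2)
  list(W = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# brute-force two-sided signed-rank p by enumerating sign patterns
oracle_signrank <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  if (n == 0) return(list(V = 0, p = 1))
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  mu <- sum(rk) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% rk)
  list(V = v_obs, p = mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9))
}

# dense grid minimization of the elastic-net objective over coefficient
# space (<= 3 predictors); returns the minimum objective on the grid
oracle_enet_grid_min <- function(x, y, lambda, alpha, lim = 3, step = 0.05) {
  vals <- seq(-lim, lim, by = step)
  p <- ncol(x)
  grids <- do.call(expand.grid, rep(list(vals), p))
  best <- Inf
  for (i in seq_len(nrow(grids))) {
    b <- as.numeric(grids[i, ])
    b0 <- mean(y - x %*% b)  # intercept unpenalized: closed form given b
    obj <- enet_objective(x, y, b0, b, lambda, alpha)
    if (obj < best) best <- obj
  }
  best
}
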