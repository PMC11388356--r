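# MCMC convergence diagnostics: rank-normalized split R-hat and bulk ESS
# (Vehtari, Gelman, Simpson, Carpenter & Buerkner 2021 conventions).

split_chains <- function(mat) {
  # mat: iterations x chains -> iterations/2 x (2*chains)
  n <- nrow(mat)
  half <- n %/% 2L
  if (half < 2L) return(mat)
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1L):n, , drop = FALSE])
}

rank_normalize <- function(mat) {
  r <- rank(as.vector(mat), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(mat))
}

basic_rhat <- function(mat) {
  m <- ncol(mat)
  n <- nrow(mat)
  if (m < 2L || n < 2L) return(NA_real_)
  chain_means <- colMeans(mat)
  chain_vars <- apply(mat, 2, stats::var)
  W <- mean(chain_vars)
  B <- n * stats::var(chain_means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

rhat_value <- function(mat) {
  # split, then max of bulk (rank-normalized) and tail (folded) R-hat
  sp <- split_chains(mat)
  if (stats::sd(as.vector(sp)) == 0) return(NA_real_)
  bulk <- basic_rhat(rank_normalize(sp))
  folded <- basic_rhat(rank_normalize(abs(sp - stats::median(sp))))
  max(bulk, folded, na.rm = TRUE)
}

chain_autocov <- function(v, max_lag) {
  n <- length(v)
  v <- v - mean(v)
  vapply(0:max_lag, function(lag) {
    sum(v[seq_len(n - lag)] * v[(1 + lag):n]) / n
  }, numeric(1))
}

ess_value <- function(mat) {
  sp <- split_chains(mat)
  if (stats::sd(as.vector(sp)) == 0) return(NA_real_)
  z <- rank_normalize(sp)
  n <- nrow(z)
  m <- ncol(z)
  max_lag <- min(n - 1L, 250L)
  acov <- sapply(seq_len(m), function(j) chain_autocov(z[, j], max_lag))
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + stats::var(colMeans(z))
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer initial monotone positive sequence on paired sums
  tau_sum <- 0
  prev_pair <- Inf
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau_sum <- tau_sum + pair
    prev_pair <- pair
    t <- t + 2L
  }
  tau <- -1 + 2 * tau_sum  # paired-sum estimate incl. the lag-0 term
  ess <- n * m / max(tau, 1 / (n * m))
  min(ess, n * m)
}

mcmc_diagnostics <- function(draws) {
  pn <- dimnames(draws)[[3]]
  rhat <- ess <- rep(NA_real_, length(pn))
  for (i in seq_along(pn)) {
    mat <- draws[, , i, drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1L)
    rhat[i] <- rhat_value(mat)
    ess[i] <- ess_value(mat)
  }
  data.frame(parameter = pn, rhat = rhat, ess_bulk = ess)
}
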