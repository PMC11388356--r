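# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, textbook formulas, enumeration.

# Term-by-term log posterior, one density call per observation / cell /
# parameter. Expects data with explicit group (1..4) and replicate columns.
oracle_log_posterior <- function(params, data, spec) {
  y <- data$siderophore
  g <- data$group
  if (any(params$alpha < 0) || any(params$sigma <= 0) ||
      any(params$tau <= 0)) {
    return(-Inf)
  }
  # within-group replicate re-indexing, mirroring the documented contract
  k <- integer(length(y))
  for (j in sort(unique(g))) {
    labs <- data$replicate[g == j]
    k[g == j] <- match(labs, sort(unique(labs)))
  }
  cells <- unique(data.frame(g = g, k = k))
  cells <- cells[order(cells$g, cells$k), ]
  lam <- if (is.matrix(params$lambda)) {
    params$lambda[cbind(cells$g, cells$k)]
  } else params$lambda
  lp <- 0
  for (i in seq_along(y)) {
    ci <- which(cells$g == g[i] & cells$k == k[i])
    sd_i <- params$sigma[spec$vargroup[g[i]]]
    lp <- lp + dnorm(y[i], lam[ci], sd_i, log = TRUE)
  }
  for (ci in seq_len(nrow(cells))) {
    j <- cells$g[ci]
    nu_j <- params$alpha[spec$X1[j]] + params$beta[spec$X1[j]] * spec$X2[j]
    lp <- lp + dnorm(lam[ci], nu_j, params$tau[j], log = TRUE)
  }
  for (t in 1:2) {
    lp <- lp + log(2) + dnorm(params$alpha[t], 0, spec$prior_alpha_sd,
                              log = TRUE)
    lp <- lp + dnorm(params$beta[t], 0, spec$beta_sd, log = TRUE)
  }
  for (v in seq_along(params$sigma)) {
    lp <- lp + dexp(params$sigma[v], rate = spec$rate_sigma, log = TRUE)
  }
  for (j in 1:4) {
    lp <- lp + dexp(params$tau[j], rate = spec$rate_tau, log = TRUE)
  }
  lp
}

# small random dataset covering all four groups
random_small_data <- function(n = 10L, n_rep = 2L) {
  g <- c(1:4, sample(1:4, n - 4L, replace = TRUE))
  data.frame(group = g,
             replicate = sample.int(n_rep, n, replace = TRUE),
             siderophore = rnorm(n, 0.5, 0.2))
}

random_params <- function(data, spec) {
  g <- data$group
  k <- integer(nrow(data))
  for (j in sort(unique(g))) {
    labs <- data$replicate[g == j]
    k[g == j] <- match(labs, sort(unique(labs)))
  }
  n_cells <- nrow(unique(data.frame(g, k)))
  list(alpha = runif(2, 0, 1), beta = runif(2, -0.2, 0.2),
       sigma = runif(spec$n_sigma, 0.02, 0.3), tau = runif(4, 0.02, 0.2),
       lambda = rnorm(n_cells, 0.5, 0.2))
}

# midrank Spearman by first principles
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  list(rho = rho, S = sum((rx - ry)^2))
}

# least squares through the normal equations on the 2x2 dummy design
oracle_factorial_ls <- function(y, a, b) {
  a <- as.integer(factor(a)) - 1L
  b <- as.integer(factor(b)) - 1L
  X <- cbind(1, a, b, a * b)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# shortest HPD window by full enumeration
oracle_hpd <- function(x, mass = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    if (xs[i + m - 1] - xs[i] < best[2] - best[1]) {
      best <- c(xs[i], xs[i + m - 1])
    }
  }
  best
}

# a minimal hand-built fit object for contrast algebra tests
fake_fit <- function(alpha1, alpha2, beta1, beta2,
                     spec = model_spec("single")) {
  S <- length(alpha1)
  pn <- c("alpha[1]", "alpha[2]", "beta[1]", "beta[2]", "sigma[1]",
          paste0("tau[", 1:4, "]"))
  arr <- array(NA_real_, dim = c(S, 1, length(pn)),
               dimnames = list(NULL, NULL, pn))
  arr[, 1, "alpha[1]"] <- alpha1
  arr[, 1, "alpha[2]"] <- alpha2
  arr[, 1, "beta[1]"] <- beta1
  arr[, 1, "beta[2]"] <- beta2
  arr[, 1, "sigma[1]"] <- 0.1
  for (j in 1:4) arr[, 1, paste0("tau[", j, "]")] <- 0.02
  structure(list(draws = arr, spec = spec, chains = 1L, iterations = S),
            class = "sidero_fit")
}
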