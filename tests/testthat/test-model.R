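test_that("log_posterior equals the term-by-term oracle", {
  set.seed(101)
  for (ds in 1:5) {
    d <- random_small_data(n = 10L)
    for (vs in c("per_group", "by_isolate_type", "single")) {
      spec <- model_spec(vs)
      for (r in 1:4) {
        p <- random_params(d, spec)
        expect_equal(log_posterior(p, d, spec),
                     oracle_log_posterior(p, d, spec), tolerance = 1e-9)
      }
    }
  }
})

test_that("log_posterior likelihood term and support handling", {
  # one observation per group with y = lambda and all SDs 1:
  # each likelihood term is -log(2*pi)/2
  d <- data.frame(group = 1:4, replicate = 1, siderophore = c(1, 2, 3, 4))
  spec <- model_spec("per_group")
  p <- list(alpha = c(0.5, 0.5), beta = c(0, 0), sigma = rep(1, 4),
            tau = rep(1, 4), lambda = c(1, 2, 3, 4))
  lp <- log_posterior(p, d, spec, by_term = TRUE)
  expect_equal(unname(attr(lp, "terms")["loglik"]), 4 * (-0.5 * log(2 * pi)))
  # support violations
  p_bad <- p
  p_bad$sigma[2] <- -0.1
  expect_identical(log_posterior(p_bad, d, spec), -Inf)
  expect_error(log_posterior(p_bad, d, spec, on_invalid = "error"),
               "support")
  p_bad2 <- p
  p_bad2$alpha[1] <- -0.2
  expect_identical(log_posterior(p_bad2, d, spec), -Inf)
})

test_that("alternative prior readings rescale the spec correctly", {
  s1 <- model_spec(prior_beta_sd = 0.25)
  s2 <- model_spec(prior_beta_sd = 0.25, beta_prior_as_variance = TRUE)
  expect_equal(s1$beta_sd, 0.25)
  expect_equal(s2$beta_sd, 0.5)
  s3 <- model_spec(exp_prior_as_rate = TRUE)
  expect_equal(s3$rate_sigma, 0.2)
  expect_equal(model_spec()$rate_sigma, 5)
})

test_that("hpd_interval matches enumeration and behaves on known shapes", {
  x <- as.numeric(1:100)
  got <- hpd_interval(x, 0.95)
  expect_equal(got[2] - got[1], 94)
  expect_equal(got, oracle_hpd(x, 0.95))
  expect_equal(got, c(1, 95))  # left-most optimal window
  set.seed(14)
  for (i in 1:10) {
    z <- rgamma(500, shape = 2)
    expect_equal(hpd_interval(z, 0.9), oracle_hpd(z, 0.9))
  }
  # symmetric unimodal: HPD ~ equal-tailed
  z <- rnorm(1e5)
  h <- hpd_interval(z)
  q <- quantile(z, c(0.025, 0.975))
  expect_lt(max(abs(h - q)), 0.06)
  # degenerate sample
  expect_equal(hpd_interval(rep(3, 200)), c(3, 3))
  expect_error(hpd_interval(rnorm(50)), "at least 100")
})

test_that("sampler is seed-deterministic and respects parameter support", {
  cfg <- synthetic_config(seed = 31, n_replicates = 3, n_isolates = 6,
                          dropout_prob = 0)
  d <- simulate_siderophore(cfg)
  f1 <- suppressWarnings(sample_posterior(d, chains = 2, iterations = 60,
                                          warmup = 40, seed = 5))
  f2 <- suppressWarnings(sample_posterior(d, chains = 2, iterations = 60,
                                          warmup = 40, seed = 5))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(sample_posterior(d, chains = 2, iterations = 60,
                                          warmup = 40, seed = 6))
  expect_false(identical(f1$draws, f3$draws))
  pn <- dimnames(f1$draws)[[3]]
  expect_true(all(f1$draws[, , grep("^sigma|^tau", pn)] > 0))
  expect_true(all(f1$draws[, , grep("^alpha", pn)] >= 0))
  expect_equal(nrow(f1$diagnostics), length(pn))
})

test_that("non-convergence is flagged, not silent", {
  # two chains that cannot agree: white noise vs shifted white noise
  m_ok <- cbind(rnorm(1000), rnorm(1000), rnorm(1000), rnorm(1000))
  expect_lt(siderotrait:::rhat_value(m_ok), 1.01)
  m_bad <- cbind(rnorm(500), rnorm(500) + 3)
  expect_gt(siderotrait:::rhat_value(m_bad), 1.2)
})

test_that("fixed-sigma/tau reduction matches the conjugate normal update", {
  cfg <- synthetic_config(seed = 41, n_replicates = 4, dropout_prob = 0)
  d <- simulate_siderophore(cfg)
  spec <- model_spec()
  fx <- list(alpha = c(0.5, 0.7), beta = c(0.04, -0.04),
             sigma = c(0.1, 0.07, 0.03, 0.035), tau = rep(0.05, 4))
  f <- sample_posterior(d, spec, chains = 2, iterations = 1500, warmup = 100,
                        seed = 3, fix = fx)
  lay <- group_layout()
  nu <- fx$alpha[lay$X1] + fx$beta[lay$X1] * lay$X2
  pn <- dimnames(f$draws)[[3]]
  for (nm in grep("^lambda", pn, value = TRUE)) {
    jk <- as.integer(strsplit(gsub("lambda\\[|\\]", "", nm), ",")[[1]])
    sel <- d$group == jk[1] &
      match(d$replicate, sort(unique(d$replicate[d$group == jk[1]]))) ==
        jk[2]
    yb <- mean(d$siderophore[sel])
    n <- sum(sel)
    prec <- n / fx$sigma[jk[1]]^2 + 1 / fx$tau[jk[1]]^2
    m_post <- (n * yb / fx$sigma[jk[1]]^2 + nu[jk[1]] / fx$tau[jk[1]]^2) /
      prec
    v <- as.vector(f$draws[, , nm])
    expect_equal(mean(v), m_post, tolerance = 6 / sqrt(length(v)) *
                   sqrt(1 / prec) / max(abs(m_post), 1e-12))
    expect_equal(sd(v), sqrt(1 / prec), tolerance = 0.1)
  }
})

test_that("MAP lands at the prior mode for uninformed directions", {
  # no group carries copper: beta is prior-dominated, MAP beta = 0
  spec0 <- model_spec(X2 = c(0L, 0L, 0L, 0L))
  set.seed(51)
  d <- data.frame(group = rep(1:4, each = 12),
                  replicate = rep(rep(1:3, each = 4), 4),
                  siderophore = rnorm(48, 0.5, 0.1))
  m <- map_estimate(d, spec0, restarts = 4, seed = 2)
  expect_lt(max(abs(m$params$beta)), 1e-4)
})

test_that("MAP beats a 1000-draw random search on a tiny dataset", {
  set.seed(52)
  d <- data.frame(group = rep(1:4, each = 4),
                  replicate = rep(rep(1:2, each = 2), 4),
                  siderophore = rnorm(16, 0.6, 0.1))
  spec <- model_spec()
  m <- map_estimate(d, spec, restarts = 6, seed = 3)
  lp_map <- log_posterior(m$params, d, spec)
  pre_cells <- 8L
  best_rand <- -Inf
  for (i in 1:1000) {
    p <- list(alpha = runif(2, 0, 1.5), beta = runif(2, -0.5, 0.5),
              sigma = runif(4, 0.01, 0.5), tau = runif(4, 0.01, 0.5),
              lambda = rnorm(pre_cells, 0.6, 0.3))
    best_rand <- max(best_rand, log_posterior(p, d, spec))
  }
  expect_gt(lp_map, best_rand)
})

test_that("MAP approaches the truth on a large well-identified simulation", {
  cfg <- synthetic_config(seed = 61, n_isolates = 200, n_replicates = 12,
                          dropout_prob = 0)
  d <- simulate_siderophore(cfg)  # 9600 isolates
  m <- map_estimate(d, model_spec(), restarts = 3, seed = 4)
  expect_lt(max(abs(m$params$alpha - cfg$alpha)), 0.03)
  expect_lt(max(abs(m$params$beta - cfg$beta)), 0.03)
  expect_lt(max(abs(m$params$sigma - cfg$sigma)), 0.01)
})

test_that("derived contrasts honor their algebraic identities", {
  set.seed(71)
  S <- 500
  b1 <- rnorm(S, 0.05, 0.02)
  f <- fake_fit(alpha1 = rnorm(S, 0.5, 0.02), alpha2 = rnorm(S, 0.7, 0.02),
                beta1 = b1, beta2 = -b1)
  ct <- derived_contrasts(f)
  # beta1 = -beta2: combined effect degenerate at 0
  cmb <- ct[ct$name == "combined_effect", ]
  expect_equal(cmb$estimate, 0, tolerance = 1e-12)
  expect_equal(cmb$hpd_low, 0)
  expect_equal(cmb$hpd_high, 0)
  # (diff without copper) - (diff with copper) == beta1 - beta2 per draw
  a1 <- as.vector(f$draws[, , "alpha[1]"])
  a2 <- as.vector(f$draws[, , "alpha[2]"])
  b2 <- as.vector(f$draws[, , "beta[2]"])
  lhs <- (a2 - a1) - ((a2 + b2) - (a1 + b1))
  expect_equal(lhs, b1 - b2)
  red <- ct[ct$name == "copper_reduction_of_diff", ]
  expect_equal(unname(c(red$hpd_low, red$hpd_high)),
               unname(hpd_interval(b1 - b2)))
  # sigma contrasts only exist for the per-group structure
  expect_false(any(grepl("sigma", ct$name)))
})

test_that("posterior recovery works end to end on one paper-scale run", {
  cfg <- synthetic_config(seed = 81, dropout_prob = 0)
  d <- simulate_siderophore(cfg)
  f <- sample_posterior(d, model_spec(), chains = 2, iterations = 800,
                        warmup = 600, seed = 9)
  s <- posterior_summary(f)
  rownames(s) <- s$parameter
  for (t in 1:2) {
    a <- s[sprintf("alpha[%d]", t), ]
    expect_lt(abs(a$mean - cfg$alpha[t]), 0.06)
  }
  for (j in 1:4) {
    sg <- s[sprintf("sigma[%d]", j), ]
    expect_true(sg$hpd_low < cfg$sigma[j] * 1.25 &&
                  sg$hpd_high > cfg$sigma[j] * 0.8)
  }
  m <- map_estimate(d, model_spec(), restarts = 4, seed = 9, fit = f)
  ct <- derived_contrasts(f, map = m)
  expect_equal(ct$estimate[ct$name == "type_diff_no_copper"],
               unname(m$estimates["alpha[2]"] - m$estimates["alpha[1]"]))
  expect_true(all(ct$hpd_low < ct$hpd_high))
})
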