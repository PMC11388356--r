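test_that("synthetic_config validates fields by name", {
  expect_s3_class(synthetic_config(seed = 1), "sidero_config")
  expect_error(synthetic_config(dropout_prob = 1), "dropout_prob")
  expect_error(synthetic_config(tau = c(-1, 0, 0, 0)), "tau")
  expect_error(synthetic_config(alpha = 1), "alpha")
  expect_error(synthetic_config(n_replicates = 0), "n_replicates")
  expect_error(synthetic_config(a_ref = 0), "a_ref")
})

test_that("generate_design lays out the factorial and is seed-stable", {
  cfg <- synthetic_config(seed = 3, dropout_prob = 0)
  d <- generate_design(cfg)
  expect_equal(nrow(d), 4 * 6 * 24)
  expect_equal(as.integer(table(d$group)), rep(144L, 4))
  expect_equal(length(unique(d$microcosm_id)), 12)  # coculture microcosms
  expect_identical(d, generate_design(cfg))
  d2 <- generate_design(synthetic_config(seed = 4, dropout_prob = 0.3))
  expect_lt(nrow(d2), 576)
})

test_that("dropout retention matches the binomial expectation", {
  # spec example uses 10,000 seeds; 3,000 give the same check at a
  # Monte-Carlo SE of ~0.004 isolates (tolerance below is 5 SE)
  n_runs <- 3000
  kept <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- synthetic_config(seed = i, dropout_prob = 0.05)
    kept[i] <- nrow(generate_design(cfg)) / 24  # mean per replicate
  }
  se <- sqrt(24 * 0.05 * 0.95 / (n_runs * 24))
  expect_lt(abs(mean(kept) - 22.8), 5 * se)
})

test_that("simulate_siderophore realizes the stated hierarchical process", {
  # degenerate noise: every value equals its group mean nu_j
  cfg0 <- synthetic_config(seed = 2, tau = rep(0, 4), sigma = rep(0, 4),
                           dropout_prob = 0)
  d0 <- simulate_siderophore(cfg0)
  lay <- group_layout()
  nu <- cfg0$alpha[lay$X1] + cfg0$beta[lay$X1] * lay$X2
  expect_equal(d0$siderophore, nu[d0$group])
  expect_equal(d0$lambda_true, nu[d0$group])
  # seeded determinism
  cfg <- synthetic_config(seed = 77)
  expect_identical(simulate_siderophore(cfg), simulate_siderophore(cfg))
})

test_that("empirical group means converge on nu_j (Monte Carlo)", {
  n_runs <- 200
  lay <- group_layout()
  alpha <- c(0.5, 0.7)
  beta <- c(0.04, -0.04)
  nu <- alpha[lay$X1] + beta[lay$X1] * lay$X2
  gm <- matrix(NA_real_, n_runs, 4)
  for (i in seq_len(n_runs)) {
    cfg <- synthetic_config(seed = 5000 + i, alpha = alpha, beta = beta,
                            dropout_prob = 0)
    d <- simulate_siderophore(cfg)
    gm[i, ] <- tapply(d$siderophore, d$group, mean)
  }
  for (j in 1:4) {
    se <- sd(gm[, j]) / sqrt(n_runs)
    expect_lt(abs(mean(gm[, j]) - nu[j]), 3 * se)
  }
  # pooled SD converges on sqrt(tau^2 + sigma^2)
  cfg_big <- synthetic_config(seed = 99, n_replicates = 150,
                              dropout_prob = 0)
  db <- simulate_siderophore(cfg_big)
  for (j in 1:4) {
    expect_equal(sd(db$siderophore[db$group == j]),
                 sqrt(cfg_big$tau[j]^2 + cfg_big$sigma[j]^2),
                 tolerance = 0.05)
  }
})

test_that("a null copper effect stays null (replicate-level t-tests)", {
  n_runs <- 100
  hits <- 0
  for (i in seq_len(n_runs)) {
    cfg <- synthetic_config(seed = 9000 + i, beta = c(0, 0),
                            dropout_prob = 0)
    d <- simulate_siderophore(cfg)
    comm <- d[d$isolate_type == "community", ]
    rm_means <- tapply(comm$siderophore,
                       list(comm$replicate, comm$copper), mean)
    p <- t.test(rm_means[, 1], rm_means[, 2])$p.value
    if (p < 0.01) hits <- hits + 1
  }
  # Binomial(100, 0.01): P(hits > 4) < 0.004
  expect_lte(hits, 4)
})

test_that("simulate_cas_reads inverts the quantification formula", {
  cfg <- synthetic_config(seed = 8, assay_noise_sd = 0, dropout_prob = 0)
  rec <- simulate_siderophore(cfg)
  reads <- simulate_cas_reads(rec, cfg)
  back <- siderophore_score(reads$a630, reads$a630_ref, reads$od600)
  expect_equal(back, rec$siderophore, tolerance = 1e-12)
  # zero-chelation read equals the reference absorbance
  r0 <- simulate_cas_reads(data.frame(isolate_id = "x", siderophore = 0),
                           cfg, od600 = 1)
  expect_equal(r0$a630, 0.6)
  expect_error(simulate_cas_reads(rec, cfg, od600 = 0), "od600")
})

test_that("negative recovered scores match the Normal tail probability", {
  n <- 5000
  s_true <- 0.02
  noise <- 0.01
  cfg <- synthetic_config(seed = 13, assay_noise_sd = noise)
  rec <- data.frame(isolate_id = seq_len(n), siderophore = rep(s_true, n))
  reads <- simulate_cas_reads(rec, cfg, od600 = 1)
  raw <- siderophore_score(reads$a630, reads$a630_ref, reads$od600)
  # recovered = s - eps/(a_ref * OD); negative iff eps > s * a_ref * OD
  p_neg <- pnorm(-s_true * cfg$a_ref / noise)
  se <- sqrt(p_neg * (1 - p_neg) / n)
  expect_lt(abs(mean(raw < 0) - p_neg), 4 * se)
})

test_that("simulate_competition recovers its inputs at zero noise", {
  sym <- simulate_competition(1.0, 1.0, 1e4, 1e4, 24)
  st <- competition_stats(sym)
  expect_equal(st$s_a, 0)
  expect_equal(st$r_a, 1)
  asym <- simulate_competition(1.2, 1.0, 1e4, 1e6, 24)
  st2 <- competition_stats(asym)
  expect_equal(st2$s_a, 0.2)
  expect_equal(st2$m_a, 1.2)
  expect_equal(asym$initial_frequency_a, 1e4 / (1e4 + 1e6))
  # seeded noise reproducibility
  n1 <- simulate_competition(1.2, 1.0, 1e4, 1e6, 24, noise_sd = 0.2,
                             seed = 42)
  n2 <- simulate_competition(1.2, 1.0, 1e4, 1e6, 24, noise_sd = 0.2,
                             seed = 42)
  expect_identical(n1, n2)
  expect_error(simulate_competition(1, 1, 0, 1, 24), "> 0")
})

test_that("isolate CSV round-trips with header comment and column map", {
  cfg <- synthetic_config(seed = 21)
  rec <- simulate_siderophore(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_isolate_csv(rec, path)
  expect_match(readLines(path, n = 1), "# seed: 21")
  back <- read_isolate_csv(path)
  expect_equal(back$siderophore, rec$siderophore)
  # column remapping
  odd <- back
  names(odd)[names(odd) == "siderophore"] <- "cas_score"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(odd, path2, row.names = FALSE)
  remapped <- read_isolate_csv(path2,
                               column_map = c(siderophore = "cas_score"))
  expect_equal(remapped$siderophore, rec$siderophore)
  expect_error(read_isolate_csv(path2, column_map = c(siderophore = "nope")),
               "nope")
})
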