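test_that("malthusian growth rate matches direct evaluation", {
  expect_equal(malthusian(100, 100, 10), 0)
  expect_equal(malthusian(1e2, 1e6, 48), log(1e4) / 48)
  expect_equal(malthusian(1e6, 1e5, 24), log(0.1) / 24)
  expect_error(malthusian(0, 10, 1), "> 0")
  expect_error(malthusian(10, 10, 0), "duration")
})

test_that("malthusian rates compose time-weighted over subintervals", {
  set.seed(3)
  for (i in 1:10) {
    n0 <- runif(1, 1e2, 1e4)
    n1 <- runif(1, 1e3, 1e6)
    n2 <- runif(1, 1e2, 1e7)
    t1 <- runif(1, 1, 24)
    t2 <- runif(1, 1, 24)
    m_composed <- (malthusian(n0, n1, t1) * t1 +
                     malthusian(n1, n2, t2) * t2) / (t1 + t2)
    expect_equal(m_composed, malthusian(n0, n2, t1 + t2))
  }
})

test_that("relative fitness and selection rate follow their definitions", {
  expect_equal(relative_fitness(1.5, 1.5), 1)
  expect_equal(relative_fitness(1.98, 1.88), 1.98 / 1.88)
  expect_error(relative_fitness(1.2, 0), "selection_rate")
  expect_equal(selection_rate(1.5, 1.5), 0)
  expect_equal(selection_rate(1.3, 1.0), 0.3)
  expect_equal(selection_rate(-0.2, 0.1), -0.3)
  # antisymmetry / reciprocity
  set.seed(4)
  a <- rnorm(20, 1, 0.5)
  b <- rnorm(20, 1, 0.5)
  expect_equal(selection_rate(a, b), -selection_rate(b, a))
  expect_equal(relative_fitness(a, b), 1 / relative_fitness(b, a))
})

test_that("cohens_d uses the (n-1)-weighted pooled SD and is scale free", {
  x <- rnorm(10)
  expect_equal(cohens_d(x, x), 0)
  expect_equal(cohens_d(c(0, 1), c(1, 2)), -1 / sqrt(0.5))
  set.seed(6)
  cu <- rnorm(8, 0.4, 0.2)
  ct <- rnorm(12, 0.6, 0.15)
  d0 <- cohens_d(cu, ct)
  for (cc in c(0.1, 3, 42)) expect_equal(cohens_d(cc * cu, cc * ct), d0)
  # hand-computed pooled SD oracle
  sp <- sqrt((7 * var(cu) + 11 * var(ct)) / 18)
  expect_equal(d0, (mean(cu) - mean(ct)) / sp)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "degenerate")
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("spearman_rho matches the brute-force midrank oracle", {
  expect_equal(spearman_rho(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_rho(1:6, (1:6)^2)$S, 0)
  rev4 <- spearman_rho(1:4, 4:1)
  expect_equal(rev4$rho, -1)
  expect_equal(rev4$S, 4 * (16 - 1) / 3)
  set.seed(7)
  for (i in 1:15) {
    n <- sample(4:20, 1)
    x <- sample(round(rnorm(n), 1))       # duplicates force midranks
    y <- sample(round(rnorm(n), 1))
    got <- spearman_rho(x, y)
    want <- oracle_spearman(x, y)
    expect_equal(got$rho, want$rho)
    expect_equal(got$S, want$S)
  }
  # the tied example from the contract
  got <- spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4))
  want <- oracle_spearman(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(got$rho, want$rho)
  expect_equal(got$S, want$S)
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("spearman exact permutation p agrees with the asymptotic path", {
  # untied small-n p-values also agree with cor.test's exact method
  set.seed(8)
  for (i in 1:5) {
    x <- sample(7)
    y <- sample(7)
    got <- spearman_rho(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = TRUE))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  # large-n t approximation
  x <- 1:30
  y <- x + rnorm(30, 0, 10)
  got <- spearman_rho(x, y)
  tt <- got$rho * sqrt(28 / (1 - got$rho^2))
  expect_equal(got$p_value, 2 * pt(-abs(tt), 28))
})

test_that("factorial_lm equals the normal-equations oracle", {
  set.seed(9)
  for (i in 1:10) {
    n_per <- sample(2:6, 4, replace = TRUE)
    d <- data.frame(
      a = rep(c("x", "x", "y", "y"), n_per),
      b = rep(c("u", "v", "u", "v"), n_per))
    d$y <- rnorm(nrow(d), 1, 0.5)
    fit <- factorial_lm(d, "y", "a", "b")
    want <- oracle_factorial_ls(d$y, d$a, d$b)
    expect_equal(unname(fit$coefficients), unname(want), tolerance = 1e-10)
  }
})

test_that("factorial_lm marginal means and degenerate fits behave", {
  # balanced data: marginal mean of a level = average of its two cell means
  set.seed(10)
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:5)
  d$y <- rnorm(nrow(d), 0.5, 0.1)
  fit <- factorial_lm(d, "y", "a", "b")
  cell <- tapply(d$y, list(d$a, d$b), mean)
  mm <- fit$marginal_means
  expect_equal(mm$mean[mm$factor == "a" & mm$level == "x"],
               mean(cell["x", ]))
  expect_equal(mm$mean[mm$factor == "b" & mm$level == "v"],
               mean(cell[, "v"]))
  expect_true(all(mm$lower < mm$mean & mm$mean < mm$upper))
  # constant response: all F = 0
  d$y <- 1
  fit0 <- factorial_lm(d, "y", "a", "b")
  expect_equal(fit0$anova$F, c(0, 0, 0))
  # empty cell errors
  d2 <- d[!(d$a == "x" & d$b == "u"), ]
  expect_error(factorial_lm(d2, "y", "a", "b"), "empty design cell")
})

test_that("genus_effect_sizes composes cohens_d and spearman_rho", {
  set.seed(12)
  genera <- paste0("G", 1:6)
  base <- seq(0.3, 0.8, length.out = 6)
  rows <- list()
  for (i in seq_along(genera)) {
    # effect size decreasing in baseline: stabilizing selection
    shift <- 0.25 - 0.5 * (base[i] - 0.3) / 0.5
    rows[[i]] <- data.frame(
      genus = genera[i],
      copper = rep(c(0, 1), each = 12),
      siderophore = c(rnorm(12, base[i], 0.05),
                      rnorm(12, base[i] + shift, 0.05)))
  }
  rec <- do.call(rbind, rows)
  res <- genus_effect_sizes(rec)
  expect_equal(nrow(res$effects), 6)
  # compositional oracle, per genus
  for (i in seq_along(genera)) {
    sub <- rec[rec$genus == genera[i], ]
    expect_equal(res$effects$cohens_d[i],
                 cohens_d(sub$siderophore[sub$copper == 1],
                          sub$siderophore[sub$copper == 0]))
    expect_equal(res$effects$baseline_mean[i],
                 mean(sub$siderophore[sub$copper == 0]))
  }
  sp <- spearman_rho(res$effects$cohens_d, res$effects$baseline_mean)
  expect_equal(res$spearman$rho, sp$rho)
  expect_lt(res$spearman$rho, 0)
  expect_identical(res$effects$high_baseline, base > 0.55)
  # constructed strict monotonicity gives rho = -1
  spread <- rep(c(-0.01, 0.01), 3)  # identical within-group SD everywhere
  rec2 <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(genus = paste0("H", i), copper = rep(c(0, 1), each = 6),
               siderophore = c(0.2 * i + spread,
                               0.2 * i + 0.5 - 0.1 * i + spread))
  }))
  expect_equal(genus_effect_sizes(rec2)$spearman$rho, -1)
  # too few qualifying genera
  expect_error(genus_effect_sizes(rec[rec$genus %in% genera[1:2], ]),
               "fewer than 3 genera")
})
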