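#' Malthusian growth parameter
#'
#' Per-hour exponential growth rate over an assay interval,
#' \eqn{m = \ln(N_1 / N_0) / t}. Densities may be CFU counts or OD proxies as
#' long as both time points use the same units; `m` is negative for declining
#' populations.
#'
#' @param density_t0,density_t1 Start and final population densities (> 0).
#' @param duration Assay duration in hours (> 0). Week-long compost
#'   competitions should be converted to hours before calling.
#' @return Numeric vector of growth rates per hour.
#' @examples
#' malthusian(1e2, 1e6, 48) # ~0.1919
#' @export
malthusian <- function(density_t0, density_t1, duration) {
  if (any(!is.finite(density_t0)) || any(!is.finite(density_t1)) ||
      any(!is.finite(duration))) {
    stop("densities and duration must be finite", call. = FALSE)
  }
  if (any(density_t0 <= 0) || any(density_t1 <= 0)) {
    stop("densities must be > 0 (log of a non-positive density)",
         call. = FALSE)
  }
  if (any(duration <= 0)) stop("'duration' must be > 0 hours", call. = FALSE)
  log(density_t1 / density_t0) / duration
}

#' Relative fitness as a ratio of Malthusian parameters
#'
#' \eqn{r = m_{producer} / m_{nonproducer}}. Undefined when the reference
#' strain neither grew nor declined; and misleading when either `m` is
#' negative -- use [selection_rate()] in that case.
#'
#' @param m_producer,m_nonproducer Malthusian parameters (per hour) of the
#'   focal and reference competitor.
#' @return Numeric vector of fitness ratios.
#' @export
relative_fitness <- function(m_producer, m_nonproducer) {
  stopifnot(is.numeric(m_producer), is.numeric(m_nonproducer))
  if (any(m_nonproducer == 0)) {
    stop("m_nonproducer is 0: the ratio is undefined; ",
         "use selection_rate() which tolerates zero or negative rates",
         call. = FALSE)
  }
  m_producer / m_nonproducer
}

#' Selection rate (difference of Malthusian parameters)
#'
#' \eqn{s = m_{mutant} - m_{wildtype}}; the preferred relative-fitness
#' measure when some growth rates are negative (common in toxic copper
#' compost), since the difference keeps its sign and scale there.
#'
#' @param m_mutant,m_wildtype Malthusian parameters (per hour).
#' @return Numeric vector of selection rates.
#' @export
selection_rate <- function(m_mutant, m_wildtype) {
  stopifnot(is.numeric(m_mutant), is.numeric(m_wildtype))
  if (any(!is.finite(m_mutant)) || any(!is.finite(m_wildtype))) {
    stop("growth rates must be finite", call. = FALSE)
  }
  m_mutant - m_wildtype
}

#' Cohen's d for the copper effect on a trait
#'
#' Standardized mean difference \eqn{d = (\bar x_{Cu} - \bar x_{ctrl}) /
#' s_{pooled}} with the classic pooled standard deviation using
#' \eqn{(n-1)} weights. The sign convention puts copper first: a copper-driven
#' reduction in siderophore production gives \eqn{d < 0}.
#'
#' @param group_copper,group_control Numeric vectors of trait values (each of
#'   length >= 2) for the copper and control treatment.
#' @return Scalar effect size.
#' @examples
#' cohens_d(c(0, 1), c(1, 2)) # -sqrt(2)
#' @export
cohens_d <- function(group_copper, group_control) {
  stopifnot(is.numeric(group_copper), is.numeric(group_control))
  n1 <- length(group_copper)
  n2 <- length(group_control)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs >= 2 values to estimate a pooled SD",
         call. = FALSE)
  }
  sp2 <- ((n1 - 1) * stats::var(group_copper) +
            (n2 - 1) * stats::var(group_control)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    stop("degenerate pooled variance: groups carry no within-group spread",
         call. = FALSE)
  }
  (mean(group_copper) - mean(group_control)) / sqrt(sp2)
}

# All permutations of 1..n as an n!-row matrix (recursive insertion).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman rank correlation with midrank ties
#'
#' Ranks both vectors with midranks for ties, reports the rank correlation
#' \eqn{\rho} (Pearson correlation of the ranks), the classical statistic
#' \eqn{S = \sum_i (R_i - Q_i)^2} (non-integer under ties), and a two-sided
#' p-value. For \eqn{n \le 7} the p-value is an exact permutation p over all
#' \eqn{n!} pairings; for \eqn{n = 8, 9} a seeded Monte Carlo permutation
#' null with 20,000 draws; for larger \eqn{n} the asymptotic t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n - 2} df.
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @param n_mc Monte Carlo permutation draws used for `n` of 8 or 9.
#' @return List with elements `rho`, `S`, `p_value`, `n`, `method`.
#' @export
spearman_rho <- function(x, y, n_mc = 20000L) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop("'x' and 'y' must be paired vectors of equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported",
                                 call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("all ranks tied in one variable: rho is undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  S <- sum((rx - ry)^2)
  rho_perm <- function(perm_matrix) {
    # correlation of ry against each permutation of rx, vectorized
    rxm <- matrix(rx[perm_matrix], nrow = nrow(perm_matrix))
    sx <- stats::sd(rx)
    sy <- stats::sd(ry)
    (rxm %*% (ry - mean(ry))) / ((n - 1) * sx * sy)
  }
  eps <- 1e-12
  if (n <= 7L) {
    perms <- all_permutations(n)
    p <- mean(abs(rho_perm(perms)) >= abs(rho) - eps)
    method <- "exact permutation"
  } else if (n <= 9L) {
    perms <- t(vapply(seq_len(n_mc), function(i) sample.int(n),
                      integer(n)))
    p <- (sum(abs(rho_perm(perms)) >= abs(rho) - eps) + 1) / (n_mc + 1)
    method <- "Monte Carlo permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, S = S, p_value = min(p, 1), n = n, method = method)
}

#' Two-way factorial linear model on per-microcosm means
#'
#' Ordinary least squares for a 2x2 factorial with interaction on
#' unit-level (per-microcosm) trait means, with the model-reduction F-tests
#' used for factorial screens: the interaction is tested against the additive
#' model, then each main effect is tested by deleting it from the additive
#' model. Marginal means for each factor pool over the levels of the other
#' factor with equal weight and carry t-based 95% confidence intervals on the
#' residual df of the reduced (additive) model when the interaction is
#' dropped at `alpha_drop`, or of the full model otherwise.
#'
#' @param data Data frame of per-unit means.
#' @param response Name of the numeric response column.
#' @param factor_a,factor_b Names of the two binary factor columns.
#' @param alpha_drop Significance level for dropping the interaction
#'   (default 0.05).
#' @return List with `coefficients`, `anova` (term, df1, df2, F, p),
#'   `marginal_means` (factor, level, mean, lower, upper, df), and the
#'   fitted `model` used for the means.
#' @export
factorial_lm <- function(data, response, factor_a, factor_b,
                         alpha_drop = 0.05) {
  for (col in c(response, factor_a, factor_b)) {
    if (!col %in% names(data)) stop("column '", col, "' not found",
                                    call. = FALSE)
  }
  y <- data[[response]]
  if (!is.numeric(y)) stop("response must be numeric", call. = FALSE)
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  if (nlevels(fa) != 2L || nlevels(fb) != 2L) {
    stop("both factors must have exactly 2 observed levels", call. = FALSE)
  }
  cell_n <- table(fa, fb)
  if (any(cell_n == 0L)) stop("empty design cell: every factor combination ",
                              "needs observations", call. = FALSE)
  if (any(cell_n < 2L)) stop("each design cell needs >= 2 units",
                             call. = FALSE)
  d <- data.frame(y = y, a = fa, b = fb)
  full <- stats::lm(y ~ a * b, data = d)
  if (any(is.na(stats::coef(full)))) stop("singular design", call. = FALSE)
  additive <- stats::lm(y ~ a + b, data = d)
  only_a <- stats::lm(y ~ a, data = d)
  only_b <- stats::lm(y ~ b, data = d)

  y_scale <- mean(y^2) + 1
  ftest <- function(reduced, larger) {
    rss_r <- sum(stats::residuals(reduced)^2)
    rss_l <- sum(stats::residuals(larger)^2)
    df1 <- stats::df.residual(reduced) - stats::df.residual(larger)
    df2 <- stats::df.residual(larger)
    num <- (rss_r - rss_l) / df1
    den <- rss_l / df2
    eps <- 1e-12 * y_scale   # a constant response gives 0/0, reported as 0
    Fv <- if (num <= eps) 0 else if (den <= eps) Inf else num / den
    c(df1 = df1, df2 = df2, F = Fv,
      p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  }
  t_int <- ftest(additive, full)
  t_a <- ftest(only_b, additive)
  t_b <- ftest(only_a, additive)
  anova_tab <- data.frame(
    term = c(paste0(factor_a, ":", factor_b), factor_a, factor_b),
    df1 = c(t_int["df1"], t_a["df1"], t_b["df1"]),
    df2 = c(t_int["df2"], t_a["df2"], t_b["df2"]),
    F = c(t_int["F"], t_a["F"], t_b["F"]),
    p = c(t_int["p"], t_a["p"], t_b["p"]),
    row.names = NULL
  )
  model <- if (is.finite(t_int["p"]) && t_int["p"] < alpha_drop) full else
    additive

  # marginal mean of level l of one factor: average the two cell predictions
  mm_row <- function(fname, flev, other_levs) {
    grid <- data.frame(
      a = factor(if (fname == "a") rep(flev, length(other_levs)) else
        other_levs, levels = levels(fa)),
      b = factor(if (fname == "b") rep(flev, length(other_levs)) else
        other_levs, levels = levels(fb)))
    X <- stats::model.matrix(stats::delete.response(stats::terms(model)),
                             grid)
    cvec <- colMeans(X)
    est <- sum(cvec * stats::coef(model))
    se <- sqrt(drop(t(cvec) %*% suppressWarnings(stats::vcov(model)) %*%
                      cvec))
    df <- stats::df.residual(model)
    tq <- stats::qt(0.975, df)
    c(mean = est, lower = est - tq * se, upper = est + tq * se, df = df)
  }
  rows <- list()
  for (lev in levels(fa)) {
    rows[[length(rows) + 1L]] <- data.frame(
      factor = factor_a, level = lev,
      t(mm_row("a", lev, levels(fb))), row.names = NULL)
  }
  for (lev in levels(fb)) {
    rows[[length(rows) + 1L]] <- data.frame(
      factor = factor_b, level = lev,
      t(mm_row("b", lev, levels(fa))), row.names = NULL)
  }
  list(coefficients = stats::coef(full), anova = anova_tab,
       marginal_means = do.call(rbind, rows), model = model)
}

#' Genus-level copper effect sizes and their baseline relationship
#'
#' For every genus observed in both copper treatments with at least `min_n`
#' isolates in each, computes the baseline (control) mean siderophore score,
#' the copper effect size (Cohen's d, copper minus control), and a
#' high/low-baseline flag at `baseline_threshold`. The stabilizing-selection
#' signature -- copper pulling trait extremes toward the middle -- shows up as
#' a negative Spearman correlation between effect size and baseline mean
#' across genera.
#'
#' @param records Data frame with columns `genus`, `copper` (logical or 0/1)
#'   and `siderophore`.
#' @param min_n Minimum isolates per genus per treatment to retain a genus
#'   (default 3).
#' @param baseline_threshold High-baseline annotation cutoff on the control
#'   mean (default 0.55, the conventional split for this trait scale).
#' @return List with `effects` (one row per retained genus: genus,
#'   baseline_mean, cohens_d, n_control, n_copper, high_baseline) and
#'   `spearman`, the [spearman_rho()] summary of `cohens_d` against
#'   `baseline_mean`.
#' @export
genus_effect_sizes <- function(records, min_n = 3L, baseline_threshold = 0.55) {
  need <- c("genus", "copper", "siderophore")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records are missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cu <- as.logical(records$copper)
  if (anyNA(cu)) stop("'copper' must be logical or 0/1", call. = FALSE)
  rows <- list()
  for (g in sort(unique(as.character(records$genus)))) {
    sel <- records$genus == g
    x_cu <- records$siderophore[sel & cu]
    x_ct <- records$siderophore[sel & !cu]
    if (length(x_cu) < min_n || length(x_ct) < min_n) next
    base <- mean(x_ct)
    rows[[length(rows) + 1L]] <- data.frame(
      genus = g, baseline_mean = base,
      cohens_d = cohens_d(x_cu, x_ct),
      n_control = length(x_ct), n_copper = length(x_cu),
      high_baseline = base > baseline_threshold,
      row.names = NULL)
  }
  if (length(rows) < 3L) {
    stop("fewer than 3 genera meet the min_n = ", min_n,
         " retention rule; the baseline-effect correlation is undefined",
         call. = FALSE)
  }
  effects <- do.call(rbind, rows)
  sp <- spearman_rho(effects$cohens_d, effects$baseline_mean)
  list(effects = effects, spearman = sp)
}
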