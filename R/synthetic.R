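#' Canonical treatment-group layout
#'
#' The four treatment groups of the coculture design, in the fixed canonical
#' order used everywhere in this package:
#' 1 = community / no copper, 2 = community / copper,
#' 3 = SBW25 / no copper, 4 = SBW25 / copper.
#' `X1` indexes isolate type (1 = community, 2 = SBW25) and `X2` indicates
#' copper presence (1 = copper added).
#'
#' @return Data frame with columns `group`, `isolate_type`, `copper`, `X1`,
#'   `X2`.
#' @export
group_layout <- function() {
  data.frame(
    group = 1:4,
    isolate_type = c("community", "community", "SBW25", "SBW25"),
    copper = c(0L, 1L, 0L, 1L),
    X1 = c(1L, 1L, 2L, 2L),
    X2 = c(0L, 1L, 0L, 1L)
  )
}

#' Configuration for the synthetic microcosm experiment
#'
#' Describes one simulated run of the factorial selection experiment:
#' isolate type (focal strain SBW25 vs. the rest of the compost community)
#' crossed with copper amendment, six replicate microcosms per copper level,
#' and up to 24 isolates picked per type per microcosm. The generative model
#' is exactly the hierarchical model fitted downstream: per-group mean
#' \eqn{\nu_j = \alpha_{X1[j]} + \beta_{X1[j]} X2[j]}, replicate-level means
#' \eqn{\lambda_{j,k} \sim N(\nu_j, \tau_j)}, isolate scores
#' \eqn{y \sim N(\lambda_{j,k}, \sigma_j)}.
#'
#' Defaults state the experimental world this generator emulates: baseline
#' means 0.49 (community) and 0.70 (SBW25), copper effects +0.045 and -0.040,
#' residual SDs (0.10, 0.07, 0.03, 0.035) in canonical group order,
#' replicate-level SD 0.02, and an isolate dropout probability of 0.089
#' reproducing the observed shortfall from 1,152 possible to ~1,049 assayed
#' isolates.
#'
#' @param seed Integer RNG seed; recorded in every output.
#' @param n_replicates Replicate microcosms per group (default 6).
#' @param n_isolates Isolate slots per replicate (default 24).
#' @param dropout_prob Probability that an isolate slot is lost
#'   (i.i.d. Bernoulli; default 0.089).
#' @param alpha Length-2 baseline mean score per isolate type
#'   (community, SBW25).
#' @param beta Length-2 additive copper effect per isolate type.
#' @param tau Length-4 replicate-level SD per group (canonical order).
#' @param sigma Length-4 residual SD per group (canonical order).
#' @param assay_noise_sd SD of additive absorbance noise on simulated CAS
#'   reads (default 0.01 absorbance units).
#' @param a_ref Reference absorbance of the CAS mixture (default 0.6).
#' @param genus_levels Character vector of community genus labels.
#' @param genus_probs Sampling probabilities for `genus_levels` (uniform by
#'   default).
#' @param genus_offsets Per-genus additive mean offsets (all zero by default,
#'   which keeps the generative model exactly the hierarchical model; set
#'   nonzero offsets to build genus-structured panels for effect-size tests).
#' @param n_groups Number of treatment groups; must be 4 (canonical layout).
#' @return Object of class `sidero_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_replicates = 6L,
                             n_isolates = 24L,
                             dropout_prob = 0.089,
                             alpha = c(0.49, 0.70),
                             beta = c(0.045, -0.040),
                             tau = rep(0.02, 4),
                             sigma = c(0.10, 0.07, 0.03, 0.035),
                             assay_noise_sd = 0.01,
                             a_ref = 0.6,
                             genus_levels = c("Pseudomonas", "Bacillus",
                                              "Arthrobacter", "Cupriavidus",
                                              "Achromobacter",
                                              "Lysinibacillus",
                                              "Stenotrophomonas",
                                              "Rhodococcus"),
                             genus_probs = NULL,
                             genus_offsets = NULL,
                             n_groups = 4L) {
  fail <- function(field, why) {
    stop("invalid synthetic config: field '", field, "' ", why,
         call. = FALSE)
  }
  if (length(seed) != 1L || !is.finite(seed)) fail("seed", "must be a scalar")
  if (n_groups != 4L) fail("n_groups", "must be 4 (canonical 2x2 layout)")
  if (length(n_replicates) != 1L || n_replicates < 1L)
    fail("n_replicates", "must be >= 1")
  if (length(n_isolates) != 1L || n_isolates < 1L)
    fail("n_isolates", "must be >= 1")
  if (length(dropout_prob) != 1L || dropout_prob < 0 || dropout_prob >= 1)
    fail("dropout_prob", "must lie in [0, 1)")
  if (length(alpha) != 2L || anyNA(alpha)) fail("alpha", "must be a 2-vector")
  if (length(beta) != 2L || anyNA(beta)) fail("beta", "must be a 2-vector")
  if (length(tau) != 4L || any(tau < 0)) fail("tau", "must be 4 SDs >= 0")
  if (length(sigma) != 4L || any(sigma < 0))
    fail("sigma", "must be 4 SDs >= 0")
  if (length(assay_noise_sd) != 1L || assay_noise_sd < 0)
    fail("assay_noise_sd", "must be >= 0")
  if (length(a_ref) != 1L || a_ref <= 0) fail("a_ref", "must be > 0")
  if (is.null(genus_probs)) {
    genus_probs <- rep(1 / length(genus_levels), length(genus_levels))
  }
  if (is.null(genus_offsets)) genus_offsets <- rep(0, length(genus_levels))
  if (length(genus_probs) != length(genus_levels))
    fail("genus_probs", "must match genus_levels in length")
  if (any(genus_probs < 0) || sum(genus_probs) <= 0)
    fail("genus_probs", "must be nonnegative and sum > 0")
  if (length(genus_offsets) != length(genus_levels))
    fail("genus_offsets", "must match genus_levels in length")
  structure(list(
    seed = as.integer(seed), n_groups = 4L,
    n_replicates = as.integer(n_replicates),
    n_isolates = as.integer(n_isolates),
    dropout_prob = dropout_prob, alpha = alpha, beta = beta,
    tau = tau, sigma = sigma, assay_noise_sd = assay_noise_sd,
    a_ref = a_ref, genus_levels = genus_levels,
    genus_probs = genus_probs / sum(genus_probs),
    genus_offsets = genus_offsets
  ), class = "sidero_config")
}

#' @export
print.sidero_config <- function(x, ...) {
  cat("Synthetic microcosm configuration (seed ", x$seed, ")\n", sep = "")
  cat("  design: 4 groups x", x$n_replicates, "replicates x", x$n_isolates,
      "isolate slots, dropout", x$dropout_prob, "\n")
  cat("  alpha:", format(x$alpha), " beta:", format(x$beta), "\n")
  cat("  tau:  ", format(x$tau), "\n  sigma:", format(x$sigma), "\n")
  invisible(x)
}

#' Generate the factorial design table
#'
#' Lays out one (group, replicate, isolate) row per retained isolate slot.
#' Each replicate keeps `Binomial(n_isolates, 1 - dropout_prob)` slots, with
#' slot losses i.i.d.; community and SBW25 isolates from the same copper
#' level and replicate share a microcosm, mirroring the coculture treatment.
#' Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `isolate_id`, `microcosm_id`, `group`,
#'   `replicate`, `isolate`, `isolate_type`, `copper`, `community_context`.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "sidero_config"))
  set.seed(config$seed)
  lay <- group_layout()
  rows <- vector("list", 4L * config$n_replicates)
  idx <- 0L
  for (j in 1:4) {
    for (k in seq_len(config$n_replicates)) {
      keep <- if (config$dropout_prob > 0) {
        which(stats::runif(config$n_isolates) >= config$dropout_prob)
      } else {
        seq_len(config$n_isolates)
      }
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        group = j, replicate = k, isolate = keep,
        isolate_type = lay$isolate_type[j], copper = lay$copper[j],
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  out$microcosm_id <- sprintf("M_Cu%d_R%02d", out$copper, out$replicate)
  out$isolate_id <- sprintf("%s_%s_%02d", out$microcosm_id,
                            ifelse(out$isolate_type == "SBW25", "S", "C"),
                            out$isolate)
  out$community_context <- TRUE
  out[, c("isolate_id", "microcosm_id", "group", "replicate", "isolate",
          "isolate_type", "copper", "community_context")]
}

#' Simulate isolate-level siderophore scores
#'
#' Draws the full hierarchical generative process on top of
#' [generate_design()]: replicate-level means
#' \eqn{\lambda_{j,k} \sim N(\nu_j, \tau_j)} with
#' \eqn{\nu_j = \alpha_{X1[j]} + \beta_{X1[j]} X2[j]}, then isolate scores
#' \eqn{y \sim N(\lambda_{j,k} + \delta_{genus}, \sigma_j)} where the genus
#' offsets \eqn{\delta} are zero by default. Community isolates receive a
#' genus label from the configured categorical distribution; SBW25 clones are
#' labelled `"SBW25"`.
#'
#' @param config A [synthetic_config()].
#' @return Data frame of isolate records (canonical isolate columns plus
#'   `genus`, `siderophore`, and the true `lambda_true` and `nu_true` for
#'   test introspection). The true \eqn{\lambda} matrix is attached as
#'   attribute `lambda_matrix` (groups x replicates) and the config as
#'   attribute `config`.
#' @export
simulate_siderophore <- function(config) {
  stopifnot(inherits(config, "sidero_config"))
  design <- generate_design(config)   # seeds the RNG stream
  lay <- group_layout()
  nu <- config$alpha[lay$X1] + config$beta[lay$X1] * lay$X2
  lambda <- matrix(stats::rnorm(4L * config$n_replicates,
                                mean = rep(nu, each = config$n_replicates),
                                sd = rep(config$tau,
                                         each = config$n_replicates)),
                   nrow = 4L, ncol = config$n_replicates, byrow = TRUE)
  n <- nrow(design)
  genus <- rep("SBW25", n)
  is_comm <- design$isolate_type == "community"
  if (any(is_comm)) {
    genus[is_comm] <- sample(config$genus_levels, sum(is_comm),
                             replace = TRUE, prob = config$genus_probs)
  }
  offset <- ifelse(is_comm,
                   config$genus_offsets[match(genus, config$genus_levels)],
                   0)
  lam_i <- lambda[cbind(design$group, design$replicate)]
  design$genus <- genus
  design$siderophore <- stats::rnorm(n, mean = lam_i + offset,
                                     sd = config$sigma[design$group])
  design$lambda_true <- lam_i
  design$nu_true <- nu[design$group]
  attr(design, "lambda_matrix") <- lambda
  attr(design, "config") <- config
  design
}

#' Simulate raw CAS plate reads for a set of isolate records
#'
#' Inverts the CAS quantification formula: given a target score \eqn{s} and a
#' culture density \eqn{OD \sim U(0.3, 1.2)}, emits
#' \eqn{A_{630} = A_{ref}(1 - s \cdot OD) + \epsilon} with
#' \eqn{\epsilon \sim N(0, \mathrm{assay\_noise\_sd})}, so that
#' [siderophore_score()] recovers \eqn{s} exactly at zero noise. OD draws are
#' capped so that the noiseless absorbance stays positive
#' (\eqn{s \cdot OD \le 0.95}); noisy reads are floored at 0 absorbance.
#' Negative *recovered* scores remain possible (and are the point of
#' min-zero standardization downstream).
#'
#' @param records Data frame with `isolate_id` and `siderophore` columns
#'   (e.g. from [simulate_siderophore()]); scores are the targets.
#' @param config A [synthetic_config()] supplying `a_ref` and
#'   `assay_noise_sd`.
#' @param od600 Optional vector of ODs (> 0) to use instead of the uniform
#'   draw; recycled.
#' @return Data frame with columns `isolate_id`, `a630`, `a630_ref`,
#'   `od600`.
#' @export
simulate_cas_reads <- function(records, config, od600 = NULL) {
  stopifnot(inherits(config, "sidero_config"))
  if (!all(c("isolate_id", "siderophore") %in% names(records))) {
    stop("records need 'isolate_id' and 'siderophore' columns",
         call. = FALSE)
  }
  s <- records$siderophore
  n <- length(s)
  set.seed(config$seed + 1L)  # separate stream from the score simulation
  if (is.null(od600)) {
    od <- stats::runif(n, 0.3, 1.2)
    cap <- s > 0 & s * od > 0.95
    od[cap] <- 0.95 / s[cap]
  } else {
    od <- rep_len(od600, n)
    if (any(od <= 0)) stop("'od600' must be > 0", call. = FALSE)
  }
  a <- config$a_ref * (1 - s * od)
  if (config$assay_noise_sd > 0) {
    a <- a + stats::rnorm(n, 0, config$assay_noise_sd)
  }
  data.frame(isolate_id = records$isolate_id, a630 = pmax(a, 0),
             a630_ref = config$a_ref, od600 = od)
}

#' Simulate a pairwise competition assay
#'
#' Exponential growth of two co-inoculated strains over `duration` hours:
#' final density \eqn{N_0 e^{m t}} with multiplicative log-normal noise of SD
#' `noise_sd` on the log scale. At zero noise the downstream Malthusian /
#' selection-rate calculations recover the inputs exactly.
#'
#' @param m_a,m_b True Malthusian parameters (per hour) of strains A and B.
#' @param n0_a,n0_b Starting densities (> 0).
#' @param duration Assay duration in hours (> 0).
#' @param noise_sd SD of log-scale density noise (default 0).
#' @param seed Optional seed for the noise draw.
#' @return Object of class `competition_assay`: a list with the per-strain
#'   start/final densities, duration and initial frequency of strain A.
#' @export
simulate_competition <- function(m_a, m_b, n0_a, n0_b, duration,
                                 noise_sd = 0, seed = NULL) {
  if (n0_a <= 0 || n0_b <= 0) stop("starting densities must be > 0",
                                   call. = FALSE)
  if (duration <= 0) stop("'duration' must be > 0 hours", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise_sd > 0) stats::rnorm(2, 0, noise_sd) else c(0, 0)
  structure(list(
    strain_a = "A", strain_b = "B",
    density_t0_a = n0_a, density_t0_b = n0_b,
    density_t1_a = n0_a * exp(m_a * duration + eps[1]),
    density_t1_b = n0_b * exp(m_b * duration + eps[2]),
    duration = duration,
    initial_frequency_a = n0_a / (n0_a + n0_b)
  ), class = "competition_assay")
}

#' Fitness statistics of a competition assay
#'
#' @param assay A [simulate_competition()] result (or any list with the same
#'   fields).
#' @return List with per-strain Malthusian parameters `m_a`, `m_b`, the
#'   fitness ratio `r_a` (A relative to B) and selection rate `s_a`
#'   (`m_a - m_b`).
#' @export
competition_stats <- function(assay) {
  m_a <- malthusian(assay$density_t0_a, assay$density_t1_a, assay$duration)
  m_b <- malthusian(assay$density_t0_b, assay$density_t1_b, assay$duration)
  list(m_a = m_a, m_b = m_b,
       r_a = if (m_b != 0) m_a / m_b else NA_real_,
       s_a = m_a - m_b)
}

#' Write / read the canonical isolate CSV
#'
#' The canonical isolate table has columns `isolate_id`, `microcosm_id`,
#' `group`, `replicate`, `isolate_type`, `copper`, `community_context`,
#' `genus`, `siderophore`. The writer records the seed (when known) in a
#' `#`-prefixed header comment; the reader skips comment lines and can remap
#' arbitrary column names via `column_map`.
#'
#' @param records Isolate data frame.
#' @param path Output CSV path.
#' @param seed Seed to record in the header; taken from the attached config
#'   when present.
#' @return `path`, invisibly.
#' @export
write_isolate_csv <- function(records, path, seed = NULL) {
  cfg <- attr(records, "config")
  if (is.null(seed) && !is.null(cfg)) seed <- cfg$seed
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  cols <- intersect(c("isolate_id", "microcosm_id", "group", "replicate",
                      "isolate_type", "copper", "community_context", "genus",
                      "siderophore"), names(records))
  utils::write.csv(records[, cols], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isolate_csv
#' @param path Input CSV path.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(siderophore = "cas_score", copper = "treatment")`.
#' @export
read_isolate_csv <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("column-mapping error: file has no column '", src, "'",
             call. = FALSE)
      }
      df[[canon]] <- df[[src]]
    }
  }
  df
}

#' Write the assay-read CSV
#'
#' @param reads Assay data frame (`isolate_id`, `a630`, `a630_ref`, `od600`).
#' @param path Output CSV path.
#' @param seed Optional seed recorded in a header comment.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(reads, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(reads, con, row.names = FALSE)
  invisible(path)
}
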