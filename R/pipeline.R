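#' Validate a pipeline configuration
#'
#' A pipeline run takes exactly one data source -- a synthetic-generator
#' configuration or paths to input CSVs -- plus sampler settings and an
#' output directory. Missing fields fall back to the experiment's defaults
#' (4 chains x 1,000 draws, per-group residual SDs).
#'
#' @param config Named list or path to a JSON config file with fields:
#'   `synthetic` (list of [synthetic_config()] arguments) *or* `inputs`
#'   (list with `isolates` and/or `assays` paths and optional `column_map`);
#'   optional `sampler` (`chains`, `iterations`, `warmup`, `seed`),
#'   `variance_structures` (character; first entry is the headline model),
#'   `effect_sizes` (`min_n`, `baseline_threshold`), `out_dir`, `seed`.
#' @return Normalized config list of class `sidero_pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  has_syn <- !is.null(config$synthetic)
  has_in <- !is.null(config$inputs)
  if (has_syn == has_in) {
    stop("config must contain exactly one of 'synthetic' or 'inputs'",
         call. = FALSE)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  sam <- config$sampler %||% list()
  config$sampler <- list(chains = as.integer(sam$chains %||% 4L),
                         iterations = as.integer(sam$iterations %||% 1000L),
                         warmup = as.integer(sam$warmup %||% 1000L),
                         seed = as.integer(sam$seed %||% config$seed))
  config$variance_structures <-
    config$variance_structures %||% "per_group"
  es <- config$effect_sizes %||% list()
  config$effect_sizes <- list(
    min_n = as.integer(es$min_n %||% 3L),
    baseline_threshold = es$baseline_threshold %||% 0.55)
  config$out_dir <- config$out_dir %||% tempfile("siderotrait_run_")
  class(config) <- "sidero_pipeline_config"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_pipeline_isolates <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    if (is.null(syn$seed)) syn$seed <- config$seed
    cfg <- do.call(synthetic_config, syn)
    return(simulate_siderophore(cfg))
  }
  inp <- config$inputs
  cmap <- inp$column_map
  if (!is.null(cmap)) cmap <- unlist(cmap)
  if (!is.null(inp$assays)) {
    reads <- read_isolate_csv(inp$assays, cmap)
    validate_columns(reads, c("isolate_id", "a630", "a630_ref", "od600"),
                     inp$assays)
    q <- quantify_assays(reads)
    if (!is.null(inp$isolates)) {
      meta <- read_isolate_csv(inp$isolates, cmap)
      q$siderophore_raw <- NULL
      return(merge(meta, q[, c("isolate_id", "siderophore")],
                   by = "isolate_id"))
    }
    return(q)
  }
  iso <- read_isolate_csv(inp$isolates, cmap)
  validate_columns(iso, c("isolate_type", "copper", "replicate",
                          "siderophore"), inp$isolates)
  iso
}

validate_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("schema error in '", path, "': missing column(s) ",
         paste(miss, collapse = ", "),
         " (use inputs$column_map to remap names)", call. = FALSE)
  }
  invisible(df)
}

stage_msg <- function(...) message("[siderotrait] ", ...)

#' Run the full analysis pipeline
#'
#' Orchestrates the stages of the copper/siderophore analysis in their
#' methodological order: obtain isolate scores (simulate, or quantify raw
#' CAS reads), fit the hierarchical model under each requested
#' residual-variance structure, compare structures by PSIS-LOO, compute MAP
#' estimates and derived contrasts for the headline (first-listed)
#' structure, run the factorial marginal-means model on per-microcosm type
#' means, and -- when genus labels are present -- the genus effect-size
#' screen. All outputs are written under `out_dir` with a manifest of file
#' MD5 hashes, the seed, and a config hash; re-running with the same config
#' and seed reproduces the report.
#'
#' @param config A [pipeline_config()] (or list / JSON path accepted by it).
#' @return Invisibly, a list with the isolate table, fits, loo table,
#'   contrasts, marginal means, effect sizes, and manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "sidero_pipeline_config")) {
    config <- pipeline_config(config)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  stage_msg("stage 1/5: isolate table")
  isolates <- load_pipeline_isolates(config)
  iso_path <- file.path(config$out_dir, "isolates.csv")
  write_isolate_csv(isolates, iso_path, seed = config$seed)

  stage_msg("stage 2/5: hierarchical model fits (",
            paste(config$variance_structures, collapse = ", "), ")")
  sam <- config$sampler
  fits <- list()
  for (vs in config$variance_structures) {
    fits[[vs]] <- sample_posterior(isolates, model_spec(vs),
                                   chains = sam$chains,
                                   iterations = sam$iterations,
                                   warmup = sam$warmup, seed = sam$seed)
  }
  headline <- fits[[config$variance_structures[1]]]

  loo_tab <- NULL
  if (length(fits) > 1L) {
    stage_msg("stage 3/5: PSIS-LOO comparison")
    loo_tab <- psis_loo(fits)
    utils::write.csv(loo_tab, file.path(config$out_dir, "loo.csv"),
                     row.names = FALSE)
  } else stage_msg("stage 3/5: skipped (single variance structure)")

  stage_msg("stage 4/5: MAP, HPD and contrasts")
  map <- map_estimate(isolates, headline$spec, seed = sam$seed,
                      fit = headline)
  summ <- posterior_summary(headline)
  summ$map <- map$estimates[summ$parameter]
  utils::write.csv(summ, file.path(config$out_dir, "posterior_summary.csv"),
                   row.names = FALSE)
  contrasts <- derived_contrasts(headline, map = map)
  utils::write.csv(contrasts, file.path(config$out_dir, "contrasts.csv"),
                   row.names = FALSE)

  stage_msg("stage 5/5: marginal means and effect sizes")
  means_tab <- tryCatch({
    agg <- stats::aggregate(siderophore ~ microcosm_id + isolate_type +
                              copper, data = isolates, FUN = mean)
    factorial_lm(agg, "siderophore", "copper", "isolate_type")
  }, error = function(e) {
    stage_msg("marginal means skipped: ", conditionMessage(e)); NULL
  })
  if (!is.null(means_tab)) {
    utils::write.csv(means_tab$marginal_means,
                     file.path(config$out_dir, "marginal_means.csv"),
                     row.names = FALSE)
  }
  effects <- NULL
  if ("genus" %in% names(isolates)) {
    comm <- isolates[isolates$isolate_type == "community", , drop = FALSE]
    effects <- tryCatch(
      genus_effect_sizes(comm, min_n = config$effect_sizes$min_n,
                         baseline_threshold =
                           config$effect_sizes$baseline_threshold),
      error = function(e) {
        stage_msg("effect sizes skipped: ", conditionMessage(e)); NULL
      })
    if (!is.null(effects)) {
      utils::write.csv(effects$effects,
                       file.path(config$out_dir, "effect_sizes.csv"),
                       row.names = FALSE)
    }
  }

  core <- grep("^lambda", summ$parameter, invert = TRUE)
  report <- list(
    seed = config$seed,
    sampler = sam,
    variance_structures = config$variance_structures,
    converged = headline$converged,
    n_observations = nrow(isolates),
    parameters = lapply(seq_along(core), function(i) {
      r <- summ[core[i], ]
      list(parameter = r$parameter, map = unname(r$map), mean = r$mean,
           hpd95 = c(r$hpd_low, r$hpd_high), rhat = r$rhat)
    }),
    contrasts = lapply(seq_len(nrow(contrasts)), function(i) {
      r <- contrasts[i, ]
      list(name = r$name, map = r$estimate,
           hpd95 = c(r$hpd_low, r$hpd_high))
    }),
    loo = if (!is.null(loo_tab)) loo_tab else NULL,
    spearman = if (!is.null(effects)) effects$spearman else NULL
  )
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("siderotrait")),
    r_version = as.character(getRversion()),
    config_hash = config_hash(config),
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_msg("done in ",
            format(round(difftime(Sys.time(), t0, units = "secs"), 1)))
  invisible(list(isolates = isolates, fits = fits, loo = loo_tab,
                 map = map, summary = summ, contrasts = contrasts,
                 means = means_tab, effect_sizes = effects,
                 manifest = manifest, out_dir = config$out_dir))
}

config_hash <- function(config) {
  flat <- unclass(config)
  flat$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(flat, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
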