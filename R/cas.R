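#' Siderophore score from a chrome azurol S (CAS) plate read
#'
#' Converts a raw CAS assay read into a per-isolate siderophore production
#' score. Iron chelation by culture supernatant strips iron from the CAS dye
#' and lowers absorbance at 630 nm relative to an un-inoculated reference
#' mixture, so production is scored as the fractional loss of dye absorbance,
#' corrected for how much the culture grew:
#'
#' \deqn{s = \frac{1 - A_{630} / A_{ref}}{OD_{600}}}
#'
#' Scores are unitless ("arbitrary units"). Negative values are possible when
#' a read exceeds its reference (e.g. pigmented supernatants); they are kept
#' as-is here and handled downstream by [standardize_min_zero()].
#'
#' @param a630 Numeric vector, absorbance of the assay mixture at 630 nm.
#' @param a630_ref Numeric vector (recycled), absorbance at 630 nm of the
#'   reference mixture (growth medium + CAS). Must be positive.
#' @param od600 Numeric vector (recycled), optical density of the culture at
#'   600 nm. Must be strictly positive; values below `od_warn` trigger a
#'   warning because the OD correction becomes ill-conditioned for
#'   non-growing isolates.
#' @param od_warn Warning threshold for small `od600` (default 0.05).
#' @return Numeric vector of raw (possibly negative) siderophore scores.
#' @seealso [standardize_min_zero()], [quantify_assays()]
#' @examples
#' siderophore_score(a630 = 0.3, a630_ref = 0.6, od600 = 1.0) # 0.5
#' @export
siderophore_score <- function(a630, a630_ref, od600, od_warn = 0.05) {
  stopifnot(is.numeric(a630), is.numeric(a630_ref), is.numeric(od600))
  n <- max(length(a630), length(a630_ref), length(od600))
  a630 <- rep_len(a630, n)
  a630_ref <- rep_len(a630_ref, n)
  od600 <- rep_len(od600, n)
  if (anyNA(a630) || anyNA(a630_ref) || anyNA(od600)) {
    stop("assay reads must not contain missing values", call. = FALSE)
  }
  if (any(a630_ref <= 0)) {
    stop("'a630_ref' must be > 0 (reference absorbance)", call. = FALSE)
  }
  if (any(od600 <= 0)) {
    stop("'od600' must be > 0; cannot OD-correct a non-growing culture",
         call. = FALSE)
  }
  if (any(a630 < 0)) {
    stop("'a630' must be >= 0", call. = FALSE)
  }
  if (any(od600 < od_warn)) {
    warning(sprintf("%d read(s) have od600 < %g; scores are ill-conditioned",
                    sum(od600 < od_warn), od_warn), call. = FALSE)
  }
  (1 - a630 / a630_ref) / od600
}

#' Min-zero standardization of siderophore scores
#'
#' Reference correction can push raw CAS scores below zero. Following the
#' convention of anchoring the dataset minimum at zero, the whole vector is
#' shifted by `-min(x)` when (and only when) the minimum is negative;
#' datasets without negative reads are returned unchanged, preserving their
#' absolute scale. The shift is a single dataset-wide constant (not
#' per-plate), so rank order and all pairwise differences are preserved.
#'
#' @param x Numeric vector of raw siderophore scores; must be non-empty and
#'   free of missing values.
#' @return Numeric vector with `min(result) >= 0`.
#' @examples
#' standardize_min_zero(c(-0.1, 0.2, 0.5)) # 0.0 0.3 0.6
#' @export
standardize_min_zero <- function(x) {
  if (length(x) == 0L) stop("cannot standardize an empty score vector",
                            call. = FALSE)
  stopifnot(is.numeric(x))
  if (anyNA(x)) stop("scores must not contain missing values", call. = FALSE)
  m <- min(x)
  if (m < 0) x - m else x
}

#' Quantify a table of CAS assay reads
#'
#' Data-frame front end for [siderophore_score()] followed by
#' [standardize_min_zero()] applied across the whole table (the
#' standardization scope is the analysis dataset, not the plate).
#'
#' @param assays Data frame with columns `isolate_id`, `a630`, `a630_ref`,
#'   `od600` (extra columns are carried through).
#' @param standardize Apply min-zero standardization (default `TRUE`).
#' @return The input data frame with columns `siderophore_raw` and
#'   `siderophore` appended.
#' @export
quantify_assays <- function(assays, standardize = TRUE) {
  need <- c("isolate_id", "a630", "a630_ref", "od600")
  miss <- setdiff(need, names(assays))
  if (length(miss)) {
    stop("assay table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  raw <- siderophore_score(assays$a630, assays$a630_ref, assays$od600)
  assays$siderophore_raw <- raw
  assays$siderophore <- if (standardize) standardize_min_zero(raw) else raw
  assays
}
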