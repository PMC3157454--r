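#' Seed coat minus tissue expression difference
#'
#' Per-gene difference (log2 scale) between reference seed-coat expression
#' and expression in the profiled tissue. Large positive values mark genes so
#' much more abundant in the (diploid, maternal) seed coat that dissection
#' carryover can make them look maternally biased. Missing reference data
#' propagates as `NA`.
#'
#' @param ref Reference expression data frame with columns `gene_id`,
#'   `seed_coat`, `endosperm`, `embryo` (log2 scale).
#' @param tissue The profiled tissue: `"endosperm"` or `"embryo"`.
#' @return Named numeric vector of differences (names are gene ids).
#' @export
seedcoat_difference <- function(ref, tissue = c("endosperm", "embryo")) {
  tissue <- match.arg(tissue)
  stats::setNames(ref$seed_coat - ref[[tissue]], ref$gene_id)
}

#' Default seed-coat contamination threshold
#'
#' The fixed log2 seed coat minus endosperm cutoff (approximately two-fold)
#' above which a maternally biased call is attributed to seed-coat
#' carryover.
#' @export
SEEDCOAT_THRESHOLD_DEFAULT <- 1.04

#' Derive a contamination threshold from candidate PEG differences
#'
#' Paternally expressed candidates cannot be created by maternal
#' contamination, so the spread of *their* seed coat minus tissue differences
#' calibrates how large a difference is still compatible with a genuine
#' signal: the threshold is the 95th percentile of the candidate-PEG
#' differences (linear-interpolation percentile). The fixed default
#' [SEEDCOAT_THRESHOLD_DEFAULT] is preferred when fewer than 20 candidate
#' PEGs have reference data, where the percentile is unstable.
#'
#' @param peg_differences Differences (from [seedcoat_difference()]) of the
#'   candidate PEGs at the p-value stage; `NA`s dropped.
#' @param probs Percentile to take (default 0.95).
#' @return The threshold.
#' @export
derive_seedcoat_threshold <- function(peg_differences, probs = 0.95) {
  d <- peg_differences[!is.na(peg_differences)]
  if (length(d) == 0) stop("no candidate PEG differences available")
  stats::quantile(d, probs, names = FALSE, type = 7)
}

#' Remove likely seed-coat contaminated genes from the MEG candidates
#'
#' One-sided filter: maternally biased candidates whose seed coat minus
#' tissue difference exceeds the threshold (strictly greater) are demoted to
#' `not_imprinted` with `filter_reason = "seed_coat"`. Paternally biased
#' candidates are never touched (maternal contamination cannot fake them),
#' and genes lacking reference data are retained. The filter is idempotent.
#'
#' @param results Results table from [imprinting_results()].
#' @param ref Reference expression table (see [seedcoat_difference()]).
#' @param tissue The profiled tissue.
#' @param threshold Log2 difference cutoff; default the fixed
#'   [SEEDCOAT_THRESHOLD_DEFAULT].
#' @return `results` with added columns `seedcoat_diff` and `filter_reason`,
#'   and MEG calls above the threshold demoted.
#' @export
apply_seedcoat_filter <- function(results, ref,
                                  tissue = c("endosperm", "embryo"),
                                  threshold = SEEDCOAT_THRESHOLD_DEFAULT) {
  tissue <- match.arg(tissue)
  diffs <- seedcoat_difference(ref, tissue)
  results$seedcoat_diff <- unname(diffs[results$gene_id])
  if (is.null(results$filter_reason)) {
    results$filter_reason <- NA_character_
  }
  drop <- results$call == "MEG" & !is.na(results$seedcoat_diff) &
    results$seedcoat_diff > threshold
  results$call[drop] <- "not_imprinted"
  results$filter_reason[drop] <- "seed_coat"
  results
}
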