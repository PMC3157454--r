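#' Classify genes as MEGs, PEGs, cis-dominant, low-information, or biallelic
#'
#' Applies the full calling criteria to a results table (see
#' [imprinting_results()]): genes with fewer than `min_informative` reads are
#' `low_info`; genes passing the p-value and imprinting-factor cutoffs become
#' candidates; candidates whose strain cis effect is significant, large, and
#' larger than the imprinting factor are excluded as `cis_dominant`; the
#' remaining candidates are called `MEG` or `PEG` by the direction of the
#' confident allelic fold; everything else is `not_imprinted`. All thresholds
#' are inclusive (`>= 15` reads, factor `>= 2`).
#'
#' @param results Data frame with columns `n_informative`, `p_imprint`,
#'   `q_imprint`, `imprinting_factor`, `direction`, `q_cis`, `cis_factor`.
#' @param cfg A [criteria_config()].
#' @return Character vector of calls, one per row.
#' @export
classify_imprinting <- function(results, cfg = criteria_config()) {
  p_crit <- if (cfg$use_q) results$q_imprint else results$p_imprint
  call <- rep("not_imprinted", nrow(results))
  candidate <- !is.na(p_crit) & p_crit < cfg$alpha &
    results$imprinting_factor >= cfg$min_if
  cis_dom <- candidate &
    !is.na(results$q_cis) & results$q_cis < cfg$cis_alpha &
    results$cis_factor >= cfg$cis_min_factor &
    results$cis_factor > results$imprinting_factor
  call[candidate & !cis_dom & results$direction == "maternal"] <- "MEG"
  call[candidate & !cis_dom & results$direction == "paternal"] <- "PEG"
  call[cis_dom] <- "cis_dominant"
  call[results$n_informative < cfg$min_informative] <- "low_info"
  call
}

#' Per-gene imprinting statistics for a reciprocal count table
#'
#' The core analysis stage: for every gene in a reciprocal allelic count table
#' it computes the exact imprinting p-value against the tissue null, BH
#' q-values, the imprinting factor and its direction, the cis-effect p/q and
#' factor, percent maternal transcripts, and the final call. BH correction is
#' applied across the genes that meet the informative-read filter (the tested
#' universe); low-information genes keep their raw p-values but `NA`
#' q-values.
#'
#' @param counts Data frame with columns `gene_id`, `colxler_col`,
#'   `colxler_ler`, `lerxcol_col`, `lerxcol_ler` (allelic read counts per
#'   reciprocal cross).
#' @param tissue `"endosperm"` or `"embryo"`.
#' @param cfg A [criteria_config()].
#' @param stat Extremity ordering passed to [exact_two_binomial_test()].
#' @return Data frame with one row per gene: the four counts, `n_informative`,
#'   `percent_maternal`, `p_imprint`, `q_imprint`, `imprinting_factor`,
#'   `direction`, `p_cis`, `q_cis`, `cis_factor`, `call`.
#' @examples
#' counts <- data.frame(
#'   gene_id = c("g1", "g2"),
#'   colxler_col = c(129, 40), colxler_ler = c(0, 20),
#'   lerxcol_col = c(9, 42), lerxcol_ler = c(77, 19)
#' )
#' imprinting_results(counts, tissue = "endosperm")
#' @export
imprinting_results <- function(counts, tissue = c("endosperm", "embryo"),
                               cfg = criteria_config(),
                               stat = c("per_copy", "deviation")) {
  tissue <- match.arg(tissue)
  stat <- match.arg(stat)
  req <- c("gene_id", "colxler_col", "colxler_ler", "lerxcol_col",
           "lerxcol_ler")
  if (!all(req %in% names(counts))) {
    stop("counts must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(counts$gene_id)) {
    stop("duplicate gene_id in count table")
  }
  null <- null_spec(tissue)
  n <- nrow(counts)
  a1 <- counts$colxler_col
  b1 <- counts$colxler_ler
  a2 <- counts$lerxcol_col
  b2 <- counts$lerxcol_ler
  n1 <- a1 + b1
  n2 <- a2 + b2
  p_imp <- p_cis <- imf <- cisf <- pmat <- numeric(n)
  dir <- character(n)
  for (g in seq_len(n)) {
    p_imp[g] <- exact_two_binomial_test(a1[g], n1[g], a2[g], n2[g],
                                        null = null, stat = stat)
    f <- imprinting_factor(a1[g], b1[g], a2[g], b2[g], null, cfg)
    imf[g] <- f$factor
    dir[g] <- f$direction
    ct <- cis_test(a1[g], b1[g], a2[g], b2[g], null, cfg)
    p_cis[g] <- ct$p
    cisf[g] <- ct$factor
    pmat[g] <- if (n1[g] + n2[g] > 0) {
      round(100 * (a1[g] + b2[g]) / (n1[g] + n2[g]), 1)
    } else {
      NA_real_
    }
  }
  tested <- n1 + n2 >= cfg$min_informative
  q_imp <- q_cis <- rep(NA_real_, n)
  q_imp[tested] <- bh_adjust(p_imp[tested])
  q_cis[tested] <- bh_adjust(p_cis[tested])
  res <- data.frame(
    gene_id = counts$gene_id,
    colxler_col = a1, colxler_ler = b1,
    lerxcol_col = a2, lerxcol_ler = b2,
    n_informative = n1 + n2,
    percent_maternal = pmat,
    p_imprint = p_imp, q_imprint = q_imp,
    imprinting_factor = imf, direction = dir,
    p_cis = p_cis, q_cis = q_cis, cis_factor = cisf,
    stringsAsFactors = FALSE
  )
  res$call <- classify_imprinting(res, cfg)
  res
}
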