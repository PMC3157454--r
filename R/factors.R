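#' Calling criteria for imprinted genes
#'
#' The thresholds used to call a gene imprinted: raw imprinting p-value below
#' `alpha`, at least `min_informative` informative reads with the reciprocal
#' crosses combined, an imprinting factor of at least `min_if`, and exclusion
#' of genes whose strain cis effect dominates (BH-adjusted cis q-value below
#' `cis_alpha`, cis factor at least `cis_min_factor` and larger than the
#' imprinting factor). `z` is the normal quantile of the confidence level used
#' by the factor construction (1.96 for 95% intervals); `pseudocount` is the
#' Haldane correction added to each dosage-adjusted count. `use_q` switches
#' the `alpha` cutoff from the raw p-value (default, with q-values reported
#' alongside) to the BH-adjusted q-value.
#'
#' @param alpha Imprinting p-value cutoff.
#' @param min_informative Minimum informative reads, both crosses combined
#'   (inclusive).
#' @param min_if Minimum imprinting factor (inclusive).
#' @param cis_alpha Cis q-value cutoff for the cis-dominance exclusion.
#' @param cis_min_factor Minimum cis factor for the cis-dominance exclusion.
#' @param z Normal quantile for the confidence-bound factors.
#' @param pseudocount Haldane pseudocount added after dosage adjustment.
#' @param use_q Apply `alpha` to BH-adjusted q-values instead of raw p-values.
#' @return A list of class `criteria_config`.
#' @export
criteria_config <- function(alpha = 0.01, min_informative = 15, min_if = 2,
                            cis_alpha = 0.01, cis_min_factor = 2,
                            z = 1.96, pseudocount = 0.5, use_q = FALSE) {
  vals <- c(alpha, min_informative, min_if, cis_alpha, cis_min_factor, z,
            pseudocount)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all criteria must be positive and finite")
  }
  structure(
    list(alpha = alpha, min_informative = min_informative, min_if = min_if,
         cis_alpha = cis_alpha, cis_min_factor = cis_min_factor, z = z,
         pseudocount = pseudocount, use_q = isTRUE(use_q)),
    class = "criteria_config"
  )
}

# Dosage-adjusted, pseudocounted cell counts shared by the imprinting and cis
# factors. In the endosperm the maternal count of each cross (Col in ColxLer,
# Ler in LerxCol) is halved so that the null Col:Ler ratio is centred at 1 in
# both crosses; the pseudocount is added afterwards so the null log-ratio
# stays centred at 0.
.adjusted_counts <- function(a1, b1, a2, b2, null, pseudocount) {
  if (null$tissue == "endosperm") {
    a1 <- a1 / 2
    b2 <- b2 / 2
  }
  list(a1 = a1 + pseudocount, b1 = b1 + pseudocount,
       a2 = a2 + pseudocount, b2 = b2 + pseudocount)
}

#' Imprinting factor: confident fold-difference of allelic ratios
#'
#' Quantifies the magnitude of imprinting independently of read depth: the
#' confident (lower 95% bound) fold-difference between the Col:Ler read ratio
#' in one cross and in its reciprocal. Maternal counts are first
#' dosage-adjusted (halved in endosperm), the Haldane pseudocount is added,
#' and a normal (Katz-type) confidence interval is taken on the log ratio of
#' ratios: with `r1 = a1'/b1'` and `r2 = a2'/b2'`,
#' `factor = exp(|log(r1/r2)| - z * SE)` where
#' `SE = sqrt(1/a1' + 1/b1' + 1/a2' + 1/b2')`. A factor of at least 2 means
#' high confidence that the Col:Ler ratio is at least twice as large in one
#' reciprocal hybrid as in the other. Genes with all reads in a single cross
#' (`n1 == 0` or `n2 == 0`) get factor 0: a single cross cannot separate
#' imprinting from a strain effect.
#'
#' @param a1,b1 Col and Ler reads in the Col x Ler cross.
#' @param a2,b2 Col and Ler reads in the Ler x Col cross.
#' @param null A [null_spec()] carrying the tissue dosage.
#' @param cfg A [criteria_config()] (for `z` and `pseudocount`).
#' @return List with `factor` (>= 0) and `direction` (`"maternal"`,
#'   `"paternal"` or `"none"`).
#' @examples
#' # deep but weak bias: confident fold only ~1.3
#' imprinting_factor(4925, 2893, 2893, 4925, null_spec("endosperm"))
#' @export
imprinting_factor <- function(a1, b1, a2, b2,
                              null = null_spec("endosperm"),
                              cfg = criteria_config()) {
  if (a1 + b1 == 0 || a2 + b2 == 0) {
    return(list(factor = 0, direction = "none"))
  }
  ad <- .adjusted_counts(a1, b1, a2, b2, null, cfg$pseudocount)
  r1 <- ad$a1 / ad$b1
  r2 <- ad$a2 / ad$b2
  l <- abs(log(r1 / r2))
  se <- sqrt(1 / ad$a1 + 1 / ad$b1 + 1 / ad$a2 + 1 / ad$b2)
  dir <- if (r1 > r2) "maternal" else if (r1 < r2) "paternal" else "none"
  list(factor = max(0, exp(l - cfg$z * se)), direction = dir)
}

#' Cis-effect test and factor
#'
#' A strain (cis) effect raises one accession's allele in *both* crosses,
#' whereas imprinting raises the maternal allele in both. Under no cis effect
#' the maternal read fraction is the same in the two crosses whatever the
#' degree of imprinting, so the cis p-value compares the maternal fractions
#' `a1/n1` (Col reads when Col is mother) and `b2/n2` (Ler reads when Ler is
#' mother) with the pooled-mode exact test. The cis factor is the confident
#' geometric-mean Col:Ler fold across the two crosses, computed from the same
#' dosage-adjusted pseudocounted counts as the imprinting factor:
#' `exp(|log(r1 * r2)| / 2 - z * SE / 2)`.
#'
#' @inheritParams imprinting_factor
#' @return List with `p` and `factor`.
#' @examples
#' # pure imprinting, perfectly reciprocal: no cis signal
#' cis_test(90, 10, 10, 90, null_spec("embryo"))
#' @export
cis_test <- function(a1, b1, a2, b2,
                     null = null_spec("endosperm"),
                     cfg = criteria_config()) {
  n1 <- a1 + b1
  n2 <- a2 + b2
  p <- exact_two_binomial_test(a1, n1, b2, n2, null = "pooled")
  if (n1 == 0 || n2 == 0) {
    return(list(p = p, factor = 0))
  }
  ad <- .adjusted_counts(a1, b1, a2, b2, null, cfg$pseudocount)
  l <- abs(log((ad$a1 / ad$b1) * (ad$a2 / ad$b2)))
  se <- sqrt(1 / ad$a1 + 1 / ad$b1 + 1 / ad$a2 + 1 / ad$b2)
  list(p = p, factor = max(0, exp(l / 2 - cfg$z * se / 2)))
}

#' Percent maternal transcripts
#'
#' Percentage of informative reads (reciprocal crosses combined) derived from
#' the maternal allele: `100 * (a1 + b2) / (a1 + b1 + a2 + b2)`, reported to
#' one decimal. Percent paternal is its complement. Genes with no informative
#' reads return `NA` with a warning.
#'
#' @inheritParams imprinting_factor
#' @return Percent maternal in `[0, 100]`, rounded to one decimal.
#' @examples
#' percent_maternal(142, 1898, 0, 0) # wholly maternal-free cross 2 absent
#' @export
percent_maternal <- function(a1, b1, a2, b2) {
  total <- a1 + b1 + a2 + b2
  if (total == 0) {
    warning("no informative reads; percent maternal undefined")
    return(NA_real_)
  }
  round(100 * (a1 + b2) / total, 1)
}
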