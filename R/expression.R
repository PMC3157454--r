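#' Reads per kilobase per million mapped reads
#'
#' `rpkm = 1e9 * count / (length * total)`: the read count normalised by exon
#' union length (bp) and by the library's total uniquely mapped reads.
#' Vectorised over genes.
#'
#' @param count Reads mapping uniquely to the gene.
#' @param gene_length_bp Exon union length in bp (> 0).
#' @param total_mapped_reads Library total of uniquely mapped reads (> 0).
#' @return RPKM values.
#' @examples
#' rpkm(1000, 1000, 1e6) # 1000
#' @export
rpkm <- function(count, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp <= 0)) stop("gene length must be positive")
  if (any(total_mapped_reads <= 0)) stop("total mapped reads must be positive")
  1e9 * count / (gene_length_bp * total_mapped_reads)
}

#' Upper-quartile library scaling factors
#'
#' The 75th percentile of each library's per-gene read counts, computed over
#' the genes with a nonzero count in at least one of the two libraries
#' (all-zero genes say nothing about sequencing depth). Percentiles use
#' linear interpolation between order statistics ([stats::quantile()] type
#' 7).
#'
#' @param counts_lib1,counts_lib2 Equal-length per-gene count vectors.
#' @return Numeric vector `c(q75_1, q75_2)`.
#' @export
upper_quartile <- function(counts_lib1, counts_lib2) {
  if (length(counts_lib1) != length(counts_lib2)) {
    stop("count vectors must have equal length")
  }
  keep <- counts_lib1 > 0 | counts_lib2 > 0
  if (!any(keep)) stop("all genes have zero counts in both libraries")
  c(
    stats::quantile(counts_lib1[keep], 0.75, names = FALSE, type = 7),
    stats::quantile(counts_lib2[keep], 0.75, names = FALSE, type = 7)
  )
}

#' Fisher's exact test for differential expression with upper-quartile
#' normalisation
#'
#' Compares a gene's read-count ratio across two libraries to the ratio of
#' the libraries' 75th-percentile counts: a two-sided Fisher's exact test on
#' the 2x2 table `[[c1, c2], [round(q75_1 * S), round(q75_2 * S)]]`, where
#' the common scale `S` makes the reference-row entries integral and of
#' magnitude about `ref_scale` (a documented sensitivity knob: the reference
#' row plays the role of a pseudo-library whose counts sit exactly at the
#' null ratio). Direction is the sign of the difference of
#' upper-quartile-normalised counts.
#'
#' @param c1,c2 The gene's read counts in the two libraries (vectorised).
#' @param q75_1,q75_2 Upper quartiles from [upper_quartile()] (> 0).
#' @param ref_scale Target magnitude of the reference-row entries.
#' @return Data frame with `p_de` and `direction` (+1 higher in library 1,
#'   -1 higher in library 2, 0 equal).
#' @export
fisher_de <- function(c1, c2, q75_1, q75_2, ref_scale = 1000) {
  if (q75_1 <= 0 || q75_2 <= 0) stop("upper quartiles must be positive")
  s <- 2 * ref_scale / (q75_1 + q75_2)
  r1 <- round(q75_1 * s)
  r2 <- round(q75_2 * s)
  p <- mapply(function(x, y) {
    stats::fisher.test(matrix(c(x, y, r1, r2), nrow = 2,
                              byrow = TRUE))$p.value
  }, c1, c2)
  data.frame(
    p_de = pmin(1, p),
    direction = sign(c1 / q75_1 - c2 / q75_2)
  )
}

#' Differential expression factor
#'
#' Confident lower bound on the upper-quartile-normalised fold change
#' between two libraries, constructed like the imprinting and cis factors:
#' `exp(|log((c1 + 0.5) / (c2 + 0.5) * q75_2 / q75_1)| - z * SE)` with
#' `SE = sqrt(1/(c1 + 0.5) + 1/(c2 + 0.5))`. Values below 1 mean no
#' confident fold difference.
#'
#' @inheritParams fisher_de
#' @param z Normal quantile of the confidence level (1.96 for 95%).
#' @return The factor (>= 0), vectorised.
#' @export
de_factor <- function(c1, c2, q75_1, q75_2, z = 1.96) {
  a <- c1 + 0.5
  b <- c2 + 0.5
  l <- abs(log(a / b * q75_2 / q75_1))
  se <- sqrt(1 / a + 1 / b)
  pmax(0, exp(l - z * se))
}

#' Between-library expression correlation
#'
#' Reporting utility: Pearson or Spearman correlation between two libraries'
#' per-gene expression values (RPKM or counts), over genes expressed in at
#' least one library.
#'
#' @param x,y Per-gene expression vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return The correlation coefficient.
#' @export
library_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- (x > 0 | y > 0) & !is.na(x) & !is.na(y)
  stats::cor(x[keep], y[keep], method = method)
}
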