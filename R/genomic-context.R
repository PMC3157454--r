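#' Associate genes with differentially methylated regions
#'
#' A gene is DMR-associated if any DMR intersects the gene body extended by
#' `flank_bp` on both sides (the regulatory neighbourhood: within the gene or
#' 2 kb 5' or 3' by default). Strand is ignored.
#'
#' @param genes A [GenomicRanges::GRanges] of gene bodies (names or a
#'   `gene_id` column identify genes).
#' @param dmrs A `GRanges` of DMR intervals.
#' @param flank_bp Flank in bp added to each side of the gene.
#' @return Logical vector, one per gene.
#' @export
associate_dmrs <- function(genes, dmrs, flank_bp = 2000) {
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(
      pmax(1L, GenomicRanges::start(genes) - flank_bp),
      GenomicRanges::end(genes) + flank_bp
    )
  )
  # disjoint chromosome sets between genes and DMRs are legitimate input
  lv <- union(GenomeInfoDb::seqlevels(ext), GenomeInfoDb::seqlevels(dmrs))
  GenomeInfoDb::seqlevels(ext) <- lv
  GenomeInfoDb::seqlevels(dmrs) <- lv
  IRanges::overlapsAny(ext, dmrs, ignore.strand = TRUE)
}

#' DMR enrichment of imprinted genes over random informative gene sets
#'
#' Compares the number of imprinted genes associated with DMRs to the
#' association count of randomly drawn gene sets of the same size from the
#' informative universe (genes with enough allele-informative coverage to
#' have been testable). The expected count is the mean over `n_draws` seeded
#' draws; the fold is observed over expected; significance is a two-sided
#' Fisher's exact test on
#' `[[assoc_imprinted, non_assoc_imprinted], [assoc_random,
#' non_assoc_random]]` with the random row rounded to the nearest integer.
#'
#' @param imprinted_ids Character vector of imprinted gene ids.
#' @param universe A `GRanges` of the informative universe with a `gene_id`
#'   metadata column (must contain the imprinted genes).
#' @param dmrs A `GRanges` of DMRs.
#' @param flank_bp Flank passed to [associate_dmrs()].
#' @param n_draws Number of random draws.
#' @param seed RNG seed for the draws.
#' @return List with `n_assoc`, `expected`, `fold`, and `p` (Fisher).
#' @export
dmr_enrichment <- function(imprinted_ids, universe, dmrs, flank_bp = 2000,
                           n_draws = 1000, seed = 1L) {
  assoc <- associate_dmrs(universe, dmrs, flank_bp)
  ids <- universe$gene_id
  if (!all(imprinted_ids %in% ids)) {
    stop("imprinted genes missing from the informative universe")
  }
  k <- length(imprinted_ids)
  n_assoc <- sum(assoc[ids %in% imprinted_ids])
  set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(i) {
    sum(assoc[sample.int(length(ids), k)])
  }, numeric(1))
  expected <- mean(draws)
  tab <- matrix(c(n_assoc, k - n_assoc,
                  round(expected), k - round(expected)),
                nrow = 2, byrow = TRUE)
  list(
    n_assoc = n_assoc,
    expected = expected,
    fold = if (expected > 0) n_assoc / expected else Inf,
    p = stats::fisher.test(tab)$p.value
  )
}

#' Find mini-clusters of imprinted genes
#'
#' Single-linkage chaining: imprinted genes whose gene bodies lie within
#' `window_bp` of one another (boundary-to-boundary distance) join the same
#' cluster; clusters of two or more genes are reported. When the informative
#' universe is supplied, a cluster is flagged `adjacent` if no other
#' informative gene starts strictly between its members (imprinted
#' neighbours with nothing testable in between). Output is invariant to the
#' input ordering.
#'
#' @param imprinted A `GRanges` of imprinted gene bodies with a `gene_id`
#'   column.
#' @param window_bp Maximum gap between cluster members (inclusive).
#' @param informative Optional `GRanges` of the informative universe with
#'   `gene_id`.
#' @return Data frame with `cluster_id`, `chrom`, `start`, `end`, `n_genes`,
#'   `gene_ids` (comma-separated, in genomic order), `adjacent`.
#' @export
find_miniclusters <- function(imprinted, window_bp = 10000,
                              informative = NULL) {
  if (length(imprinted) == 0) {
    return(data.frame(cluster_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_genes = integer(0), gene_ids = character(0),
                      adjacent = logical(0)))
  }
  g <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(imprinted),
                           ignore.strand = TRUE)
  merged <- GenomicRanges::reduce(g, min.gapwidth = window_bp + 1L,
                                  with.revmap = TRUE, ignore.strand = TRUE)
  keep <- lengths(merged$revmap) >= 2L
  merged <- merged[keep]
  if (length(merged) == 0) {
    return(data.frame(cluster_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_genes = integer(0), gene_ids = character(0),
                      adjacent = logical(0)))
  }
  rows <- lapply(seq_along(merged), function(i) {
    members <- g[merged$revmap[[i]]]
    adjacent <- NA
    if (!is.null(informative)) {
      other <- informative[!informative$gene_id %in% members$gene_id]
      # informative gene starting strictly inside the cluster span breaks
      # adjacency
      inside <- as.character(GenomicRanges::seqnames(other)) ==
        as.character(GenomicRanges::seqnames(merged))[i] &
        GenomicRanges::start(other) > min(GenomicRanges::start(members)) &
        GenomicRanges::start(other) < max(GenomicRanges::start(members))
      adjacent <- !any(inside)
    }
    data.frame(
      cluster_id = i,
      chrom = as.character(GenomicRanges::seqnames(merged))[i],
      start = GenomicRanges::start(merged)[i],
      end = GenomicRanges::end(merged)[i],
      n_genes = length(members),
      gene_ids = paste(members$gene_id, collapse = ","),
      adjacent = adjacent,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
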