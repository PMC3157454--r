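#' Read a Col/Ler SNP table
#'
#' Reads a tab-separated SNP table with columns `chrom`, `pos` (1-based),
#' `col_base`, `ler_base`, and optionally `consensus_fraction` (the fraction
#' of base calls supporting the Ler consensus in the source resequencing
#' data; missing values allowed). Positions stay 1-based in the returned
#' table; conversion to internal 0-based half-open coordinates happens at the
#' point of use.
#'
#' @param path Path to the TSV.
#' @return Data frame of SNP records.
#' @export
read_snp_table <- function(path) {
  snps <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "col_base", "ler_base")
  if (!all(req %in% names(snps))) {
    stop("SNP table must have columns: ", paste(req, collapse = ", "))
  }
  if (!"consensus_fraction" %in% names(snps)) {
    snps$consensus_fraction <- NA_real_
  }
  bad <- !(snps$col_base %in% c("A", "C", "G", "T")) |
    !(snps$ler_base %in% c("A", "C", "G", "T")) |
    snps$col_base == snps$ler_base
  if (any(bad)) {
    stop(sum(bad), " SNP record(s) with invalid or identical alleles")
  }
  snps
}

#' Filter SNPs by resequencing consensus support
#'
#' Removes SNPs whose known Ler consensus support is below `min_consensus`
#' (boundary inclusive: exactly 95% support is retained). SNPs with missing
#' consensus information are retained.
#'
#' @param snps SNP data frame (see [read_snp_table()]).
#' @param min_consensus Minimum consensus fraction, default 0.95.
#' @return The filtered SNP data frame.
#' @examples
#' snps <- data.frame(chrom = "Chr1", pos = 1:3,
#'                    col_base = "A", ler_base = "C",
#'                    consensus_fraction = c(0.94, 0.95, NA))
#' filter_snps(snps)$pos # 0.94 dropped, 0.95 and unknown kept
#' @export
filter_snps <- function(snps, min_consensus = 0.95) {
  keep <- is.na(snps$consensus_fraction) |
    snps$consensus_fraction >= min_consensus
  snps[keep, , drop = FALSE]
}

#' Read gene models from GFF3 or BED
#'
#' Imports gene models and returns exons grouped per gene as a
#' [GenomicRanges::GRangesList]. For GFF3, features of type `exon` are
#' grouped by their `gene_id` attribute (falling back to `Parent`, then
#' `ID`); GFF3 coordinates are 1-based inclusive and BED 0-based half-open,
#' both handled by the importer. For BED12, block structure defines the
#' exons. Exons are unioned per gene, so the `length` attribute is the exon
#' union length used for RPKM.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @return A `GRangesList` of reduced exons, one element per gene.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "exon"]
    ids <- if (!is.null(gr$gene_id)) {
      as.character(gr$gene_id)
    } else if (!is.null(gr$Parent) && all(lengths(gr$Parent) > 0)) {
      vapply(gr$Parent, `[[`, character(1), 1L)
    } else {
      as.character(gr$ID)
    }
    genes <- GenomicRanges::split(gr, ids)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
    blocks <- if (!is.null(gr$blocks)) {
      rtracklayer::blocks(gr)
    } else {
      GenomicRanges::split(gr, seq_along(gr))
    }
    names(blocks) <- ids
    genes <- blocks
  } else {
    stop("unsupported gene-model format: .", ext)
  }
  GenomicRanges::reduce(genes)
}

#' Classify one read from its bases at overlapped SNPs
#'
#' The all-SNPs-agree rule: a read is `Col` only if every overlapped SNP
#' shows the Col base, `Ler` only if every one shows the Ler base; a read
#' overlapping no SNP is `ambiguous`; any mixture, or a third allele at any
#' SNP, makes the read `conflicting` (conservative: a non-matching base is
#' treated as disagreement, not ignored). Bases that are not resolved
#' (positions under deletions or splice gaps) are skipped.
#'
#' @param bases Character vector of the read's base at each overlapped SNP.
#' @param col_base,ler_base The strain alleles at those SNPs.
#' @return One of `"Col"`, `"Ler"`, `"ambiguous"`, `"conflicting"`.
#' @export
classify_read <- function(bases, col_base, ler_base) {
  resolved <- bases %in% c("A", "C", "G", "T")
  bases <- bases[resolved]
  col_base <- col_base[resolved]
  ler_base <- ler_base[resolved]
  if (length(bases) == 0) {
    return("ambiguous")
  }
  if (all(bases == col_base)) {
    return("Col")
  }
  if (all(bases == ler_base)) {
    return("Ler")
  }
  "conflicting"
}

#' Count Col/Ler reads per gene from a SAM file
#'
#' Classifies every uniquely mapping, single-gene read as Col, Ler,
#' ambiguous (no SNP overlap), or conflicting (SNP disagreement), and tallies
#' the four classes per gene. Mapping uniqueness is approximated at the SAM
#' level by a mapping-quality floor (reads with `MAPQ > mapq_floor` are kept;
#' multi-mappers receive MAPQ 0 from most aligners). Reads whose aligned
#' blocks (CIGAR match segments, so spliced alignments are respected)
#' intersect the exon union of more than one gene are excluded. Reads on
#' chromosomes absent from the gene models are skipped with a warning.
#'
#' @param sam_path Path to a SAM (or BAM) file.
#' @param gene_models `GRangesList` of exons per gene (see
#'   [read_gene_models()]).
#' @param snps SNP data frame (see [read_snp_table()]); apply
#'   [filter_snps()] first.
#' @param cross Cross label attached to the output (`"ColxLer"` or
#'   `"LerxCol"`).
#' @param mapq_floor Reads must have mapping quality strictly above this
#'   (default 0); missing MAPQ (255 in spec terms, `NA` here) is accepted.
#' @return Data frame with `gene_id`, `cross`, `n_col`, `n_ler`,
#'   `n_ambiguous`, `n_conflicting`, and an attribute `total_mapped`: the
#'   number of uniquely mapped reads (the RPKM denominator).
#' @export
count_alleles <- function(sam_path, gene_models, snps,
                          cross = c("ColxLer", "LerxCol"), mapq_floor = 0) {
  cross <- match.arg(cross)
  bam <- if (grepl("\\.bam$", sam_path, ignore.case = TRUE)) {
    sam_path
  } else {
    Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                     indexDestination = TRUE)
  }
  gal <- GenomicAlignments::readGAlignments(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("seq", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    )
  )
  mapq <- S4Vectors::mcols(gal)$mapq
  gal <- gal[is.na(mapq) | mapq > mapq_floor]
  total_mapped <- length(gal)

  empty <- data.frame(
    gene_id = names(gene_models), cross = cross,
    n_col = 0L, n_ler = 0L, n_ambiguous = 0L, n_conflicting = 0L,
    stringsAsFactors = FALSE
  )
  known_chroms <- unique(as.character(
    GenomicRanges::seqnames(unlist(gene_models, use.names = FALSE))
  ))
  on_known <- as.character(GenomicRanges::seqnames(gal)) %in% known_chroms
  if (any(!on_known)) {
    warning(sum(!on_known), " read(s) on chromosomes absent from the gene ",
            "models; skipped")
    gal <- gal[on_known]
  }
  if (length(gal) == 0) {
    attr(empty, "total_mapped") <- total_mapped
    return(empty)
  }

  blocks <- GenomicAlignments::grglist(gal)
  ov <- GenomicRanges::findOverlaps(blocks, gene_models, ignore.strand = TRUE)
  hits_per_read <- tabulate(S4Vectors::queryHits(ov), nbins = length(gal))
  single <- hits_per_read == 1L
  ov1 <- ov[single[S4Vectors::queryHits(ov)]]
  read_idx <- S4Vectors::queryHits(ov1)
  gene_idx <- S4Vectors::subjectHits(ov1)
  if (length(read_idx) == 0) {
    attr(empty, "total_mapped") <- total_mapped
    return(empty)
  }

  # reference-space sequences: deletions '-' and splice gaps '.' stay
  # unresolved and are skipped during classification
  ref_seq <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(gal)$seq[read_idx],
    GenomicAlignments::cigar(gal)[read_idx]
  )
  read_start <- GenomicRanges::start(gal)[read_idx]
  read_end <- GenomicRanges::end(gal)[read_idx]
  read_chrom <- as.character(GenomicRanges::seqnames(gal))[read_idx]

  snp_gr <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$pos, width = 1L)
  )
  span <- GenomicRanges::GRanges(
    read_chrom, IRanges::IRanges(read_start, read_end)
  )
  snp_ov <- GenomicRanges::findOverlaps(span, snp_gr)
  calls <- rep("ambiguous", length(read_idx))
  if (length(snp_ov) > 0) {
    r <- S4Vectors::queryHits(snp_ov)
    s <- S4Vectors::subjectHits(snp_ov)
    offset <- snps$pos[s] - read_start[r] + 1L
    base <- substr(as.character(ref_seq[r]), offset, offset)
    with_snp <- unique(r)
    base_by_read <- split(base, r)
    col_by_read <- split(snps$col_base[s], r)
    ler_by_read <- split(snps$ler_base[s], r)
    calls[with_snp] <- mapply(
      classify_read,
      base_by_read[as.character(with_snp)],
      col_by_read[as.character(with_snp)],
      ler_by_read[as.character(with_snp)]
    )
  }

  tab <- table(
    factor(names(gene_models)[gene_idx], levels = names(gene_models)),
    factor(calls, levels = c("Col", "Ler", "ambiguous", "conflicting"))
  )
  out <- data.frame(
    gene_id = rownames(tab), cross = cross,
    n_col = as.integer(tab[, "Col"]),
    n_ler = as.integer(tab[, "Ler"]),
    n_ambiguous = as.integer(tab[, "ambiguous"]),
    n_conflicting = as.integer(tab[, "conflicting"]),
    stringsAsFactors = FALSE
  )
  attr(out, "total_mapped") <- total_mapped
  out
}

#' Merge per-cross allelic counts into a reciprocal count table
#'
#' Outer join on `gene_id` of the two per-cross count tables from
#' [count_alleles()]; genes absent from one cross get zero counts there.
#' Cross 1 must be Col x Ler (Col mother) and cross 2 Ler x Col, so the
#' maternal read total of a gene is `colxler_col + lerxcol_ler`.
#'
#' @param counts_colxler,counts_lerxcol Per-cross tables with `gene_id`,
#'   `n_col`, `n_ler`.
#' @return Data frame with `gene_id`, `colxler_col`, `colxler_ler`,
#'   `lerxcol_col`, `lerxcol_ler`.
#' @export
merge_reciprocal <- function(counts_colxler, counts_lerxcol) {
  for (tb in list(counts_colxler, counts_lerxcol)) {
    if (anyDuplicated(tb$gene_id)) {
      stop("duplicate gene_id within one count table")
    }
  }
  m <- merge(
    counts_colxler[, c("gene_id", "n_col", "n_ler")],
    counts_lerxcol[, c("gene_id", "n_col", "n_ler")],
    by = "gene_id", all = TRUE, suffixes = c("_1", "_2")
  )
  m[is.na(m)] <- 0L
  data.frame(
    gene_id = m$gene_id,
    colxler_col = m$n_col_1, colxler_ler = m$n_ler_1,
    lerxcol_col = m$n_col_2, lerxcol_ler = m$n_ler_2,
    stringsAsFactors = FALSE
  )
}
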