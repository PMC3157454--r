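#' Simulate a toy two-accession genome with genes and SNPs
#'
#' Builds a small single-chromosome reference (the Col accession), spliced
#' two-exon gene models, and a table of Col/Ler SNPs placed inside the first
#' exon of each gene (one substitution per site, 100 bp apart so a short read
#' covers at most one). Used to exercise the read-classification stage end to
#' end; no attempt is made to model realistic transcript structure, sequencing
#' error, or quality scores.
#'
#' @param n_genes Number of genes.
#' @param chrom Chromosome name.
#' @param exon_len,intron_len,spacing Gene geometry in bp.
#' @param snps_per_gene SNPs per gene (1 to 3), at offsets 50, 150, 250 of
#'   exon 1.
#' @param seed RNG seed for the reference sequence.
#' @return List with `seq` (a [Biostrings::DNAStringSet]), `genes` (a
#'   [GenomicRanges::GRangesList] of exons per gene), and `snps` (data frame
#'   `chrom`, `pos` (1-based), `col_base`, `ler_base`, `consensus_fraction`).
#' @export
simulate_genome <- function(n_genes = 4, chrom = "Chr1", exon_len = 300,
                            intron_len = 150, spacing = 1000,
                            snps_per_gene = 3, seed = 1L) {
  stopifnot(n_genes >= 1, snps_per_gene >= 1, snps_per_gene <= 3)
  set.seed(seed)
  gene_span <- 2L * exon_len + intron_len
  chrom_len <- n_genes * (gene_span + spacing) + spacing
  seq <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE), collapse = ""
  ))
  names(seq) <- chrom
  starts1 <- spacing + (seq_len(n_genes) - 1L) * (gene_span + spacing) + 1L
  gene_ids <- sprintf("GENE%03d", seq_len(n_genes))
  exons <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(
      start = c(starts1, starts1 + exon_len + intron_len),
      width = exon_len
    ),
    gene_id = rep(gene_ids, 2L)
  )
  genes <- GenomicRanges::split(exons, exons$gene_id)
  offsets <- c(50L, 150L, 250L)[seq_len(snps_per_gene)]
  pos <- as.integer(outer(offsets, starts1 - 1L, "+"))
  ref_base <- strsplit(as.character(Biostrings::subseq(
    rep(seq, length(pos)), start = pos, width = 1L
  )), "")
  col_base <- vapply(ref_base, identity, character(1))
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  list(
    seq = seq,
    genes = genes,
    snps = data.frame(
      chrom = chrom, pos = pos, col_base = col_base,
      ler_base = unname(flip[col_base]),
      consensus_fraction = NA_real_,
      stringsAsFactors = FALSE
    )
  )
}

#' Write toy genome reference files
#'
#' Writes the FASTA reference, a GFF3 of exon features (each carrying a
#' `gene_id` attribute), and the SNP TSV for a [simulate_genome()] genome.
#'
#' @param genome A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "reference.fa")
  gff <- file.path(dir, "genes.gff3")
  snp <- file.path(dir, "snps.tsv")
  Biostrings::writeXStringSet(genome$seq, fasta)
  exons <- unlist(genome$genes, use.names = FALSE)
  exons$type <- "exon"
  exons$source <- "imprintcall"
  rtracklayer::export(exons, gff, format = "gff3")
  utils::write.table(genome$snps, snp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(fasta = fasta, gff = gff, snps = snp)
}

# a single SAM alignment line for an unpaired, forward, fully matching read
.sam_line <- function(qname, chrom, pos, seq, mapq = 50L) {
  paste(qname, 0L, chrom, pos, mapq, paste0(nchar(seq), "M"), "*", 0L, 0L,
        seq, strrep("I", nchar(seq)), sep = "\t")
}

#' Simulate strain-labelled reads and write them as SAM
#'
#' Emits, per gene, a requested number of Col-haplotype and Ler-haplotype
#' reads (each covering exactly one SNP of exon 1), optional ambiguous reads
#' (placed in exon 2, which carries no SNP), and optional conflicting reads
#' (covering two nearby SNP positions with one Col and one Ler base; the
#' extra SNP needed for the pair is appended to the returned SNP table).
#' Classifying the written SAM with [count_alleles()] recovers the generating
#' counts exactly. SNPs falling outside every exon are skipped with a
#' warning.
#'
#' @param genome A [simulate_genome()] result.
#' @param n_col,n_ler,n_ambiguous,n_conflicting Per-gene read counts
#'   (recycled).
#' @param sam_path Output SAM path.
#' @param read_len Read length in bp (at most 100).
#' @return Invisibly, a list with `sam` (the path) and `snps` (the SNP table
#'   actually used, including any conflict-pair SNPs).
#' @export
simulate_sam_reads <- function(genome, n_col, n_ler, n_ambiguous = 0,
                               n_conflicting = 0, sam_path,
                               read_len = 36L) {
  gene_ids <- names(genome$genes)
  n_g <- length(gene_ids)
  n_col <- rep_len(n_col, n_g)
  n_ler <- rep_len(n_ler, n_g)
  n_ambiguous <- rep_len(n_ambiguous, n_g)
  n_conflicting <- rep_len(n_conflicting, n_g)
  chrom <- names(genome$seq)[1]
  chrom_len <- Biostrings::width(genome$seq)[1]

  snps <- genome$snps
  exons_all <- unlist(genome$genes, use.names = FALSE)
  snp_gr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, width = 1))
  in_exon <- IRanges::overlapsAny(snp_gr, exons_all)
  if (any(!in_exon)) {
    warning(sum(!in_exon), " SNP(s) outside any exon; skipped")
    snps <- snps[in_exon, , drop = FALSE]
  }

  ref_chr <- genome$seq[[1]]
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  read_at <- function(pos, ler_at = integer(0)) {
    s <- as.character(Biostrings::subseq(ref_chr, pos, width = read_len))
    if (length(ler_at)) {
      sp <- strsplit(s, "")[[1]]
      off <- ler_at - pos + 1L
      sp[off] <- flip[sp[off]]
      s <- paste(sp, collapse = "")
    }
    s
  }

  lines <- character(0)
  extra_snps <- list()
  rid <- 0L
  for (g in seq_len(n_g)) {
    ex <- GenomicRanges::sort(genome$genes[[g]])
    gsnps <- snps$pos[snps$pos >= GenomicRanges::start(ex)[1] &
                        snps$pos <= GenomicRanges::end(ex)[1]]
    if (length(gsnps) == 0 && (n_col[g] > 0 || n_ler[g] > 0)) {
      stop("gene ", gene_ids[g], " has no usable SNP for strain reads")
    }
    # the conflict-pair SNP must exist before strain reads are emitted so
    # that Ler-haplotype reads carry the Ler base there too
    pair_pos <- integer(0)
    if (n_conflicting[g] > 0) {
      pair_pos <- gsnps[1] + 12L
      pair_base <- as.character(Biostrings::subseq(ref_chr, pair_pos,
                                                   width = 1))
      extra_snps[[length(extra_snps) + 1L]] <- data.frame(
        chrom = chrom, pos = pair_pos, col_base = pair_base,
        ler_base = unname(flip[pair_base]), consensus_fraction = NA_real_,
        stringsAsFactors = FALSE
      )
    }
    all_pos <- c(gsnps, pair_pos)
    emit <- function(n, strain) {
      for (k in seq_len(n)) {
        rid <<- rid + 1L
        snp <- gsnps[((k - 1L) %% length(gsnps)) + 1L]
        start <- snp - 10L
        covered <- all_pos[all_pos >= start & all_pos < start + read_len]
        ler_at <- if (strain == "Ler") covered else integer(0)
        lines[[length(lines) + 1L]] <<- .sam_line(
          sprintf("%s_%s_%04d", gene_ids[g], strain, rid),
          chrom, start, read_at(start, ler_at)
        )
      }
    }
    emit(n_col[g], "Col")
    emit(n_ler[g], "Ler")
    for (k in seq_len(n_ambiguous[g])) {
      rid <- rid + 1L
      start <- GenomicRanges::start(ex)[2] + 5L + (k %% 50L)
      lines[[length(lines) + 1L]] <- .sam_line(
        sprintf("%s_amb_%04d", gene_ids[g], rid), chrom, start,
        read_at(start)
      )
    }
    # conflicting reads: Col base at SNP 1, Ler base at the pair SNP
    for (k in seq_len(n_conflicting[g])) {
      rid <- rid + 1L
      start <- gsnps[1] - 10L
      lines[[length(lines) + 1L]] <- .sam_line(
        sprintf("%s_conf_%04d", gene_ids[g], rid), chrom, start,
        read_at(start, ler_at = pair_pos)
      )
    }
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  writeLines(c(header, unlist(lines)), sam_path)
  invisible(list(
    sam = sam_path,
    snps = do.call(rbind, c(list(snps), extra_snps))
  ))
}
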