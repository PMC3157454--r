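test_that("SNP consensus filter is inclusive at the boundary", {
  snps <- data.frame(
    chrom = "Chr1", pos = 1:4, col_base = "A", ler_base = "C",
    consensus_fraction = c(0.94, 0.95, 0.999, NA)
  )
  kept <- filter_snps(snps)
  expect_equal(kept$pos, 2:4) # 0.94 removed; 0.95 and unknown retained
  expect_equal(nrow(filter_snps(snps[0, ])), 0)
})

test_that("reads are classified by the all-SNPs-agree rule", {
  expect_equal(classify_read(c("A", "G"), c("A", "G"), c("C", "T")), "Col")
  expect_equal(classify_read(c("C", "T"), c("A", "G"), c("C", "T")), "Ler")
  expect_equal(classify_read(c("A", "T"), c("A", "G"), c("C", "T")),
               "conflicting")
  # a third allele counts as disagreement, not as no information
  expect_equal(classify_read("T", "A", "C"), "conflicting")
  expect_equal(classify_read(character(0), character(0), character(0)),
               "ambiguous")
  # unresolved bases (deletion/splice gap) are skipped
  expect_equal(classify_read(c("A", "-"), c("A", "G"), c("C", "T")), "Col")
  expect_equal(classify_read(c(".", "-"), c("A", "G"), c("C", "T")),
               "ambiguous")
})

test_that("synthetic SAM round-trips to the generating counts exactly", {
  g <- simulate_genome(4, seed = 5)
  sam <- tempfile(fileext = ".sam")
  n_col <- c(12, 0, 7, 3)
  n_ler <- c(4, 9, 0, 3)
  fx <- simulate_sam_reads(g, n_col, n_ler, n_ambiguous = c(2, 0, 1, 0),
                           n_conflicting = c(1, 0, 0, 2), sam_path = sam)
  ac <- count_alleles(sam, g$genes, fx$snps, cross = "ColxLer")
  expect_equal(ac$n_col, n_col)
  expect_equal(ac$n_ler, n_ler)
  expect_equal(ac$n_ambiguous, c(2, 0, 1, 0))
  expect_equal(ac$n_conflicting, c(1, 0, 0, 2))
  # every unique single-gene read lands in exactly one class
  expect_equal(sum(ac$n_col + ac$n_ler + ac$n_ambiguous + ac$n_conflicting),
               attr(ac, "total_mapped"))
})

test_that("gene-model readers give identical exon unions for GFF3", {
  g <- simulate_genome(3, seed = 6)
  dir <- tempfile()
  paths <- write_genome_files(g, dir)
  models <- read_gene_models(paths[["gff"]])
  expect_equal(names(models), names(g$genes))
  expect_equal(sum(GenomicRanges::width(unlist(models))),
               sum(GenomicRanges::width(unlist(g$genes))))
  snps <- read_snp_table(paths[["snps"]])
  expect_equal(snps$pos, g$snps$pos)
})

test_that("zero-read SAM gives an all-zero table", {
  g <- simulate_genome(2, seed = 7)
  sam <- tempfile(fileext = ".sam")
  simulate_sam_reads(g, n_col = 0, n_ler = 0, sam_path = sam)
  ac <- count_alleles(sam, g$genes, g$snps, cross = "LerxCol")
  expect_equal(nrow(ac), 2)
  expect_true(all(ac[, c("n_col", "n_ler", "n_ambiguous",
                         "n_conflicting")] == 0))
  expect_equal(attr(ac, "total_mapped"), 0)
})

test_that("reads spanning exons of two genes are counted for neither", {
  g <- simulate_genome(2, seed = 8)
  # make an overlapping phantom gene covering gene 1's first exon
  ex1 <- GenomicRanges::sort(g$genes[[1]])[1]
  phantom <- GenomicRanges::shift(ex1, 10L)
  phantom$gene_id <- "PHANTOM"
  overlapping <- c(g$genes, GenomicRanges::GRangesList(PHANTOM = phantom))
  sam <- tempfile(fileext = ".sam")
  simulate_sam_reads(g, n_col = c(5, 4), n_ler = c(0, 0), sam_path = sam)
  ac <- count_alleles(sam, overlapping, g$snps, cross = "ColxLer")
  expect_equal(ac$n_col[ac$gene_id == "GENE001"], 0) # shared-exon reads
  expect_equal(ac$n_col[ac$gene_id == "PHANTOM"], 0)
  expect_equal(ac$n_col[ac$gene_id == "GENE002"], 4) # unaffected gene
})

test_that("reads on unknown chromosomes are skipped with a warning", {
  g <- simulate_genome(2, seed = 9)
  sam <- tempfile(fileext = ".sam")
  simulate_sam_reads(g, n_col = c(3, 2), n_ler = 0, sam_path = sam)
  lines <- readLines(sam)
  lines <- c(lines[1], "@SQ\tSN:ChrX\tLN:5000",
             lines[-1],
             sub("Chr1", "ChrX", lines[length(lines)]))
  writeLines(lines, sam)
  expect_warning(ac <- count_alleles(sam, g$genes, g$snps, "ColxLer"),
                 "absent from the gene models")
  expect_equal(sum(ac$n_col), 5)
})

test_that("merging reciprocal crosses zero-fills and checks duplicates", {
  c1 <- data.frame(gene_id = c("a", "b"), n_col = c(3, 1), n_ler = c(0, 2))
  c2 <- data.frame(gene_id = c("b", "c"), n_col = c(5, 7), n_ler = c(1, 0))
  m <- merge_reciprocal(c1, c2)
  expect_equal(m$gene_id, c("a", "b", "c"))
  expect_equal(m$colxler_col, c(3, 1, 0))
  expect_equal(m$lerxcol_ler, c(0, 1, 0))
  # maternal total identity: Col of cross 1 plus Ler of cross 2
  expect_equal(m$colxler_col + m$lerxcol_ler, c(3, 2, 0))
  dup <- data.frame(gene_id = c("a", "a"), n_col = 1, n_ler = 1)
  expect_error(merge_reciprocal(dup, c2), "duplicate")
})

test_that("SNPs outside exons are skipped with a warning", {
  g <- simulate_genome(2, seed = 10)
  g$snps <- rbind(g$snps, data.frame(chrom = "Chr1", pos = 5L,
                                     col_base = "A", ler_base = "C",
                                     consensus_fraction = NA_real_))
  sam <- tempfile(fileext = ".sam")
  expect_warning(
    fx <- simulate_sam_reads(g, n_col = c(2, 2), n_ler = 0, sam_path = sam),
    "outside any exon"
  )
  expect_false(5L %in% fx$snps$pos)
})
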