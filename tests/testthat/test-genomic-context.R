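gr_genes <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         gene_id = df$gene_id)
}

test_that("DMR association respects the flank boundary", {
  genes <- gr_genes(data.frame(chrom = "Chr1", start = 10000, end = 12000,
                               gene_id = "g"))
  inside <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(11000, 11100))
  at_flank <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(14000, 14050))
  past_flank <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(14001, 14050))
  expect_true(associate_dmrs(genes, inside))
  expect_true(associate_dmrs(genes, at_flank)) # touches end + 2000
  expect_false(associate_dmrs(genes, past_flank)) # flank + 1 past the end
  other_chrom <- GenomicRanges::GRanges("Chr2", IRanges::IRanges(11000, 11100))
  expect_false(associate_dmrs(genes, other_chrom))
})

test_that("interval association equals the naive scan on random fixtures", {
  set.seed(14)
  for (rep in 1:5) {
    genes_df <- data.frame(
      chrom = sample(c("Chr1", "Chr2"), 60, replace = TRUE),
      start = sample(1:500000, 60), gene_id = sprintf("g%02d", 1:60)
    )
    genes_df$end <- genes_df$start + sample(500:5000, 60)
    dmr_df <- data.frame(
      chrom = sample(c("Chr1", "Chr2"), 30, replace = TRUE),
      start = sample(1:500000, 30)
    )
    dmr_df$end <- dmr_df$start + sample(50:2000, 30)
    dmrs <- GenomicRanges::GRanges(dmr_df$chrom,
                                   IRanges::IRanges(dmr_df$start, dmr_df$end))
    expect_equal(associate_dmrs(gr_genes(genes_df), dmrs, flank_bp = 2000),
                 oracle_associate(genes_df, dmr_df, flank = 2000))
    # with zero flank the association is plain interval intersection
    expect_equal(associate_dmrs(gr_genes(genes_df), dmrs, flank_bp = 0),
                 oracle_associate(genes_df, dmr_df, flank = 0))
  }
})

test_that("random gene sets show no DMR enrichment", {
  set.seed(15)
  df <- data.frame(chrom = "Chr1", start = seq(1, by = 4000, length = 400),
                   gene_id = sprintf("g%03d", 1:400))
  df$end <- df$start + 2000
  universe <- gr_genes(df)
  dmrs <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(
    sample(1:1600000, 60), width = 300
  ))
  random_ids <- sample(df$gene_id, 60)
  enr <- dmr_enrichment(random_ids, universe, dmrs, n_draws = 400, seed = 99)
  expect_equal(enr$fold, 1, tolerance = 0.35)
  expect_gt(enr$p, 0.05)
  expect_error(dmr_enrichment("nope", universe, dmrs), "missing")
})

test_that("an enriched set is detected with the published-scale table", {
  # 63 of 208 imprinted vs 24 of 208 random associated genes
  p <- fisher.test(matrix(c(63, 145, 24, 184), 2, byrow = TRUE))$p.value
  expect_lt(p, 1e-4)
  expect_equal(p, oracle_fisher2x2(63, 145, 24, 184), tolerance = 1e-9)
})

test_that("mini-cluster chaining respects the 10 kb window", {
  near <- gr_genes(data.frame(chrom = "Chr1", start = c(1000, 8000),
                              end = c(3000, 9000),
                              gene_id = c("a", "b"))) # 5 kb gap
  cl <- find_miniclusters(near)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$gene_ids, "a,b")
  far <- gr_genes(data.frame(chrom = "Chr1", start = c(1000, 18001),
                             end = c(3000, 19000),
                             gene_id = c("a", "b"))) # 15 kb gap
  expect_equal(nrow(find_miniclusters(far)), 0)
  expect_equal(nrow(find_miniclusters(near[0])), 0)
})

test_that("chaining equals the transitive closure oracle, order-invariant", {
  set.seed(16)
  for (rep in 1:5) {
    df <- data.frame(
      chrom = sample(c("Chr1", "Chr2"), 40, replace = TRUE),
      start = sample(1:400000, 40), gene_id = sprintf("g%02d", 1:40)
    )
    df$end <- df$start + sample(500:3000, 40)
    cl <- find_miniclusters(gr_genes(df), window_bp = 10000)
    oracle <- Filter(function(x) length(x) >= 2,
                     oracle_clusters(df, window = 10000))
    got <- lapply(strsplit(cl$gene_ids, ","), sort)
    want <- lapply(unname(oracle), sort)
    expect_setequal(got, want)
    # shuffling the input changes nothing
    cl2 <- find_miniclusters(gr_genes(df[sample(40), ]), window_bp = 10000)
    expect_equal(cl2, cl)
  }
})

test_that("adjacency is flagged against the informative universe", {
  imprinted <- gr_genes(data.frame(chrom = "Chr1", start = c(1000, 8000),
                                   end = c(3000, 9000),
                                   gene_id = c("a", "b")))
  informative_between <- gr_genes(data.frame(
    chrom = "Chr1", start = c(1000, 4000, 8000), end = c(3000, 5000, 9000),
    gene_id = c("a", "x", "b")
  ))
  cl <- find_miniclusters(imprinted, informative = informative_between)
  expect_false(cl$adjacent)
  cl2 <- find_miniclusters(imprinted, informative = imprinted)
  expect_true(cl2$adjacent)
})
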