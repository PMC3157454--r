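test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 300, seed = 42)
  s1 <- simulate_allelic_counts(cfg)
  s2 <- simulate_allelic_counts(cfg)
  expect_identical(s1, s2)
  r1 <- simulate_reference_expression(cfg, s1$truth)
  r2 <- simulate_reference_expression(cfg, s2$truth)
  expect_identical(r1, r2)
  s3 <- simulate_allelic_counts(sim_config(n_genes = 300, seed = 43))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("informative reads per cross equal the drawn depth", {
  sim <- simulate_allelic_counts(sim_config(n_genes = 500, seed = 2,
                                            kappa = 0))
  expect_equal(sim$counts$colxler_col + sim$counts$colxler_ler,
               sim$truth$depth1)
  expect_equal(sim$counts$lerxcol_col + sim$counts$lerxcol_ler,
               sim$truth$depth2)
  # with contamination the excess is exactly the recorded carryover
  simk <- simulate_allelic_counts(sim_config(n_genes = 500, seed = 2,
                                             kappa = 0.3))
  expect_equal(simk$counts$colxler_col + simk$counts$colxler_ler,
               simk$truth$depth1 + simk$truth$contam1)
})

test_that("null endosperm genes sit near the 2:1 dosage expectation", {
  cfg <- sim_config(n_genes = 3000, frac_meg = 0, frac_peg = 0,
                    frac_cis = 0, kappa = 0, depth_mean = 80,
                    depth_size = 5, seed = 9)
  sim <- simulate_allelic_counts(cfg)
  n1 <- sim$counts$colxler_col + sim$counts$colxler_ler
  n2 <- sim$counts$lerxcol_col + sim$counts$lerxcol_ler
  frac1 <- sum(sim$counts$colxler_col) / sum(n1)
  frac2 <- sum(sim$counts$lerxcol_col) / sum(n2)
  expect_equal(frac1, 2 / 3, tolerance = 0.01)
  expect_equal(frac2, 1 / 3, tolerance = 0.01)
})

test_that("complete maternal imprinting leaves no paternal reads", {
  cfg <- sim_config(n_genes = 200, frac_meg = 1, frac_peg = 0, frac_cis = 0,
                    meg_m = c(1, 1), kappa = 0, seed = 3)
  sim <- simulate_allelic_counts(cfg)
  # cross 1 paternal allele is Ler, cross 2 paternal allele is Col
  expect_true(all(sim$counts$colxler_ler == 0))
  expect_true(all(sim$counts$lerxcol_col == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_meg = 0.7, frac_peg = 0.4), "sum")
  expect_error(sim_config(kappa = 1), "kappa")
  expect_error(sim_config(meg_m = c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("reference expression encodes the contamination structure", {
  cfg <- sim_config(n_genes = 2000, seed = 8, frac_contam = 0.15,
                    missing_frac = 0.1)
  sim <- simulate_allelic_counts(cfg)
  ref <- simulate_reference_expression(cfg, sim$truth)
  d <- seedcoat_difference(ref, "endosperm")
  contaminating <- sim$truth$contaminating & !is.na(d)
  # contaminating genes exceed the filter threshold by construction
  expect_true(all(d[contaminating] > SEEDCOAT_THRESHOLD_DEFAULT))
  expect_lt(abs(mean(is.na(ref$seed_coat)) - 0.1), 0.02)
  # missing data propagates through the difference
  expect_true(all(is.na(d[is.na(ref$seed_coat)])))
})

test_that("an all-biallelic table keeps the downstream call rate at null", {
  cfg <- sim_config(n_genes = 2000, frac_meg = 0, frac_peg = 0,
                    frac_cis = 0, kappa = 0, depth_mean = 50,
                    depth_size = 5, seed = 13)
  sim <- simulate_allelic_counts(cfg)
  res <- imprinting_results(sim$counts, "endosperm")
  tested <- res$call != "low_info"
  expect_lte(mean(res$p_imprint[tested] < 0.01), 0.015)
  expect_lte(mean(res$call[tested] %in% c("MEG", "PEG")), 0.01)
})
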