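#!/usr/bin/env Rscript
# Build the synthetic reciprocal-cross seed cohort used by the downstream
# drivers: an endosperm dataset (null maternal fraction 2/3) and an embryo
# dataset (1/2), each with known MEG/PEG/cis structure, plus the reference
# expression table that encodes the seed-coat contamination structure.
#
# Found on the default run: ~3% of endosperm genes are truly imprinted,
# contamination touches ~5% of genes, and a small tail of lowly expressed
# genes falls below the 15-read coverage filter.

library(imprintcall)

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg_endo <- sim_config(n_genes = 600, tissue = "endosperm", kappa = 0.05,
                       frac_meg = 0.03, frac_peg = 0.01, seed = 11)
cfg_emb <- sim_config(n_genes = 600, tissue = "embryo", frac_meg = 0.002,
                      frac_peg = 0.001, kappa = 0.05, seed = 12)

endo <- simulate_allelic_counts(cfg_endo)
emb <- simulate_allelic_counts(cfg_emb)
ref <- simulate_reference_expression(cfg_endo, endo$truth)

sig <- function(x) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], signif, 6)
  x
}
write_tsv_table(endo$counts, file.path(out, "endosperm_counts.tsv"))
write_tsv_table(sig(endo$truth), file.path(out, "endosperm_truth.tsv"))
write_tsv_table(emb$counts, file.path(out, "embryo_counts.tsv"))
write_tsv_table(sig(ref), file.path(out, "reference_expression.tsv"))

summary_tab <- data.frame(
  dataset = c("endosperm", "embryo"),
  n_genes = c(nrow(endo$counts), nrow(emb$counts)),
  true_megs = c(sum(endo$truth$class == "MEG"), sum(emb$truth$class == "MEG")),
  true_pegs = c(sum(endo$truth$class == "PEG"), sum(emb$truth$class == "PEG")),
  true_cis = c(sum(endo$truth$class == "cis"), sum(emb$truth$class == "cis")),
  below_15_reads = c(
    sum(endo$counts$colxler_col + endo$counts$colxler_ler +
          endo$counts$lerxcol_col + endo$counts$lerxcol_ler < 15),
    sum(emb$counts$colxler_col + emb$counts$colxler_ler +
          emb$counts$lerxcol_col + emb$counts$lerxcol_ler < 15)
  )
)
write_tsv_table(summary_tab, file.path(out, "cohort_summary.tsv"))
print(summary_tab)
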