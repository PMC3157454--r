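#!/usr/bin/env Rscript
# Desk-scale anchors: rerun the statistics on the published count tables
# shipped with the package and tabulate the outcomes.
#
# Found: the three known imprinted genes with adequate coverage pass every
# criterion (HDG3 as PEG, MYB3R2 and HDG9 as MEGs); FIS2 is significant but
# fails the imprinting-factor cutoff; FWA has reads in one cross only
# (p = 1); the SDG20 clone counts show a ~60% Col fraction in both
# genotypes, a strain effect rather than imprinting.

library(imprintcall)

out <- "results/anchors"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

t1 <- known_imprinted_counts()
res <- imprinting_results(t1, tissue = "endosperm")
res$name <- t1$name
write_tsv_table(res, file.path(out, "known_genes_results.tsv"))
print(res[, c("name", "n_informative", "percent_maternal", "p_imprint",
              "imprinting_factor", "call")])

peg <- epigenetic_peg_reads()
peg$percent_paternal <- 100 - vapply(seq_len(nrow(peg)), function(i) {
  percent_maternal(peg$maternal_reads[i], peg$paternal_reads[i], 0, 0)
}, numeric(1))
write_tsv_table(peg, file.path(out, "epigenetic_pegs_percent_paternal.tsv"))

cl <- sdg20_clone_counts()
sdg <- do.call(rbind, lapply(c("ColxLer", "LerxCol"), function(cr) {
  tot <- colSums(cl[cl$cross == cr, c("col_clones", "ler_clones")])
  data.frame(cross = cr, col = tot[["col_clones"]], ler = tot[["ler_clones"]],
             percent_col = round(100 * tot[["col_clones"]] / sum(tot), 1))
}))
write_tsv_table(sdg, file.path(out, "sdg20_clone_fractions.tsv"))
print(sdg)
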