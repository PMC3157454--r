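#!/usr/bin/env Rscript
# Expression-level support: two sequencing libraries of the same tissue share
# per-gene expression up to sampling noise, so simulate a shared lognormal
# expression profile, Poisson read sampling per library, and a planted 5%
# subset of genes shifted four-fold in library 2. Compute RPKM with
# simulated exon-union lengths, upper-quartile-normalised Fisher DE, the DE
# factor, and the between-library correlation.
#
# Found: the libraries correlate near 1 on log RPKM, and the confident DE
# calls (BH q < 0.05 and DE factor >= 2) recover the planted shifted genes
# with high sensitivity and almost no calls among unshifted genes.

library(imprintcall)

out <- "results/expression"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

set.seed(51)
n <- 2000
mu <- rlnorm(n, meanlog = 4, sdlog = 1.2)
shifted <- runif(n) < 0.05
mu2 <- mu * ifelse(shifted, sample(c(4, 0.25), n, replace = TRUE), 1)
lib1 <- rpois(n, mu)
lib2 <- rpois(n, mu2)
len <- sample(400:4000, n, replace = TRUE)
gene_id <- sprintf("SIM%05d", seq_len(n))

rpkm1 <- rpkm(lib1, len, sum(lib1))
rpkm2 <- rpkm(lib2, len, sum(lib2))
r <- library_correlation(log2(rpkm1 + 1), log2(rpkm2 + 1))

q <- upper_quartile(lib1, lib2)
de <- fisher_de(lib1, lib2, q[1], q[2])
de$q_de <- bh_adjust(de$p_de)
de$de_factor <- de_factor(lib1, lib2, q[1], q[2])
called <- de$q_de < 0.05 & de$de_factor >= 2

tab <- data.frame(gene_id = gene_id, length = len, shifted = shifted,
                  count_1 = lib1, count_2 = lib2,
                  rpkm_1 = rpkm1, rpkm_2 = rpkm2, de, called = called)
write_tsv_table(tab[called | shifted, ], file.path(out, "cross_de.tsv"))

cat(sprintf("upper quartiles: %.1f / %.1f; Pearson r (log RPKM) = %.3f\n",
            q[1], q[2], r))
cat(sprintf("DE sensitivity: %.2f (%d of %d planted); false calls: %d of %d\n",
            mean(called[shifted]), sum(called & shifted), sum(shifted),
            sum(called & !shifted), sum(!shifted)))
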