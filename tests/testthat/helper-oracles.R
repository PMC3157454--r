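# Independent brute-force oracles. These enumerate the full outcome grid (or
# use the direct textbook formula) and stay deliberately separate from the
# package's fast implementations.

# exact unconditional two-binomial p-value by full O(n1*n2) enumeration
oracle_exact_p <- function(x1, n1, x2, n2, null = "pooled",
                           stat = c("per_copy", "deviation")) {
  stat <- match.arg(stat)
  if (n1 == 0 || n2 == 0) {
    return(1)
  }
  if (identical(null, "pooled")) {
    p1e <- p2e <- (x1 + x2) / (n1 + n2)
    f1 <- (0:n1) / n1
    f2 <- (0:n2) / n2
    t_obs <- abs(x1 / n1 - x2 / n2)
  } else {
    p1e <- null$p1
    p2e <- null$p2
    if (stat == "per_copy") {
      w1 <- (1 - p1e) / p1e
      w2 <- (1 - p2e) / p2e
      pc <- function(x, n, w) x * w / (x * w + (n - x))
      f1 <- pc(0:n1, n1, w1)
      f2 <- pc(0:n2, n2, w2)
      t_obs <- abs(pc(x1, n1, w1) - pc(x2, n2, w2))
    } else {
      f1 <- (0:n1) / n1 - p1e
      f2 <- (0:n2) / n2 - p2e
      t_obs <- abs((x1 / n1 - p1e) - (x2 / n2 - p2e))
    }
  }
  tmat <- abs(outer(f1, f2, "-"))
  pmat <- outer(dbinom(0:n1, n1, p1e), dbinom(0:n2, n2, p2e))
  min(1, sum(pmat[tmat >= t_obs - 1e-12]))
}

# step-up BH by the direct formula min_{k >= i} m * p_(k) / k
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# two-sided Fisher p for a 2x2 table by enumerating all tables with the same
# margins (sum of hypergeometric probabilities <= observed)
oracle_fisher2x2 <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive O(n*m) interval association with flanks
oracle_associate <- function(genes_df, dmrs_df, flank) {
  vapply(seq_len(nrow(genes_df)), function(i) {
    any(dmrs_df$chrom == genes_df$chrom[i] &
          dmrs_df$end >= genes_df$start[i] - flank &
          dmrs_df$start <= genes_df$end[i] + flank)
  }, logical(1))
}

# clustering as transitive closure of the pairwise "within window" predicate
oracle_clusters <- function(genes_df, window) {
  n <- nrow(genes_df)
  near <- outer(seq_len(n), seq_len(n), function(i, j) {
    genes_df$chrom[i] == genes_df$chrom[j] &
      pmax(genes_df$start[i], genes_df$start[j]) -
        pmin(genes_df$end[i], genes_df$end[j]) - 1 <= window
  })
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[near[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  split(genes_df$gene_id, comp)
}

# the printed-table null spec used throughout
endo_null <- function() null_spec("endosperm")
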