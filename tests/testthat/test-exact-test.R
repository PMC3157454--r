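test_that("symmetric observations under a symmetric null are never extreme", {
  expect_equal(exact_two_binomial_test(5, 10, 5, 10, null_spec("embryo")), 1)
  # pooled mode: equal fractions likewise
  expect_equal(exact_two_binomial_test(8, 20, 4, 10, "pooled"), 1)
})

test_that("a cross with zero informative reads gives p = 1", {
  # the known maternally imprinted FWA case: reads only in one cross
  expect_equal(exact_two_binomial_test(5, 5, 0, 0, endo_null()), 1)
  expect_equal(exact_two_binomial_test(0, 0, 3, 10, endo_null()), 1)
  expect_equal(exact_two_binomial_test(0, 0, 0, 0, "pooled"), 1)
})

test_that("invalid counts are rejected", {
  expect_error(exact_two_binomial_test(11, 10, 0, 5, endo_null()), "exceed")
  expect_error(exact_two_binomial_test(-1, 10, 0, 5, endo_null()),
               "non-negative")
  expect_error(exact_two_binomial_test(1, 2, 1, 2, null = "banana"),
               "null_spec")
})

test_that("strong reciprocal maternal bias gives an extreme p-value", {
  # HDG9-like counts; expected value frozen from the enumeration oracle
  p <- exact_two_binomial_test(29, 30, 3, 120, endo_null())
  expect_equal(p, oracle_exact_p(29, 30, 3, 120, endo_null()))
  expect_equal(p, 2.0402e-18, tolerance = 1e-4)
  expect_lt(p, 1e-15)
})

test_that("implementation matches full enumeration on random cases", {
  set.seed(11)
  for (rep in 1:60) {
    n1 <- sample(0:40, 1)
    n2 <- sample(0:40, 1)
    x1 <- if (n1 > 0) sample(0:n1, 1) else 0L
    x2 <- if (n2 > 0) sample(0:n2, 1) else 0L
    null <- null_spec(sample(c("embryo", "endosperm"), 1))
    expect_equal(
      exact_two_binomial_test(x1, n1, x2, n2, null),
      oracle_exact_p(x1, n1, x2, n2, null),
      tolerance = 1e-12
    )
    expect_equal(
      exact_two_binomial_test(x1, n1, x2, n2, null, stat = "deviation"),
      oracle_exact_p(x1, n1, x2, n2, null, stat = "deviation"),
      tolerance = 1e-12
    )
    expect_equal(
      exact_two_binomial_test(x1, n1, x2, n2, "pooled"),
      oracle_exact_p(x1, n1, x2, n2, "pooled"),
      tolerance = 1e-12
    )
  }
})

test_that("p-values stay exact at read depths in the tens of thousands", {
  # weak paternal bias at very high coverage: tiny p by depth alone
  p <- exact_two_binomial_test(4925, 7818, 2893, 7818, endo_null())
  expect_gt(p, 1e-24)
  expect_lt(p, 1e-18)
})

test_that("the test is symmetric under allele relabeling plus cross swap", {
  set.seed(21)
  for (rep in 1:25) {
    n1 <- sample(1:60, 1)
    n2 <- sample(1:60, 1)
    x1 <- sample(0:n1, 1)
    x2 <- sample(0:n2, 1)
    for (tissue in c("embryo", "endosperm")) {
      null <- null_spec(tissue)
      p_orig <- exact_two_binomial_test(x1, n1, x2, n2, null)
      # swap crosses and relabel Col<->Ler: (x1,n1) <-> (n2-x2, n2)
      p_swap <- exact_two_binomial_test(n2 - x2, n2, n1 - x1, n1, null)
      expect_equal(p_orig, p_swap, tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(5)
  p <- runif(20)
  expect_equal(bh_adjust(p), oracle_bh(p))
  # stable under reordering
  o <- sample(20)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
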