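test_that("the Wakefield labf matches its closed form", {
  # direct evaluation: V = 0.0025, W = 0.0225, z = 2
  expect_equal(wakefield_labf(0.1, 0.05, 0.0225),
               0.5 * (log(0.1) + 3.6), tolerance = 1e-12)
  # null shrinkage: z = 0 gives a negative labf
  expect_lt(wakefield_labf(0, 0.05, 0.0225), 0)
  # degenerate prior: W -> 0 gives labf -> 0
  expect_lt(abs(wakefield_labf(0.3, 0.05, 1e-12)), 1e-6)
  expect_error(wakefield_labf(0.1, -1), "se")
})

test_that("PIPs are a stable softmax of the labfs", {
  fm <- pip_from_labf(rep(1.7, 5))
  expect_equal(fm$pip, rep(0.2, 5))
  fm2 <- pip_from_labf(c(10, 0))
  expect_equal(fm2$pip, c(exp(10), 1) / (exp(10) + 1), tolerance = 1e-9)
  expect_equal(fm2$pip[2L], 4.54e-5, tolerance = 1e-2)
  # shift invariance and overflow stability
  expect_equal(pip_from_labf(c(10, 0) + 1000)$pip, fm2$pip)
  expect_equal(sum(pip_from_labf(stats::rnorm(50) * 400)$pip), 1,
               tolerance = 1e-9)
  expect_error(pip_from_labf(numeric(0)), "labf")
})

test_that("coloc masses match explicit enumeration over configurations", {
  set.seed(33L)
  for (k in 1:20) {
    m <- sample(2:12, 1L)
    l1 <- stats::rnorm(m, 0, 4)
    l2 <- stats::rnorm(m, 0, 4)
    res <- coloc_pair(l1, l2)
    oracle <- coloc_enum_oracle(l1, l2)
    expect_equal(unlist(res[, c("pp_h0", "pp_h1", "pp_h2", "pp_h3",
                                "pp_h4")]),
                 oracle, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(sum(unlist(res[, paste0("pp_h", 0:4)])), 1,
                 tolerance = 1e-9)
  }
})

test_that("coloc posteriors behave at the edges", {
  # flat evidence over many SNPs: H0 dominates, matching the oracle
  res0 <- coloc_pair(rep(0, 100), rep(0, 100))
  expect_gt(res0$pp_h0, 0.97)
  # value from the closed form: 1 / (1 + p1*m + p2*m + p1*p2*m*(m-1) + p12*m)
  m <- 100
  denom <- 1 + 1e-4 * m + 1e-4 * m + 1e-8 * m * (m - 1) + 1e-5 * m
  expect_equal(res0$pp_h0, 1 / denom, tolerance = 1e-10)

  # single common SNP: H3 impossible, H4 beats H1/H2 when both signals big
  res1 <- coloc_pair(20, 22)
  expect_equal(res1$pp_h3, 0)
  expect_gt(res1$pp_h4, res1$pp_h1)
  expect_gt(res1$pp_h4, res1$pp_h2)

  # swapping traits swaps H1 and H2, preserves H0/H3/H4
  set.seed(44L)
  l1 <- stats::rnorm(30, 0, 3); l2 <- stats::rnorm(30, 0, 3)
  a <- coloc_pair(l1, l2); b <- coloc_pair(l2, l1)
  expect_equal(a$pp_h1, b$pp_h2)
  expect_equal(a$pp_h2, b$pp_h1)
  expect_equal(a$pp_h0, b$pp_h0)
  expect_equal(a$pp_h3, b$pp_h3)
  expect_equal(a$pp_h4, b$pp_h4)

  # identical sharp labf vectors drive H4 toward 1
  sharp <- c(rep(0, 9), 40)
  expect_gt(coloc_pair(sharp, sharp)$pp_h4, 0.99)
  expect_error(coloc_pair(numeric(0), numeric(0)), "common SNP")
})

test_that("PP(H4) is monotone in the shared-causal prior p12", {
  set.seed(55L)
  l1 <- stats::rnorm(25, 0, 3); l2 <- l1 + stats::rnorm(25, 0, 0.5)
  grid <- 10^seq(-8, -4.5, length.out = 8)
  h4 <- vapply(grid, function(p12)
    coloc_pair(l1, l2, coloc_config(p12 = p12))$pp_h4, numeric(1L))
  expect_true(all(diff(h4) >= -1e-12))
})

test_that("priors are validated", {
  expect_error(coloc_config(p12 = 0.5), "p12")
  expect_error(coloc_config(p1 = 0), "\\(0, 1\\)")
  expect_error(coloc_config(prior_var_W = -1), "prior_var_W")
})

test_that("conditional colocalization resolves the planted scenarios", {
  # shared causal variant: high H4
  h4_hits <- 0L
  for (k in 1:10) {
    b <- make_scenario(scenario_spec("single_shared", seed = 1100L + k))
    m <- b$weights_true$GENE1
    cr <- conditional_coloc(b$qtl_sumstats$GENE1, b$gwas$trait1, b$panel,
                            c(1, m$start, m$stop))
    if (max(cr$pp_h4) >= 0.8) h4_hits <- h4_hits + 1L
    expect_equal(rowSums(cr[, paste0("pp_h", 0:4)]), rep(1, nrow(cr)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_gte(h4_hits, 8L)

  # distinct causal variants in LD: H3 wins
  h3_hits <- 0L
  for (k in 1:10) {
    b <- make_scenario(scenario_spec("distinct_in_ld", seed = 1200L + k))
    m <- b$weights_true$GENE1
    cr <- conditional_coloc(b$qtl_sumstats$GENE1, b$gwas$trait1, b$panel,
                            c(1, m$start, m$stop))
    if (max(cr$pp_h3) > max(cr$pp_h4)) h3_hits <- h3_hits + 1L
  }
  expect_gte(h3_hits, 7L)

  # two independent trait signals, QTL sharing only one: the matching pair
  # colocalizes, the other does not
  pair_hits <- 0L
  for (k in 1:10) {
    b <- make_scenario(scenario_spec("two_signals", seed = 1300L + k))
    m <- b$weights_true$GENE1
    sA <- b$truth$feature_causal$GENE1
    cr <- conditional_coloc(b$qtl_sumstats$GENE1, b$gwas$trait1, b$panel,
                            c(1, m$start, m$stop))
    if (nrow(cr) >= 2L && sA %in% cr$trait_signal) {
      on_A <- cr$trait_signal == sA
      if (max(cr$pp_h4[on_A]) >= 0.8 && all(cr$pp_h4[!on_A] < 0.8))
        pair_hits <- pair_hits + 1L
    }
  }
  expect_gte(pair_hits, 7L)
})
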