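ortho_sumstats <- function(z = c(3, 4)) {
  pan <- orthogonal_panel()
  gwas_sumstats("t", data.frame(
    snp_id = pan$snps$snp_id, chr = 1, pos = pan$snps$pos,
    a1 = pan$snps$a1, a2 = pan$snps$a2, freq = 0.5,
    beta = z * 0.1, se = 0.1, z = z, n = 1000))
}

test_that("xwas z reduces to the GWAS z for a single-SNP model", {
  pan <- orthogonal_panel()
  m <- weight_model("g", "expression", "t", 1, 50, 150,
                    data.frame(snp_id = "rs1", a1 = "A", a2 = "G",
                               weight = 1))
  r <- xwas_z(m, ortho_sumstats(), pan)
  expect_equal(r$z_xwas, 3)
  expect_equal(r$p_xwas, 2 * stats::pnorm(-3), tolerance = 1e-12)
})

test_that("xwas z follows the closed form w'z / sqrt(w'Rw)", {
  pan <- orthogonal_panel()
  m <- weight_model("g", "expression", "t", 1, 50, 250,
                    data.frame(snp_id = c("rs1", "rs2"),
                               a1 = c("A", "C"), a2 = c("G", "T"),
                               weight = c(1, 1)))
  r <- xwas_z(m, ortho_sumstats(c(3, 4)), pan)
  expect_equal(r$z_xwas, 7 / sqrt(2), tolerance = 1e-12)
  expect_equal(r$n_snps_used, 2L)

  # invariance to scaling all weights by a positive constant
  m3 <- m; m3$entries$weight <- m$entries$weight * 3
  expect_equal(xwas_z(m3, ortho_sumstats(), pan)$z_xwas, r$z_xwas)

  # invariance to simultaneous allele relabeling of weights and sumstats
  ssf <- ortho_sumstats()
  ssf$records$a1[1L] <- "G"; ssf$records$a2[1L] <- "A"
  ssf$records$z[1L] <- -3; ssf$records$beta[1L] <- -0.3
  ssf$records$freq[1L] <- 0.5
  mf <- m
  mf$entries$a1[1L] <- "G"; mf$entries$a2[1L] <- "A"
  mf$entries$weight[1L] <- -1
  expect_equal(xwas_z(mf, ssf, pan)$z_xwas, r$z_xwas)
})

test_that("Bonferroni thresholds reproduce the unique-feature divisors", {
  expect_equal(signif(bonferroni_threshold(12893, 0.05), 2), 3.9e-6)
  expect_equal(signif(bonferroni_threshold(1342, 0.05), 2), 3.7e-5)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_error(bonferroni_threshold(10, 1.5), "alpha")
  expect_error(bonferroni_threshold(0, 0.05), "n_unique")
})

test_that("the screen tests per tissue but counts unique features once", {
  b <- make_scenario(scenario_spec("single_shared", seed = 61L))
  m1 <- b$weights_true$GENE1
  m1b <- m1; m1b$tissue <- "other_tissue"
  m2 <- b$weights_true$GENE2
  res <- run_xwas_screen(list(m1, m1b, m2), b$gwas$trait1, b$panel)
  expect_equal(nrow(res), 3L)
  # divisor is 2 unique features, not 3 models
  expect_true(all(res$threshold == 0.05 / 2))
  # planted mediated feature is significant at n_gwas = 1e5
  expect_true(all(res$significant[res$feature_id == "GENE1"]))

  # manifest of one model reduces to xwas_z
  one <- run_xwas_screen(list(m1), b$gwas$trait1, b$panel)
  expect_equal(one$z_xwas, xwas_z(m1, b$gwas$trait1, b$panel)$z_xwas)
})

test_that("no feature reaches Bonferroni under the global null", {
  sp <- scenario_spec("null", p_snps = 30L, n_panel = 400L, seed = 71L)
  pan <- simulate_ld_panel(sp)
  set.seed(72L)
  models <- lapply(1:100, function(i) {
    j <- sample.int(30L, 2L)
    weight_model(paste0("g", i), "expression", "t", 1,
                 pan$snps$pos[min(j)], pan$snps$pos[max(j)],
                 data.frame(snp_id = pan$snps$snp_id[j],
                            a1 = pan$snps$a1[j], a2 = pan$snps$a2[j],
                            weight = stats::rnorm(2L)))
  })
  ss <- simulate_gwas_sumstats(pan, numeric(0), 1e5, seed = 73L)
  res <- run_xwas_screen(models, ss, pan)
  # expected false positives at 0.05/100 over 100 tests: ~0.05
  expect_lte(sum(res$significant), 1L)
})

test_that("shared classification follows each trait's own threshold", {
  r1 <- data.frame(feature_id = c("a", "b"), tissue = "t",
                   significant = c(TRUE, TRUE))
  r2 <- data.frame(feature_id = c("a", "c"), tissue = "t",
                   significant = c(TRUE, TRUE))
  lab <- classify_shared(r1, r2)
  expect_equal(lab$label[lab$feature_id == "a"], "shared")
  expect_equal(lab$label[lab$feature_id == "b"], "trait1_only")
  expect_equal(lab$label[lab$feature_id == "c"], "trait2_only")
})

test_that("a feature mediating two traits is classified shared", {
  hits <- 0L; reps <- 20L
  for (k in seq_len(reps)) {
    b <- make_scenario(scenario_spec("coregulated_pair", seed = 500L + k))
    ms <- b$weights_true
    res1 <- run_xwas_screen(ms, b$gwas$trait1, b$panel)
    res2 <- run_xwas_screen(ms, b$gwas$trait2, b$panel)
    lab <- classify_shared(res1, res2)
    if (any(lab$feature_id == "GENE1" & lab$label == "shared"))
      hits <- hits + 1L
  }
  expect_gte(hits, 16L)
})

test_that("summary xwas agrees with individual-level regression in sample", {
  sp <- scenario_spec("single_shared", p_snps = 50L, n_panel = 5000L,
                      h2_cis = 0.3, seed = 81L)
  pan <- simulate_ld_panel(sp)
  f <- simulate_feature(pan, sp, seed = 82L)
  set.seed(83L)
  y <- 0.1 * f$values + stats::rnorm(nrow(pan$dosages))
  ss <- insample_sumstats(pan, y)
  zx <- xwas_z(f$model, ss, pan, ridge = 0)$z_xwas
  fit <- summary(stats::lm(y ~ impute_feature(pan, f$model)))
  z_reg <- fit$coefficients[2L, 3L]
  expect_lt(abs(zx - z_reg) / abs(z_reg), 0.05)
})
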