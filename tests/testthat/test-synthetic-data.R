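test_that("LD panel generation matches the latent AR(1) model", {
  # independence: mean |off-diagonal r| small
  sp0 <- scenario_spec("null", p_snps = 15L, n_panel = 2000L, ld_decay = 0,
                       seed = 11L)
  R <- panel_cor(simulate_ld_panel(sp0))
  off <- abs(R[upper.tri(R)])
  expect_lte(mean(off), 2 / sqrt(sp0$n_panel))

  # decay 0.9: adjacent empirical r within 0.1 of the bivariate-normal
  # orthant oracle
  sp9 <- scenario_spec("null", p_snps = 20L, n_panel = 2000L, ld_decay = 0.9,
                       seed = 12L)
  pan <- simulate_ld_panel(sp9)
  R9 <- panel_cor(pan)
  emp <- R9[cbind(1:19, 2:20)]
  maf <- pan$snps$freq
  pred <- vapply(1:19, function(j)
    predicted_indicator_r(maf[j], maf[j + 1L], 0.9), numeric(1L))
  expect_lt(abs(mean(emp) - mean(pred)), 0.1)
  # sign of adjacent r follows ld_decay
  expect_true(all(emp > 0))
})

test_that("panel simulation is reproducible and validates parameters", {
  sp <- scenario_spec("null", p_snps = 8L, n_panel = 50L, seed = 5L)
  expect_identical(simulate_ld_panel(sp)$dosages,
                   simulate_ld_panel(sp)$dosages)
  expect_error(scenario_spec("null", maf_range = c(0.3, 0.1)),
               "maf_range")
  expect_error(scenario_spec("null", h2_cis = 1.2), "h2_cis")
  expect_error(scenario_spec("frobnicate"), "arg")
})

test_that("simulated features hit the target cis heritability", {
  sp <- scenario_spec("null", p_snps = 20L, n_panel = 2000L, h2_cis = 0.99,
                      n_causal = 1L, seed = 21L)
  pan <- simulate_ld_panel(sp)
  f <- simulate_feature(pan, sp)
  expect_gte(stats::cor(f$values, pan$dosages[, f$causal_ids])^2, 0.9)
  expect_lt(abs(stats::var(f$values) - 1), 0.1)

  # near-zero heritability: genetic variance share below 5%
  sp0 <- sp; sp0$h2_cis <- 1e-3
  f0 <- simulate_feature(pan, sp0)
  X <- scale(pan$dosages[, f0$causal_ids, drop = FALSE])
  g <- drop(X %*% f0$model$entries$weight)
  expect_lt(stats::var(g) / stats::var(f0$values), 0.05)

  # empirical h2 near target at moderate h2
  sp5 <- sp; sp5$h2_cis <- 0.5
  f5 <- simulate_feature(pan, sp5)
  X5 <- scale(pan$dosages[, f5$causal_ids, drop = FALSE])
  h2_emp <- stats::var(drop(X5 %*% f5$model$entries$weight)) /
    stats::var(f5$values)
  expect_lt(abs(h2_emp - 0.5), 0.05)
})

test_that("simulated GWAS z-scores follow their asymptotic distribution", {
  sp <- scenario_spec("null", p_snps = 50L, n_panel = 1500L, ld_decay = 0.5,
                      seed = 31L)
  pan <- simulate_ld_panel(sp)

  # null: type-I error 0.05 +/- 0.01 over 5000 SNP draws
  zs <- unlist(lapply(1:100, function(k)
    simulate_gwas_sumstats(pan, numeric(0), 1e5, seed = 1000L + k)$records$z))
  expect_lt(abs(mean(abs(zs) > 1.96) - 0.05), 0.01)

  # mean z at the causal SNP matches sqrt(n) * b over 200 reps
  causal <- stats::setNames(0.05, pan$snps$snp_id[25L])
  zc <- vapply(1:200, function(k)
    simulate_gwas_sumstats(pan, causal, 1e5, seed = 2000L + k)$records$z[25L],
    numeric(1L))
  expect_lt(abs(mean(zc) - sqrt(1e5) * 0.05), 3 / sqrt(200))

  # every SNP's mean matches sqrt(n) * (R b); in particular near-zero-LD
  # SNPs have mean near zero
  mu_pred <- sqrt(1e5) * drop(panel_cor(pan) %*%
                                ifelse(pan$snps$snp_id == names(causal),
                                       0.05, 0))
  zmat <- vapply(1:200, function(k)
    simulate_gwas_sumstats(pan, causal, 1e5, seed = 2000L + k)$records$z,
    numeric(50L))
  expect_lt(max(abs(rowMeans(zmat) - mu_pred)), 4 / sqrt(200))

  # back-filled fields are mutually consistent
  ss <- simulate_gwas_sumstats(pan, causal, 1e5, seed = 1L)
  expect_equal(ss$records$z, ss$records$beta / ss$records$se)
  expect_error(simulate_gwas_sumstats(pan, causal, -5, seed = 1L),
               "positive")
})

test_that("scenario bundles are self-consistent and reproducible", {
  b0 <- make_scenario(scenario_spec("null", seed = 41L))
  expect_length(b0$truth$trait_causal$trait1, 0L)

  b1 <- make_scenario(scenario_spec("single_shared", seed = 42L))
  expect_identical(b1$truth$feature_causal$GENE1,
                   b1$truth$trait_causal$trait1)

  b2 <- make_scenario(scenario_spec("two_signals", seed = 43L))
  pr <- b2$truth$trait_causal$trait1
  expect_length(pr, 2L)
  expect_lt(panel_cor(b2$panel, pr)[1L, 2L]^2, 0.05)

  b3 <- make_scenario(scenario_spec("coregulated_pair", seed = 44L))
  rho <- cis_genetic_correlation(b3$qtl_panel, b3$weights_true$GENE1,
                                 b3$weights_true$GENE2)$rho
  expect_lt(abs(rho - b3$spec$rho_target), 0.1)

  # reproducibility from (name, seed)
  b2b <- make_scenario(scenario_spec("two_signals", seed = 43L))
  expect_identical(b2b$gwas$trait1$records$z, b2$gwas$trait1$records$z)
  expect_identical(b2b$panel$dosages, b2$panel$dosages)

  # generated sumstats survive their own reader round-trip (invariants)
  p <- tempfile(fileext = ".tsv")
  write_gwas_sumstats(b1$gwas$trait1, p)
  expect_s3_class(read_gwas_sumstats(p, "full"), "GwasSumstats")
})

test_that("scenario bundles serialize to the on-disk dialects", {
  b <- make_scenario(scenario_spec("single_shared", p_snps = 20L,
                                   n_panel = 60L, n_qtl = 80L, seed = 45L))
  d <- file.path(tempdir(), "scn_rt")
  paths <- write_scenario(b, d)
  expect_true(all(file.exists(file.path(d, c("panel.snps.tsv",
                                             "trait1.sumstats.tsv",
                                             "truth.json",
                                             "scenario.yaml")))))
  pan <- read_ld_panel(file.path(d, "panel"))
  expect_equal(pan$dosages, b$panel$dosages, ignore_attr = TRUE)
})
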