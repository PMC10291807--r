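feat_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(i)
    data.frame(feature_id = paste0("g", i), tissue = "t",
               chr = rows[[i]][1L], start = rows[[i]][2L],
               stop = rows[[i]][3L])))
}

test_that("padded spans merge by overlap, transitively", {
  # two genes whose padded (500 kb) spans overlap
  one <- merge_regions(feat_df(c(1, 1.00e6, 1.01e6), c(1, 1.90e6, 1.95e6)),
                       pad = 5e5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_features, 2L)

  # with no padding they stay apart
  two <- merge_regions(feat_df(c(1, 1.00e6, 1.01e6), c(1, 1.90e6, 1.95e6)),
                       pad = 0)
  expect_equal(nrow(two), 2L)

  # transitive chain: A-B overlap and B-C overlap but not A-C
  chain <- merge_regions(feat_df(c(1, 1.0e6, 1.1e6), c(1, 1.2e6, 1.3e6),
                                 c(1, 1.4e6, 1.5e6)), pad = 1e5)
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$n_features, 3L)

  expect_error(merge_regions(feat_df(c(1, 10, 5))), "start > stop")
})

test_that("merging is order-invariant, idempotent and disjoint", {
  set.seed(66L)
  feats <- data.frame(feature_id = paste0("g", 1:30), tissue = "t",
                      chr = sample(1:3, 30, TRUE),
                      start = round(stats::runif(30, 1e6, 5e7)))
  feats$stop <- feats$start + round(stats::runif(30, 1e4, 2e5))
  a <- merge_regions(feats, pad = 5e5)
  b <- merge_regions(feats[sample.int(30), ], pad = 5e5)
  expect_identical(a, b)
  # output regions are pairwise disjoint per chromosome ...
  for (ch in unique(a$chr)) {
    r <- a[a$chr == ch, ]
    if (nrow(r) > 1L)
      expect_true(all(r$start[-1L] > r$stop[-nrow(r)]))
  }
  # ... so re-merging the merged intervals changes nothing
  again <- merge_regions(data.frame(feature_id = paste0("r", a$region_id),
                                    tissue = "t", chr = a$chr,
                                    start = a$start, stop = a$stop),
                         pad = 0)
  expect_equal(nrow(again), nrow(a))
  expect_equal(again$start, a$start)
  expect_equal(again$stop, a$stop)
})

test_that("features touching the MHC collapse into its fixed span", {
  regs <- merge_regions(feat_df(c(6, 26e6, 26.1e6), c(6, 33e6, 33.1e6),
                                c(6, 40e6, 40.1e6), c(1, 1e6, 1.1e6)),
                        pad = 5e5)
  mhc <- regs[regs$is_mhc, ]
  expect_equal(nrow(mhc), 1L)
  expect_equal(c(mhc$start, mhc$stop), c(25.5e6, 34e6))
  expect_equal(mhc$n_features, 2L)
  # region ids follow genomic order
  expect_equal(regs$region_id, order(order(regs$chr, regs$start)))
})

test_that("trait support needs both xWAS significance and colocalization", {
  feats <- feat_df(c(1, 1.0e6, 1.1e6), c(1, 9.0e6, 9.1e6))
  regs <- merge_regions(feats, pad = 5e5)
  expect_equal(nrow(regs), 2L)

  xwas <- data.frame(
    feature_id = c("g1", "g1", "g2"), tissue = "t",
    trait_id = c("traitA", "traitB", "traitA"),
    significant = c(TRUE, TRUE, TRUE))
  coloc <- data.frame(
    feature_id = c("g1", "g1"), tissue = "t",
    trait_id = c("traitA", "traitB"), pp_h4 = c(0.95, 0.9))
  out <- assemble_trait_support(regs, xwas, coloc, pp4 = 0.8)
  sup <- out$support
  # g1's region: shared across both traits; g2's region: xWAS only, no coloc
  expect_true(all(sup$supported[sup$region_id == 1L]))
  expect_false(any(sup$supported[sup$region_id == 2L]))
  expect_true(any(sup$xwas_only[sup$region_id == 2L]))
  # Venn: one region in the A+B cell, none alone
  venn <- out$venn
  expect_equal(venn$n_regions[venn$trait_subset == "traitA+traitB"], 1L)
  expect_equal(sum(venn$n_regions), sum(!duplicated(
    sup$region_id[sup$supported])))

  # referential integrity: coloc rows must key into known features
  badc <- rbind(coloc, data.frame(feature_id = "ghost", tissue = "t",
                                  trait_id = "traitA", pp_h4 = 1))
  expect_error(assemble_trait_support(regs, xwas, badc), "ghost")
})

test_that("regions missed by GWAS significance are flagged", {
  regs <- merge_regions(feat_df(c(1, 1.0e6, 1.1e6)), pad = 5e5)
  xwas <- data.frame(feature_id = "g1", tissue = "t", trait_id = "traitA",
                     significant = TRUE)
  coloc <- data.frame(feature_id = "g1", tissue = "t", trait_id = "traitA",
                      pp_h4 = 0.9)
  weak <- gwas_sumstats("traitA", data.frame(
    snp_id = c("rs1", "rs2"), chr = 1, pos = c(1.02e6, 1.05e6),
    a1 = "A", a2 = "G", freq = 0.3, beta = c(0.02, 0.01), se = 0.005,
    z = c(4, 2), n = 1e5))
  out <- assemble_trait_support(regs, xwas, coloc,
                                gwas_list = list(traitA = weak))
  expect_true(out$support$twas_pwas_only[1L])
  expect_equal(out$support$best_gwas_p[1L], 2 * stats::pnorm(-4))
})
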