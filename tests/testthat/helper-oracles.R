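# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own computational paths.

# P(Z1 < a, Z2 < b) for a standard bivariate normal with correlation rho,
# by one-dimensional numeric integration.
orthant_p <- function(a, b, rho) {
  stats::integrate(function(z)
    stats::dnorm(z) * stats::pnorm((b - rho * z) / sqrt(1 - rho^2)),
    -Inf, a, rel.tol = 1e-10)$value
}

# Predicted correlation between two haplotype indicators thresholded from
# latent Gaussians with correlation rho at MAF quantiles maf1, maf2.
# (Dosages are sums of two iid haplotypes, so dosage correlation is equal.)
predicted_indicator_r <- function(maf1, maf2, rho) {
  p11 <- orthant_p(stats::qnorm(maf1), stats::qnorm(maf2), rho)
  (p11 - maf1 * maf2) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

# Explicit enumeration of the five colocalization hypothesis masses over
# every causal configuration (trait-1 causal SNP i or none) x (trait-2
# causal SNP j or none), for m <= 12 SNPs.
coloc_enum_oracle <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4,
                              p12 = 1e-5) {
  m <- length(labf1)
  stopifnot(m <= 12L, length(labf2) == m)
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  L <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (i in seq_len(m)) {
    L["h1"] <- L["h1"] + p1 * bf1[i]
    L["h2"] <- L["h2"] + p2 * bf2[i]
    L["h4"] <- L["h4"] + p12 * bf1[i] * bf2[i]
    for (j in seq_len(m)) if (j != i)
      L["h3"] <- L["h3"] + p1 * p2 * bf1[i] * bf2[j]
  }
  L / sum(L)
}

# A tiny panel with exactly orthogonal dosage columns (empirical r = 0).
orthogonal_panel <- function() {
  dos <- cbind(rs1 = c(0, 0, 2, 2, 0, 0, 2, 2),
               rs2 = c(0, 2, 0, 2, 0, 2, 0, 2))
  ld_panel(data.frame(snp_id = c("rs1", "rs2"), chr = 1,
                      pos = c(100, 200), a1 = c("A", "C"),
                      a2 = c("G", "T"), freq = c(0.5, 0.5)),
           dos)
}

# Per-SNP OLS summary statistics computed directly from individual-level
# data (intercept included), the textbook way; used as input when the
# reference panel IS the GWAS sample.
insample_sumstats <- function(panel, y, trait_id = "trait1") {
  X <- panel$dosages
  n <- length(y)
  vx <- apply(X, 2L, stats::var)
  b <- drop(crossprod(sweep(X, 2L, colMeans(X)), y - mean(y))) /
    ((n - 1) * vx)
  s2 <- pmax((stats::var(y) - b^2 * vx) * (n - 1) / (n - 2),
             .Machine$double.eps)
  se <- sqrt(s2 / ((n - 1) * vx))
  f <- pmin(pmax(colMeans(X) / 2, 1 / (2 * n)), 1 - 1 / (2 * n))
  gwas_sumstats(trait_id,
                data.frame(snp_id = panel$snps$snp_id, chr = panel$snps$chr,
                           pos = panel$snps$pos, a1 = panel$snps$a1,
                           a2 = panel$snps$a2, freq = f, beta = b, se = se,
                           z = b / se, n = n))
}

# Small well-formed sumstats data.frame for reader tests.
tiny_sumstats_df <- function() {
  data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = 1,
             POS = c(100L, 200L, 300L), A1 = c("A", "C", "G"),
             A2 = c("G", "T", "A"), FREQ = c(0.2, 0.4, 0.3),
             BETA = c(0.1, -0.05, 0.02), SE = c(0.05, 0.04, 0.02),
             Z = c(2, -1.25, 1), N = 1000L)
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  path
}
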