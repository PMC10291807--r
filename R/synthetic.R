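#' Scenario specification for the synthetic-data generator
#'
#' Defines the study conditions under which the pipeline is exercised: a
#' blockwise-LD reference panel, cis-heritable molecular features with 1-3
#' causal SNPs, trait GWAS z-scores generated under feature-mediated
#' effects with the LD-induced correlation structure, and (for
#' `coregulated_pair`) a pair of features with a stated cis genetic
#' correlation.
#'
#' @param name scenario: `"null"` (cis-heritable feature, no trait effect),
#'   `"single_shared"` (one causal SNP shared by feature and trait, plus a
#'   second co-driven feature), `"distinct_in_ld"` (feature and trait causal
#'   SNPs distinct but in moderate LD, target r-squared about 0.3),
#'   `"two_signals"` (two features on two low-LD causal SNPs, both mediating
#'   the trait), `"coregulated_pair"` (two features with cis genetic
#'   correlation `rho_target`, one mediating two traits).
#' @param p_snps number of SNPs in the region.
#' @param n_panel LD reference panel size (individuals).
#' @param n_qtl QTL study sample size (training individuals and the QTL
#'   GWAS N).
#' @param n_gwas effective trait GWAS sample size.
#' @param ld_decay AR(1) adjacent-SNP latent correlation in [0, 1).
#' @param maf_range minor-allele frequency range (lo, hi) in (0, 0.5].
#' @param h2_cis cis heritability of each feature, in (0, 1).
#' @param n_causal causal cis SNPs per feature.
#' @param alpha_mediation trait effect per SD of the mediating feature.
#' @param rho_target intended cis genetic correlation for
#'   `coregulated_pair`.
#' @param seed integer seed; every draw derives from it.
#' @return Object of class `ScenarioSpec`.
#' @export
scenario_spec <- function(name = c("null", "single_shared", "distinct_in_ld",
                                   "two_signals", "coregulated_pair"),
                          p_snps = 40L, n_panel = 500L, n_qtl = 1000L,
                          n_gwas = 1e5, ld_decay = 0.7,
                          maf_range = c(0.05, 0.5), h2_cis = 0.2,
                          n_causal = 1L, alpha_mediation = 0.15,
                          rho_target = -0.9, seed = 1L) {
  name <- match.arg(name)
  if (p_snps < 2L) stop("p_snps must be >= 2", call. = FALSE)
  if (maf_range[1L] >= maf_range[2L])
    stop("degenerate maf_range: lo >= hi", call. = FALSE)
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5)
    stop("maf_range must lie in (0, 0.5]", call. = FALSE)
  if (h2_cis <= 0 || h2_cis >= 1)
    stop("h2_cis must lie in (0, 1)", call. = FALSE)
  if (ld_decay < 0 || ld_decay >= 1)
    stop("ld_decay must lie in [0, 1)", call. = FALSE)
  if (n_causal > p_snps) stop("n_causal exceeds p_snps", call. = FALSE)
  if (abs(rho_target) > 1) stop("rho_target outside [-1, 1]", call. = FALSE)
  structure(list(name = name, p_snps = as.integer(p_snps),
                 n_panel = as.integer(n_panel), n_qtl = as.integer(n_qtl),
                 n_gwas = n_gwas, ld_decay = ld_decay,
                 maf_range = maf_range, h2_cis = h2_cis,
                 n_causal = as.integer(n_causal),
                 alpha_mediation = alpha_mediation,
                 rho_target = rho_target, seed = as.integer(seed)),
            class = "ScenarioSpec")
}

# SNP grid shared by all synthetic panels: chromosome 1, 2-kb spacing.
.synth_positions <- function(p) 1e6 + (seq_len(p) - 1L) * 2000

#' Simulate an LD reference panel
#'
#' Haplotypes are drawn by thresholding a latent Gaussian AR(1) process
#' (adjacent correlation `ld_decay`) at each SNP's MAF quantile; two
#' independent haplotype draws per individual are summed to a dosage.
#' MAFs are uniform on `maf_range`.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional override of `spec$seed`.
#' @return An [ld_panel()].
#' @export
simulate_ld_panel <- function(spec, seed = spec$seed) {
  if (spec$n_panel < 30L) stop("n_panel must be >= 30", call. = FALSE)
  set.seed(seed)
  p <- spec$p_snps
  n <- spec$n_panel
  maf <- stats::runif(p, spec$maf_range[1L], spec$maf_range[2L])
  thr <- stats::qnorm(maf)
  rho <- spec$ld_decay
  draw_haps <- function() {
    Z <- matrix(stats::rnorm(n * p), n, p)
    if (rho > 0 && p > 1L)
      for (j in 2:p) Z[, j] <- rho * Z[, j - 1L] + sqrt(1 - rho^2) * Z[, j]
    sweep(Z, 2L, thr, "<") + 0
  }
  dos <- draw_haps() + draw_haps()
  # guard against monomorphic columns at small n: flip one haplotype
  for (j in which(apply(dos, 2L, stats::sd) == 0)) {
    i <- sample.int(n, 1L)
    dos[i, j] <- if (dos[i, j] == 0) 1 else dos[i, j] - 1
  }
  # non-ambiguous (non A/T, non C/G) pairs assigned deterministically per
  # SNP index, so every panel drawn on the same grid shares alleles and
  # harmonization never has to drop a synthetic SNP
  pairs_ok <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                    c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  pair <- pairs_ok[(seq_len(p) - 1L) %% nrow(pairs_ok) + 1L, , drop = FALSE]
  snps <- data.frame(snp_id = sprintf("rs%04d", seq_len(p)), chr = 1L,
                     pos = .synth_positions(p), a1 = pair[, 1L],
                     a2 = pair[, 2L], freq = maf)
  ld_panel(snps, dos)
}

#' Simulate a cis-heritable molecular feature
#'
#' The feature is a weighted sum of standardized causal-SNP dosages plus
#' Gaussian noise, with weights rescaled so the genetic variance fraction
#' equals `h2_cis` empirically in the supplied genotypes; the returned
#' feature has variance about 1.
#'
#' @param panel genotypes to realize the feature in (an [ld_panel()]).
#' @param spec a [scenario_spec()].
#' @param causal_ids causal SNP ids; sampled uniformly when `NULL`.
#' @param feature_id,tissue,modality labels for the returned truth model.
#' @param seed optional override.
#' @param gene_span optional `(start, stop)` bp for the truth model;
#'   defaults to the middle third of the panel.
#' @return List with `model` (a [weight_model()] carrying the true
#'   standardized effects), `values` (per-individual feature), and
#'   `causal_ids`.
#' @export
simulate_feature <- function(panel, spec, causal_ids = NULL,
                             feature_id = "GENE1", tissue = "synth_tissue",
                             modality = "expression", seed = spec$seed + 1L,
                             gene_span = NULL) {
  if (spec$n_causal < 1L) stop("n_causal must be >= 1", call. = FALSE)
  set.seed(seed)
  ids <- panel$snps$snp_id
  if (is.null(causal_ids))
    causal_ids <- sort(sample(ids, spec$n_causal))
  if (!all(causal_ids %in% ids))
    stop("causal SNP(s) absent from panel", call. = FALSE)
  X <- standardize_columns(panel$dosages[, causal_ids, drop = FALSE])
  w <- stats::rnorm(length(causal_ids))
  g <- drop(X %*% w)
  w <- w * sqrt(spec$h2_cis / stats::var(g))
  g <- drop(X %*% w)
  values <- g + stats::rnorm(nrow(X), 0, sqrt(1 - spec$h2_cis))
  p <- length(ids)
  span <- gene_span %||% c(.synth_positions(p)[max(1L, p %/% 3L)],
                           .synth_positions(p)[min(p, (2L * p) %/% 3L)])
  idx <- match(causal_ids, ids)
  model <- weight_model(feature_id, modality, tissue, chr = 1L,
                        start = span[1L], stop = span[2L],
                        entries = data.frame(snp_id = causal_ids,
                                             a1 = panel$snps$a1[idx],
                                             a2 = panel$snps$a2[idx],
                                             weight = w),
                        training_r2 = spec$h2_cis)
  list(model = model, values = values, causal_ids = causal_ids)
}

#' Simulate GWAS summary statistics from standardized causal effects
#'
#' z-scores are drawn directly from their asymptotic sampling distribution,
#' `z ~ MVN(sqrt(n) R b, R)` with `R` the panel dosage correlation matrix
#' and `b` per-SNP effects on the standardized-trait / standardized-genotype
#' scale; beta, se, freq and n are back-filled consistently
#' (`se = 1/sqrt(n * 2 f (1-f))` on the standardized-trait scale).
#'
#' @param panel an [ld_panel()] whose correlation structure defines R.
#' @param causal_betas named (or panel-ordered) per-SNP standardized
#'   effects; zeros for non-causal SNPs.
#' @param n_gwas effective sample size (> 0).
#' @param seed integer seed.
#' @param trait_id trait label.
#' @param ridge stabilization used for the Cholesky draw.
#' @return A [gwas_sumstats()] object covering every panel SNP.
#' @export
simulate_gwas_sumstats <- function(panel, causal_betas, n_gwas, seed,
                                   trait_id = "trait1", ridge = 0.01) {
  if (n_gwas <= 0) stop("n_gwas must be positive", call. = FALSE)
  ids <- panel$snps$snp_id
  b <- rep(0, length(ids))
  if (length(causal_betas) == 0L) {
    # global null: no causal effects
  } else if (!is.null(names(causal_betas))) {
    idx <- match(names(causal_betas), ids)
    if (anyNA(idx))
      stop("causal effect on SNP absent from panel: ",
           paste(names(causal_betas)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    b[idx] <- causal_betas
  } else {
    if (length(causal_betas) != length(ids))
      stop("unnamed causal_betas must cover every panel SNP", call. = FALSE)
    b <- causal_betas
  }
  R <- panel_cor(panel)
  mu <- sqrt(n_gwas) * drop(R %*% b)
  L <- chol(ridge_cor(R, ridge))
  set.seed(seed)
  z <- mu + drop(stats::rnorm(length(ids)) %*% L)
  f <- pmin(pmax(panel_freq(panel), 1 / (2 * nrow(panel$dosages))),
            1 - 1 / (2 * nrow(panel$dosages)))
  se <- 1 / sqrt(n_gwas * 2 * f * (1 - f))
  gwas_sumstats(trait_id,
                data.frame(snp_id = ids, chr = panel$snps$chr,
                           pos = panel$snps$pos, a1 = panel$snps$a1,
                           a2 = panel$snps$a2, freq = f, beta = z * se,
                           se = se, z = z, n = n_gwas))
}

# Standardized causal effect vector implied by mediation of a feature:
# trait effect at SNP k = alpha * (feature's standardized weight at k).
.mediated_betas <- function(model, alpha) {
  stats::setNames(alpha * model$entries$weight, model$entries$snp_id)
}

# Pick the pair of panel SNPs whose empirical dosage r2 is closest to
# `target` within `band`; errors if none falls inside the band.
.pick_ld_pair <- function(panel, target = 0.3, band = c(0.15, 0.5)) {
  R2 <- panel_cor(panel)^2
  diag(R2) <- NA
  p <- ncol(R2)
  best <- NULL; best_d <- Inf
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    if (!is.na(R2[i, j]) && R2[i, j] >= band[1L] && R2[i, j] <= band[2L]) {
      d <- abs(R2[i, j] - target)
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
  }
  if (is.null(best))
    stop("panel has no SNP pair with r2 in [", band[1L], ", ", band[2L],
         "]; increase p_snps or adjust ld_decay", call. = FALSE)
  panel$snps$snp_id[best]
}

# Pick two SNPs with r2 below `max_r2`, well separated in the region.
.pick_low_ld_pair <- function(panel, max_r2 = 0.05) {
  ids <- panel$snps$snp_id
  p <- length(ids)
  R2 <- panel_cor(panel)^2
  i <- max(1L, p %/% 4L)
  for (j in rev(seq_len(p))) {
    if (j > i && R2[i, j] < max_r2) return(ids[c(i, j)])
  }
  stop("no low-LD SNP pair found", call. = FALSE)
}

#' Build a named scenario bundle with known ground truth
#'
#' Generates the LD reference panel, a QTL training panel, one or two
#' cis-heritable features (with their true-effect weight models and
#' individual-level values in the QTL panel), QTL summary statistics per
#' feature, trait GWAS summary statistics under the scenario's mediation
#' structure, and a `truth` record for downstream evaluation.
#'
#' @param spec a [scenario_spec()].
#' @return List of class `ScenarioBundle` with elements `spec`, `panel`,
#'   `qtl_panel`, `features`, `weights_true`, `qtl_sumstats`, `gwas`,
#'   `truth`.
#' @export
make_scenario <- function(spec) {
  seeds <- derive_seeds(spec$seed, 12L)
  panel <- simulate_ld_panel(spec, seed = seeds[1L])
  qspec <- spec; qspec$n_panel <- spec$n_qtl
  qtl_panel <- simulate_ld_panel(qspec, seed = seeds[2L])
  alpha <- spec$alpha_mediation
  feats <- list(); gwas <- list(); truth_trait <- list()
  rho_true <- NA_real_; expected <- character()

  feat <- function(causal, id, seed, panel_ = qtl_panel)
    simulate_feature(panel_, spec, causal_ids = causal, feature_id = id,
                     seed = seed)

  if (spec$name == "null") {
    feats$GENE1 <- feat(NULL, "GENE1", seeds[3L])
    gwas$trait1 <- simulate_gwas_sumstats(panel, numeric(0) ,
                                          spec$n_gwas, seeds[4L], "trait1")
    truth_trait$trait1 <- character()
    expected <- c(GENE1.trait1 = "none")
  } else if (spec$name == "single_shared") {
    s1 <- panel$snps$snp_id[spec$p_snps %/% 2L]
    feats$GENE1 <- feat(s1, "GENE1", seeds[3L])
    feats$GENE2 <- feat(s1, "GENE2", seeds[5L])
    b <- .mediated_betas(feats$GENE1$model, alpha)
    gwas$trait1 <- simulate_gwas_sumstats(panel, b, spec$n_gwas,
                                          seeds[4L], "trait1")
    truth_trait$trait1 <- s1
    expected <- c(GENE1.trait1 = "H4", GENE2.trait1 = "H4")
  } else if (spec$name == "distinct_in_ld") {
    pr <- .pick_ld_pair(panel)
    feats$GENE1 <- feat(pr[1L], "GENE1", seeds[3L])
    b <- stats::setNames(alpha * sqrt(spec$h2_cis), pr[2L])
    gwas$trait1 <- simulate_gwas_sumstats(panel, b, spec$n_gwas,
                                          seeds[4L], "trait1")
    truth_trait$trait1 <- pr[2L]
    expected <- c(GENE1.trait1 = "H3")
  } else if (spec$name == "two_signals") {
    pr <- .pick_low_ld_pair(panel)
    feats$GENE1 <- feat(pr[1L], "GENE1", seeds[3L])
    feats$GENE2 <- feat(pr[2L], "GENE2", seeds[5L])
    b <- c(.mediated_betas(feats$GENE1$model, alpha),
           .mediated_betas(feats$GENE2$model, alpha))
    gwas$trait1 <- simulate_gwas_sumstats(panel, b, spec$n_gwas,
                                          seeds[4L], "trait1")
    truth_trait$trait1 <- pr
    expected <- c(GENE1.trait1 = "H4", GENE2.trait1 = "H4")
  } else if (spec$name == "coregulated_pair") {
    ids <- panel$snps$snp_id
    pr <- .pick_low_ld_pair(panel)
    sA <- pr[1L]; sC <- pr[2L]
    feats$GENE1 <- feat(sA, "GENE1", seeds[3L])
    # co-regulated partner: genetic value rho*gA + sqrt(1-rho^2)*gC on the
    # standardized-genetic scale, so cor(gA, gB) ~ rho_target
    rho <- spec$rho_target
    wA <- feats$GENE1$model$entries$weight / sqrt(spec$h2_cis)
    wB <- c(rho * wA, sqrt(1 - rho^2)) * sqrt(spec$h2_cis)
    Xb <- standardize_columns(qtl_panel$dosages[, c(sA, sC), drop = FALSE])
    gB <- drop(Xb %*% wB)
    set.seed(seeds[5L])
    idx <- match(c(sA, sC), ids)
    modelB <- weight_model("GENE2", "expression", "synth_tissue", chr = 1L,
                           start = feats$GENE1$model$start,
                           stop = feats$GENE1$model$stop,
                           entries = data.frame(snp_id = c(sA, sC),
                                                a1 = panel$snps$a1[idx],
                                                a2 = panel$snps$a2[idx],
                                                weight = wB),
                           training_r2 = spec$h2_cis)
    feats$GENE2 <- list(model = modelB,
                        values = gB + stats::rnorm(nrow(Xb), 0,
                                                   sqrt(1 - spec$h2_cis)),
                        causal_ids = c(sA, sC))
    rho_true <- rho
    b <- .mediated_betas(feats$GENE1$model, alpha)
    gwas$trait1 <- simulate_gwas_sumstats(panel, b, spec$n_gwas,
                                          seeds[4L], "trait1")
    gwas$trait2 <- simulate_gwas_sumstats(panel, b, spec$n_gwas,
                                          seeds[6L], "trait2")
    truth_trait$trait1 <- sA
    truth_trait$trait2 <- sA
    expected <- c(GENE1.trait1 = "H4", GENE1.trait2 = "H4")
  }

  qtl_ss <- lapply(stats::setNames(names(feats), names(feats)), function(id) {
    m <- feats[[id]]$model
    simulate_gwas_sumstats(panel, stats::setNames(m$entries$weight,
                                                  m$entries$snp_id),
                           spec$n_qtl,
                           seeds[7L] + match(id, names(feats)),
                           trait_id = paste0("qtl_", id))
  })

  truth <- list(
    feature_causal = lapply(feats, `[[`, "causal_ids"),
    trait_causal = truth_trait,
    rho_true = rho_true,
    expected_coloc = as.list(expected))

  structure(list(spec = spec, panel = panel, qtl_panel = qtl_panel,
                 features = feats,
                 weights_true = lapply(feats, `[[`, "model"),
                 qtl_sumstats = qtl_ss, gwas = gwas, truth = truth),
            class = "ScenarioBundle")
}

#' Write a scenario bundle to disk in the package's file dialects
#'
#' @param bundle a [make_scenario()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  write_ld_panel(bundle$panel, file.path(dir, "panel"))
  paths["panel"] <- file.path(dir, "panel.snps.tsv")
  write_ld_panel(bundle$qtl_panel, file.path(dir, "qtl_panel"))
  paths["qtl_panel"] <- file.path(dir, "qtl_panel.snps.tsv")
  paths["weights"] <- write_weight_manifest(bundle$weights_true,
                                            file.path(dir, "weights_true"))
  for (tr in names(bundle$gwas)) {
    p <- file.path(dir, paste0(tr, ".sumstats.tsv"))
    write_gwas_sumstats(bundle$gwas[[tr]], p)
    paths[paste0("gwas_", tr)] <- p
  }
  for (id in names(bundle$qtl_sumstats)) {
    p <- file.path(dir, paste0("qtl_", id, ".sumstats.tsv"))
    write_gwas_sumstats(bundle$qtl_sumstats[[id]], p)
    paths[paste0("qtl_", id)] <- p
  }
  fv <- data.frame(lapply(bundle$features, `[[`, "values"))
  data.table::fwrite(fv, file.path(dir, "feature_values.tsv"), sep = "\t")
  paths["feature_values"] <- file.path(dir, "feature_values.tsv")
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["truth"] <- file.path(dir, "truth.json")
  yaml::write_yaml(unclass(bundle$spec), file.path(dir, "scenario.yaml"))
  paths["spec"] <- file.path(dir, "scenario.yaml")
  invisible(paths)
}
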