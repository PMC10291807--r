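#' Colocalization configuration
#'
#' Priors of the five-hypothesis colocalization model: `p1`/`p2` are the
#' prior probabilities that a SNP is causal for trait 1 / trait 2 alone,
#' `p12` that it is causal for both; `prior_var_W` is the Wakefield
#' effect-size prior variance (0.15^2 for quantitative traits).
#'
#' @param prior_var_W effect-size prior variance.
#' @param p1,p2,p12 per-SNP causal priors; `p12 <= min(p1, p2)`.
#' @param pp4_report posterior probability of a shared variant (H4) above
#'   which a pair is reported colocalized.
#' @return Object of class `ColocConfig`.
#' @export
coloc_config <- function(prior_var_W = 0.15^2, p1 = 1e-4, p2 = 1e-4,
                         p12 = 1e-5, pp4_report = 0.8) {
  for (p in c(p1, p2, p12, pp4_report))
    if (p <= 0 || p >= 1)
      stop("priors and pp4_report must lie in (0, 1)", call. = FALSE)
  if (p12 > min(p1, p2))
    stop("p12 must not exceed min(p1, p2)", call. = FALSE)
  if (prior_var_W <= 0) stop("prior_var_W must be > 0", call. = FALSE)
  structure(list(prior_var_W = prior_var_W, p1 = p1, p2 = p2, p12 = p12,
                 pp4_report = pp4_report), class = "ColocConfig")
}

#' Wakefield log approximate Bayes factor
#'
#' With `V = se^2`, `z = beta/se` and prior variance `W`:
#' `labf = 0.5 * (log(V/(V+W)) + z^2 * W/(V+W))`.
#'
#' @param beta,se effect estimate and its standard error (`se > 0`).
#' @param prior_var_W normal prior variance on the true effect (`> 0`).
#' @return Log approximate Bayes factor (vectorized).
#' @export
wakefield_labf <- function(beta, se, prior_var_W = 0.15^2) {
  if (any(!is.na(se) & se <= 0))
    stop("se must be > 0", call. = FALSE)
  if (prior_var_W <= 0) stop("prior_var_W must be > 0", call. = FALSE)
  V <- se^2
  z2 <- (beta / se)^2
  0.5 * (log(V / (V + prior_var_W)) + z2 * prior_var_W / (V + prior_var_W))
}

#' Posterior inclusion probabilities under a single-causal-variant model
#'
#' `pip_k = exp(labf_k - logsumexp(labf))`; numerically stable for large
#' labf spreads.
#'
#' @param labfs per-SNP log approximate Bayes factors (nonempty).
#' @param snp_ids optional ids attached to the output.
#' @return Object of class `SignalFineMap`: data.frame with `snp_id`,
#'   `labf`, `pip` (summing to 1).
#' @export
pip_from_labf <- function(labfs, snp_ids = NULL) {
  if (length(labfs) == 0L) stop("no labfs supplied", call. = FALSE)
  lse <- logsumexp(labfs)
  pip <- exp(labfs - lse)
  out <- data.frame(snp_id = snp_ids %||% paste0("snp", seq_along(labfs)),
                    labf = labfs, pip = pip)
  class(out) <- c("SignalFineMap", class(out))
  out
}

#' Pairwise colocalization posteriors from two labf vectors
#'
#' Five-hypothesis colocalization over a common SNP set: with
#' `S1 = sum(exp(labf1))`, `S2 = sum(exp(labf2))` and
#' `C = sum(exp(labf1 + labf2))`, the unnormalized masses are `L0 = 1`,
#' `L1 = p1*S1`, `L2 = p2*S2`, `L3 = p1*p2*(S1*S2 - C)`, `L4 = p12*C`,
#' accumulated in log space.
#'
#' @param labf1,labf2 per-SNP log ABFs for the two traits, same SNPs, same
#'   order.
#' @param cfg a [coloc_config()].
#' @param qtl_signal,trait_signal identifiers carried into the result.
#' @return Object of class `ColocResult`: one-row data.frame with
#'   `pp_h0 ... pp_h4`, `n_snps_common`, `low_coverage`, `colocalized`.
#' @export
coloc_pair <- function(labf1, labf2, cfg = coloc_config(),
                       qtl_signal = "marginal", trait_signal = "marginal") {
  ok <- !is.na(labf1) & !is.na(labf2)
  labf1 <- labf1[ok]; labf2 <- labf2[ok]
  m <- length(labf1)
  if (m < 1L)
    stop("fewer than one common SNP between the two signals", call. = FALSE)
  lS1 <- logsumexp(labf1)
  lS2 <- logsumexp(labf2)
  lC <- logsumexp(labf1 + labf2)
  lL <- c(h0 = 0,
          h1 = log(cfg$p1) + lS1,
          h2 = log(cfg$p2) + lS2,
          h3 = NA_real_,
          h4 = log(cfg$p12) + lC)
  # L3 = p1 p2 (S1 S2 - C), computed as log-diff; clamp tiny negatives
  d <- lS1 + lS2
  if (m == 1L || lC >= d) {
    lL["h3"] <- -Inf
    if (m > 1L && lC > d + 1e-9)
      warning("S1*S2 < C by rounding; H3 mass clamped to 0", call. = FALSE)
  } else {
    lL["h3"] <- log(cfg$p1) + log(cfg$p2) + d + log1p(-exp(lC - d))
  }
  pp <- exp(lL - logsumexp(lL))
  pp <- pp / sum(pp)
  out <- data.frame(qtl_signal = qtl_signal, trait_signal = trait_signal,
                    pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]],
                    pp_h2 = pp[["h2"]], pp_h3 = pp[["h3"]],
                    pp_h4 = pp[["h4"]], n_snps_common = m,
                    low_coverage = m < 10L,
                    colocalized = pp[["h4"]] >= cfg$pp4_report)
  class(out) <- c("ColocResult", class(out))
  out
}

# Per-signal (b, se) tables for colocalization: conditional tables per lead
# when a dataset has >= 2 independent signals, otherwise the marginals.
.signal_tables <- function(stats, sset) {
  if (length(sset$lead_snps) >= 2L) {
    lapply(sset$conditional, function(cs) {
      ok <- !cs$masked
      data.frame(snp_id = cs$snp_id[ok], b = cs$b_cond[ok],
                 se = cs$se_cond[ok])
    })
  } else {
    list(marginal = data.frame(snp_id = stats$snp_id, b = stats$b,
                               se = stats$se))
  }
}

#' Conditional colocalization of a molecular feature against a trait
#'
#' Within the gene span plus `flank`, both datasets are decomposed into
#' conditionally independent signals ([cojo_slct()]); for a dataset with
#' two or more leads the per-lead conditional statistics are used, else the
#' marginals ("if one or no independent genome-wide significant association
#' was detected, marginal summary statistics were used").  Wakefield labfs
#' are computed per signal and [coloc_pair()] evaluated for every
#' (QTL signal x trait signal) combination.
#'
#' @param qtl a [gwas_sumstats()] object for the molecular feature.
#' @param trait a [gwas_sumstats()] object for the trait.
#' @param panel an [ld_panel()].
#' @param gene_span numeric `(chr, start, stop)`.
#' @param cfg a [coloc_config()].
#' @param flank window flank in bp (default 250 kb).
#' @param p_entry,collinearity,ridge COJO settings.
#' @return data.frame of `ColocResult` rows (one per signal pair) with an
#'   attribute `signals` holding the two `SignalSet`s.
#' @export
conditional_coloc <- function(qtl, trait, panel, gene_span,
                              cfg = coloc_config(), flank = 2.5e5,
                              p_entry = 5e-8, collinearity = 0.1,
                              ridge = 0.01) {
  gs <- unlist(gene_span)
  chr <- gs[[1L]]; start <- gs[[2L]] - flank; stop_ <- gs[[3L]] + flank
  st_q <- marginal_stats(qtl, panel, chr, start, stop_)
  st_t <- marginal_stats(trait, panel, chr, start, stop_)
  ss_q <- cojo_slct(st_q, panel, p_entry = p_entry,
                    collinearity = collinearity, ridge = ridge)
  ss_t <- cojo_slct(st_t, panel, p_entry = p_entry,
                    collinearity = collinearity, ridge = ridge)
  tab_q <- .signal_tables(st_q, ss_q)
  tab_t <- .signal_tables(st_t, ss_t)
  rows <- list()
  for (nq in names(tab_q)) for (nt in names(tab_t)) {
    tq <- tab_q[[nq]]; tt <- tab_t[[nt]]
    common <- intersect(tq$snp_id, tt$snp_id)
    if (length(common) < 1L) next
    iq <- match(common, tq$snp_id); it <- match(common, tt$snp_id)
    l1 <- wakefield_labf(tq$b[iq], tq$se[iq], cfg$prior_var_W)
    l2 <- wakefield_labf(tt$b[it], tt$se[it], cfg$prior_var_W)
    rows[[length(rows) + 1L]] <-
      coloc_pair(l1, l2, cfg, qtl_signal = nq, trait_signal = nt)
  }
  if (length(rows) == 0L)
    stop("no signal pair shares a SNP", call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "signals") <- list(qtl = ss_q, trait = ss_t)
  out
}
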