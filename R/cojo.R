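#' Extract a region view of summary statistics harmonized to a panel
#'
#' @param sumstats a [gwas_sumstats()] object.
#' @param panel an [ld_panel()].
#' @param chr,start,stop window (1-based inclusive); defaults cover the
#'   whole panel.
#' @return data.frame of class `MarginalStats` with per-SNP
#'   `snp_id, pos, b, se, f, n, z`, ordered by position.
#' @export
marginal_stats <- function(sumstats, panel, chr = NULL, start = -Inf,
                           stop = Inf) {
  h <- harmonize_alleles(sumstats, panel)
  rec <- h$records
  keep <- rec$pos >= start & rec$pos <= stop
  if (!is.null(chr)) keep <- keep & rec$chr == chr
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no harmonized SNPs in window", call. = FALSE)
  if (any(is.na(rec$beta) | is.na(rec$se)))
    stop("conditional analysis requires beta and se (full dialect)",
         call. = FALSE)
  out <- data.frame(snp_id = rec$snp_id, pos = rec$pos, b = rec$beta,
                    se = rec$se, f = rec$freq, n = rec$n, z = rec$z)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MarginalStats", class(out))
  out
}

# Reconstructed X'X entries from reference LD: diagonal D_k = 2 f_k (1-f_k)
# N_k; off-diagonal r_jk * sqrt(2 f_j (1-f_j) * 2 f_k (1-f_k)) * min(N_j, N_k).
.cojo_xtx <- function(stats, idx, R) {
  f <- stats$f[idx]; N <- stats$n[idx]
  s <- sqrt(2 * f * (1 - f))
  B <- R * outer(s, s) * outer(N, N, pmin)
  diag(B) <- 2 * f * (1 - f) * N
  B
}

# Region-level phenotypic variance: median over SNPs of
# 2 f (1-f) (N se^2 + b^2)  (simple-regression identity up to O(1/N)).
.cojo_vary <- function(stats)
  stats::median(2 * stats$f * (1 - stats$f) *
                  (stats$n * stats$se^2 + stats$b^2))

#' Approximate joint fit of a SNP set from marginal statistics
#'
#' Reconstructs the multiple-regression solution the way GCTA-COJO does:
#' genotype cross-products are approximated from reference correlations
#' scaled by per-SNP genotype SDs and the smaller sample size of each pair,
#' the right-hand side is `D_k b_k`, and the residual variance comes from a
#' region-median phenotypic-variance estimate with
#' `min(N) - |set|` degrees of freedom.  A single-SNP set returns the
#' marginal statistics unchanged (the joint model of one SNP is the
#' marginal model).
#'
#' @param stats a [marginal_stats()] view.
#' @param snp_set SNP ids to fit jointly (pairwise reference r-squared must
#'   not exceed `collinearity`).
#' @param panel an [ld_panel()].
#' @param ridge stabilization of the selected-set correlation matrix.
#' @param collinearity pairwise r-squared cutoff checked on entry.
#' @return data.frame with per-SNP `snp_id, b_joint, se_joint, p_joint`.
#' @export
approx_joint_fit <- function(stats, snp_set, panel, ridge = 0.01,
                             collinearity = 0.1) {
  idx <- match(snp_set, stats$snp_id)
  if (length(idx) == 0L || anyNA(idx))
    stop("snp_set empty or absent from stats", call. = FALSE)
  if (length(idx) == 1L) {
    return(data.frame(snp_id = snp_set, b_joint = stats$b[idx],
                      se_joint = stats$se[idx],
                      p_joint = z_to_p(stats$b[idx] / stats$se[idx])))
  }
  R <- panel_cor(panel, snp_set, ridge = ridge)
  R2 <- R^2; diag(R2) <- 0
  if (max(R2) > collinearity)
    stop("snp_set violates the pairwise collinearity cutoff (max r2 = ",
         signif(max(R2), 3), ")", call. = FALSE)
  B <- .cojo_xtx(stats, idx, R)
  D <- diag(B)
  wvec <- D * stats$b[idx]
  Binv <- tryCatch(solve(B), error = function(e)
    stop("singular joint system after ridge stabilization", call. = FALSE))
  b_j <- drop(Binv %*% wvec)
  n_min <- min(stats$n[idx])
  yty <- .cojo_vary(stats) * n_min
  df <- max(n_min - length(idx), 1)
  sigma2 <- max((yty - sum(b_j * wvec)) / df, .Machine$double.eps)
  se_j <- sqrt(diag(Binv) * sigma2)
  data.frame(snp_id = snp_set, b_joint = b_j, se_joint = se_j,
             p_joint = z_to_p(b_j / se_j))
}

#' Conditional statistics given a set of index SNPs
#'
#' The conditional effect of each target SNP is its marginal effect minus
#' the LD-projected contribution of the joint effects of the conditioning
#' set; targets with reference r-squared above the collinearity cutoff to
#' any conditioning SNP are masked (`NA`), not zeroed.
#'
#' @param stats a [marginal_stats()] view.
#' @param condition_on SNP ids to condition on (nonempty).
#' @param panel an [ld_panel()].
#' @param collinearity r-squared masking cutoff.
#' @param ridge stabilization for the conditioning-set correlation.
#' @return data.frame over the non-conditioning SNPs with
#'   `snp_id, pos, b_cond, se_cond, z_cond, p_cond, masked`.
#' @export
conditional_stats <- function(stats, condition_on, panel,
                              collinearity = 0.1, ridge = 0.01) {
  if (length(condition_on) == 0L)
    stop("empty conditioning set; use the marginal statistics directly",
         call. = FALSE)
  cidx <- match(condition_on, stats$snp_id)
  if (anyNA(cidx))
    stop("conditioning SNP(s) absent from stats", call. = FALSE)
  joint <- approx_joint_fit(stats, condition_on, panel, ridge = ridge,
                            collinearity = Inf)
  targets <- setdiff(stats$snp_id, condition_on)
  tidx <- match(targets, stats$snp_id)
  Rall <- panel_cor(panel, c(targets, condition_on), ridge = 0)
  nt <- length(targets)
  Rtc <- Rall[seq_len(nt), nt + seq_along(condition_on), drop = FALSE]

  f_t <- stats$f[tidx]; N_t <- stats$n[tidx]
  D_t <- 2 * f_t * (1 - f_t) * N_t
  s_t <- sqrt(2 * f_t * (1 - f_t))
  f_c <- stats$f[cidx]; N_c <- stats$n[cidx]
  s_c <- sqrt(2 * f_c * (1 - f_c))
  # cross X'X blocks, same reconstruction as the joint fit
  Btc <- Rtc * outer(s_t, s_c) * outer(N_t, N_c, pmin)

  b_cond <- stats$b[tidx] - drop(Btc %*% joint$b_joint) / D_t

  # residual variance from the conditioning-set joint model
  Rcc <- panel_cor(panel, condition_on, ridge = ridge)
  Bcc <- .cojo_xtx(stats, cidx, Rcc)
  wc <- diag(Bcc) * stats$b[cidx]
  n_min <- min(stats$n[cidx])
  yty <- .cojo_vary(stats) * n_min
  df <- max(n_min - length(cidx), 1)
  sigma2 <- max((yty - sum(joint$b_joint * wc)) / df, .Machine$double.eps)
  se_cond <- sqrt(sigma2 / D_t)

  masked <- apply(Rtc^2, 1L, max) > collinearity
  b_cond[masked] <- NA_real_
  se_cond[masked] <- NA_real_
  z_cond <- b_cond / se_cond
  data.frame(snp_id = targets, pos = stats$pos[tidx], b_cond = b_cond,
             se_cond = se_cond, z_cond = z_cond, p_cond = z_to_p(z_cond),
             masked = masked)
}

#' Stepwise selection of conditionally independent signals (COJO-Slct)
#'
#' Forward selection seeded with the smallest marginal p-value; each
#' subsequent step adds the SNP with the smallest conditional p-value below
#' `p_entry` whose reference r-squared with every selected SNP is at most
#' `collinearity`; after each addition a backward check drops any selected
#' SNP whose joint p-value rises above `p_entry`.  Ties in minimal p are
#' broken by smaller genomic position.
#'
#' @param stats a [marginal_stats()] view.
#' @param panel an [ld_panel()].
#' @param p_entry conditional p-value entry threshold (default 5e-8).
#' @param collinearity pairwise r-squared cutoff (default 0.1).
#' @param ridge stabilization constant.
#' @param backward apply the backward-elimination check (default `TRUE`).
#' @return Object of class `SignalSet`: `lead_snps` (ordered ids), `joint`
#'   (per-lead joint statistics), `conditional` (named list: per-lead
#'   conditional table given the other leads; `NULL` with fewer than two
#'   leads), `used_marginal` flag.
#' @export
cojo_slct <- function(stats, panel, p_entry = 5e-8, collinearity = 0.1,
                      ridge = 0.01, backward = TRUE) {
  pick_min <- function(p, pos) {
    ok <- which(!is.na(p))
    if (length(ok) == 0L) return(NA_integer_)
    pm <- min(p[ok])
    cand <- ok[p[ok] == pm]
    cand[which.min(pos[cand])]
  }
  sel <- character()
  excluded <- character()
  p_marg <- z_to_p(stats$z)
  repeat {
    if (length(sel) == 0L) {
      i <- pick_min(p_marg, stats$pos)
      if (is.na(i) || p_marg[i] >= p_entry) break
      sel <- stats$snp_id[i]
    } else {
      cs <- conditional_stats(stats, sel, panel, collinearity = collinearity,
                              ridge = ridge)
      cs <- cs[!(cs$snp_id %in% excluded), , drop = FALSE]
      i <- pick_min(cs$p_cond, cs$pos)
      if (is.na(i) || cs$p_cond[i] >= p_entry) break
      cand <- cs$snp_id[i]
      new_sel <- c(sel, cand)
      if (backward) {
        jf <- approx_joint_fit(stats, new_sel, panel, ridge = ridge,
                               collinearity = collinearity)
        drop_ids <- jf$snp_id[jf$p_joint >= p_entry]
        if (cand %in% drop_ids) {
          # the new SNP does not survive jointly: exclude it and continue
          excluded <- c(excluded, cand)
          next
        }
        if (length(drop_ids)) {
          excluded <- c(excluded, drop_ids)
          new_sel <- setdiff(new_sel, drop_ids)
        }
      }
      sel <- new_sel
    }
  }
  joint <- if (length(sel))
    approx_joint_fit(stats, sel, panel, ridge = ridge,
                     collinearity = collinearity)
  else
    data.frame(snp_id = character(), b_joint = numeric(),
               se_joint = numeric(), p_joint = numeric())
  conditional <- NULL
  if (length(sel) >= 2L) {
    conditional <- lapply(stats::setNames(sel, sel), function(s)
      conditional_stats(stats, setdiff(sel, s), panel,
                        collinearity = collinearity, ridge = ridge))
  }
  structure(list(lead_snps = sel, joint = joint, conditional = conditional,
                 used_marginal = length(sel) <= 1L,
                 p_entry = p_entry, collinearity = collinearity),
            class = "SignalSet")
}

#' @export
print.SignalSet <- function(x, ...) {
  cat("<SignalSet> ", length(x$lead_snps), " independent signal(s)",
      if (x$used_marginal) " (marginal statistics in use)", "\n", sep = "")
  if (length(x$lead_snps)) print(x$joint)
  invisible(x)
}
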