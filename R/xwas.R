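#' TWAS/PWAS association statistic for one feature
#'
#' Computes the summary-statistic association between a genetically
#' predicted feature and a trait: `z = w'z / sqrt(w'Rw)` over the model
#' SNPs surviving harmonization, with `R` the ridge-stabilized panel
#' correlation submatrix.
#'
#' @param model a [weight_model()].
#' @param gwas a [gwas_sumstats()] object (harmonized internally).
#' @param panel an [ld_panel()].
#' @param ridge diagonal stabilization for R (default 0.01).
#' @return A one-row data.frame (class `XwasResult`): `feature_id`,
#'   `tissue`, `modality`, `trait_id`, `z_xwas`, `p_xwas`, `n_snps_used`,
#'   `degraded` (TRUE when fewer than half the model weights survive
#'   harmonization).
#' @export
xwas_z <- function(model, gwas, panel, ridge = 0.01) {
  if (model$untrainable)
    stop("model ", model$feature_id, " is untrainable", call. = FALSE)
  h <- harmonize_alleles(gwas, panel)
  rec <- h$records
  idx <- match(model$entries$snp_id, rec$snp_id)
  keep <- !is.na(idx)
  if (!any(keep))
    stop("no model SNP of ", model$feature_id,
         " survives in the harmonized GWAS/panel overlap", call. = FALSE)
  snp_ids <- model$entries$snp_id[keep]
  w <- model$entries$weight[keep]
  # align model alleles to panel orientation (same convention as imputation)
  pidx <- match(snp_ids, panel$snps$snp_id)
  a1 <- toupper(model$entries$a1[keep]); a2 <- toupper(model$entries$a2[keep])
  p1 <- toupper(panel$snps$a1[pidx]); p2 <- toupper(panel$snps$a2[pidx])
  same <- a1 == p1 & a2 == p2
  swap <- a1 == p2 & a2 == p1 & !same
  bad <- !same & !swap
  if (any(bad)) {
    snp_ids <- snp_ids[!bad]; w <- w[!bad]
    same <- same[!bad]; swap <- swap[!bad]
    if (length(snp_ids) == 0L)
      stop("no model SNP of ", model$feature_id,
           " has reconcilable alleles", call. = FALSE)
  }
  w[swap] <- -w[swap]
  z <- rec$z[match(snp_ids, rec$snp_id)]
  R <- panel_cor(panel, snp_ids, ridge = ridge)
  denom <- drop(t(w) %*% R %*% w)
  if (denom <= 0)
    stop("non-positive w'Rw for ", model$feature_id,
         " after stabilization", call. = FALSE)
  zx <- sum(w * z) / sqrt(denom)
  out <- data.frame(feature_id = model$feature_id, tissue = model$tissue,
                    modality = model$modality, trait_id = gwas$trait_id,
                    z_xwas = zx, p_xwas = z_to_p(zx),
                    n_snps_used = length(snp_ids),
                    degraded = length(snp_ids) <
                      sum(model$entries$weight != 0) / 2)
  class(out) <- c("XwasResult", class(out))
  out
}

#' Bonferroni threshold over unique features
#'
#' Uniqueness is by feature, not by feature x tissue: a gene modelled in
#' several tissues counts once, an aptamer counts once.  With 12,893 unique
#' genes at alpha = 0.05 this gives 3.9e-6 (two significant figures); with
#' 1342 unique aptamers, 3.7e-5.
#'
#' @param n_unique_features number of unique features (>= 1).
#' @param alpha family-wise error level in (0, 1).
#' @return The per-test threshold `alpha / n_unique_features`.
#' @export
bonferroni_threshold <- function(n_unique_features, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (n_unique_features < 1)
    stop("n_unique_features must be >= 1", call. = FALSE)
  alpha / n_unique_features
}

#' Run the xWAS screen over a set of weight models
#'
#' One association row per (feature x tissue, trait).  The significance
#' threshold is computed once per modality from the count of unique
#' features of that modality (genes across tissues counted once).
#' Per-feature errors are logged as warnings and the feature skipped.
#'
#' @param models list of [weight_model()]s.
#' @param gwas_list one [gwas_sumstats()] or a list of them (one per trait).
#' @param panel an [ld_panel()].
#' @param alpha family-wise error level.
#' @param ridge stabilization for the quadratic form.
#' @return data.frame of results sorted by p-value, with a `significant`
#'   flag and the applied `threshold`.
#' @export
run_xwas_screen <- function(models, gwas_list, panel, alpha = 0.05,
                            ridge = 0.01) {
  if (length(models) == 0L) stop("empty model manifest", call. = FALSE)
  if (inherits(gwas_list, "GwasSumstats")) gwas_list <- list(gwas_list)
  modality <- vapply(models, `[[`, "", "modality")
  feat <- vapply(models, `[[`, "", "feature_id")
  n_unique <- tapply(feat, modality, function(x) length(unique(x)))
  thr <- vapply(names(n_unique), function(m)
    bonferroni_threshold(n_unique[[m]], alpha), numeric(1L))
  rows <- list()
  for (g in gwas_list) {
    for (m in models) {
      r <- tryCatch(xwas_z(m, g, panel, ridge = ridge), error = function(e) {
        warning("skipping ", m$feature_id, " x ", g$trait_id, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (!is.null(r)) {
        r$threshold <- thr[[m$modality]]
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  if (length(rows) == 0L)
    stop("no feature could be tested", call. = FALSE)
  out <- do.call(rbind, rows)
  out$significant <- out$p_xwas < out$threshold
  out[order(out$p_xwas), , drop = FALSE]
}

#' Classify features shared between two traits
#'
#' A feature x tissue is `shared` when significant for both traits at each
#' trait's own threshold; otherwise it is labelled for the trait where it
#' is significant.
#'
#' @param res1,res2 xWAS result data.frames for the two traits (as from
#'   [run_xwas_screen()]).
#' @return data.frame with `feature_id`, `tissue` and `label` in
#'   `{trait1_only, trait2_only, shared}` covering every feature significant
#'   in at least one trait.
#' @export
classify_shared <- function(res1, res2) {
  key <- function(d) paste(d$feature_id, d$tissue, sep = "\r")
  s1 <- unique(key(res1[res1$significant, , drop = FALSE]))
  s2 <- unique(key(res2[res2$significant, , drop = FALSE]))
  all_k <- union(s1, s2)
  if (length(all_k) == 0L)
    return(data.frame(feature_id = character(), tissue = character(),
                      label = character()))
  parts <- do.call(rbind, strsplit(all_k, "\r", fixed = TRUE))
  lab <- ifelse(all_k %in% s1 & all_k %in% s2, "shared",
                ifelse(all_k %in% s1, "trait1_only", "trait2_only"))
  data.frame(feature_id = parts[, 1L], tissue = parts[, 2L], label = lab)
}
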