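#' Configuration for cis elastic-net training
#'
#' @param cis_window_bp distance from the gene span defining eligible SNPs
#'   (default 500 kb each side, the same window constant used for region
#'   arithmetic).
#' @param l1_ratio elastic-net mixing parameter in (0, 1]; 1 is the lasso.
#' @param cv_folds cross-validation folds (>= 3).
#' @param penalty_grid positive penalty values; defaults to 20 log-spaced
#'   values chosen from the data by glmnet's rule.
#' @param n_penalties size of the default grid.
#' @param seed integer seed controlling fold assignment.
#' @return Object of class `CisTrainingConfig`.
#' @export
cis_training_config <- function(cis_window_bp = 5e5, l1_ratio = 0.5,
                                cv_folds = 5L, penalty_grid = NULL,
                                n_penalties = 20L, seed = 1L) {
  if (cv_folds < 3L) stop("cv_folds must be >= 3", call. = FALSE)
  if (l1_ratio <= 0 || l1_ratio > 1)
    stop("l1_ratio must lie in (0, 1]", call. = FALSE)
  if (!is.null(penalty_grid)) {
    if (length(penalty_grid) == 0L || any(penalty_grid <= 0))
      stop("penalty_grid must be nonempty and positive", call. = FALSE)
    penalty_grid <- sort(penalty_grid, decreasing = TRUE)
  }
  structure(list(cis_window_bp = cis_window_bp, l1_ratio = l1_ratio,
                 cv_folds = as.integer(cv_folds),
                 penalty_grid = penalty_grid,
                 n_penalties = as.integer(n_penalties),
                 seed = as.integer(seed)),
            class = "CisTrainingConfig")
}

#' Train elastic-net cis prediction weights for one feature
#'
#' SNPs within `cis_window_bp` of the gene span are standardized (using
#' panel-estimated frequencies) and the feature is regressed on them with
#' the elastic net over a penalty grid; the penalty with the best
#' cross-validated prediction correlation is selected and `training_r2` set
#' to that cross-validated squared correlation.  A feature whose best
#' cross-validated correlation is not distinguishable from zero (one-sided
#' Fisher-z gate at the 0.01 level, protecting the maximum over the penalty
#' grid from pure noise) yields an empty model flagged `untrainable`.
#'
#' @param panel training genotypes (an [ld_panel()]).
#' @param feature per-individual feature values, length `nrow(dosages)`.
#' @param gene_span numeric `(chr, start, stop)` or list with those names.
#' @param config a [cis_training_config()].
#' @param feature_id,tissue,modality labels for the returned model.
#' @return A [weight_model()] with weights on the standardized-dosage
#'   scale.
#' @export
fit_weights <- function(panel, feature, gene_span,
                        config = cis_training_config(),
                        feature_id = "feature", tissue = "tissue",
                        modality = "expression") {
  gs <- unlist(gene_span)
  chr <- gs[[1L]]; start <- gs[[2L]]; stop_ <- gs[[3L]]
  n <- nrow(panel$dosages)
  if (n < config$cv_folds * 5L)
    stop("need at least ", config$cv_folds * 5L, " individuals", call. = FALSE)
  if (stats::sd(feature) == 0)
    stop("constant feature cannot be trained", call. = FALSE)
  cis <- panel$snps$chr == chr &
    panel$snps$pos >= start - config$cis_window_bp &
    panel$snps$pos <= stop_ + config$cis_window_bp
  if (!any(cis))
    stop("no SNPs in the cis window chr", chr, ":",
         start - config$cis_window_bp, "-", stop_ + config$cis_window_bp,
         call. = FALSE)
  snps <- panel$snps[cis, , drop = FALSE]
  X <- standardize_columns(panel$dosages[, cis, drop = FALSE])
  y <- as.numeric(feature)

  lam <- config$penalty_grid
  if (is.null(lam)) {
    fit0 <- glmnet::glmnet(X, y, alpha = config$l1_ratio, standardize = FALSE,
                           nlambda = config$n_penalties)
    lam <- fit0$lambda
  }
  set.seed(config$seed)
  foldid <- sample(rep(seq_len(config$cv_folds), length.out = n))
  pred <- matrix(NA_real_, n, length(lam))
  for (k in seq_len(config$cv_folds)) {
    hold <- foldid == k
    fit <- glmnet::glmnet(X[!hold, , drop = FALSE], y[!hold],
                          alpha = config$l1_ratio, lambda = lam,
                          standardize = FALSE)
    pred[hold, ] <- stats::predict(fit, X[hold, , drop = FALSE], s = lam)
  }
  cv_cor <- apply(pred, 2L, function(p)
    if (stats::sd(p) == 0) 0 else stats::cor(p, y))
  best <- which.max(cv_cor)
  # untrainable when the best cross-validated prediction correlation is not
  # distinguishable from zero (one-sided Fisher-z gate at 0.01; guards the
  # selection maximum over the penalty grid against pure noise)
  cv_gate <- stats::qnorm(0.99) / sqrt(max(n - 3, 1))
  if (cv_cor[best] <= max(0, cv_gate))
    return(weight_model(feature_id, modality, tissue, chr, start, stop_,
                        entries = data.frame(snp_id = character(),
                                             a1 = character(),
                                             a2 = character(),
                                             weight = numeric()),
                        training_r2 = 0, untrainable = TRUE))
  full <- glmnet::glmnet(X, y, alpha = config$l1_ratio, lambda = lam,
                         standardize = FALSE)
  w <- as.numeric(stats::coef(full, s = lam[best]))[-1L]
  if (all(w == 0)) {
    # a positive CV correlation with an all-zero refit can only arise from
    # numerical degeneracy; treat as untrainable
    return(weight_model(feature_id, modality, tissue, chr, start, stop_,
                        entries = data.frame(snp_id = character(),
                                             a1 = character(),
                                             a2 = character(),
                                             weight = numeric()),
                        training_r2 = 0, untrainable = TRUE))
  }
  keep <- w != 0
  weight_model(feature_id, modality, tissue, chr, start, stop_,
               entries = data.frame(snp_id = snps$snp_id[keep],
                                    a1 = snps$a1[keep], a2 = snps$a2[keep],
                                    weight = w[keep]),
               training_r2 = max(cv_cor[best], 0)^2)
}

#' Impute a molecular feature into a genotype panel
#'
#' Returns `X_std %*% w` where `X_std` is the column-standardized dosage
#' submatrix in model SNP order.  Model alleles are harmonized to the panel
#' first: swapped A1/A2 flips the weight sign; irreconcilable alleles are
#' an error.
#'
#' @param panel an [ld_panel()].
#' @param model a [weight_model()].
#' @return Numeric vector of imputed feature values (one per individual).
#' @export
impute_feature <- function(panel, model) {
  if (model$untrainable || nrow(model$entries) == 0L)
    return(rep(0, nrow(panel$dosages)))
  idx <- match(model$entries$snp_id, panel$snps$snp_id)
  if (anyNA(idx))
    stop("model SNP(s) missing from panel: ",
         paste(model$entries$snp_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  w <- model$entries$weight
  a1 <- toupper(model$entries$a1); a2 <- toupper(model$entries$a2)
  p1 <- toupper(panel$snps$a1[idx]); p2 <- toupper(panel$snps$a2[idx])
  same <- a1 == p1 & a2 == p2
  swap <- a1 == p2 & a2 == p1 & !same
  bad <- !same & !swap
  if (any(bad))
    stop("irreconcilable alleles between model and panel for: ",
         paste(model$entries$snp_id[bad], collapse = ", "), call. = FALSE)
  w[swap] <- -w[swap]
  X <- standardize_columns(panel$dosages[, idx, drop = FALSE])
  drop(X %*% w)
}
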