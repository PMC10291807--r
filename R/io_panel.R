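#' LD reference panel
#'
#' Container for a genotype dosage reference used for allele-frequency and
#' SNP-SNP correlation lookups: a SNP metadata table plus an individuals x
#' SNPs dosage matrix of effect-allele (A1) counts in [0, 2].
#'
#' @param snps data.frame with columns `snp_id`, `chr`, `pos`, `a1`, `a2`,
#'   `freq` (stated A1 frequency in (0, 1)).
#' @param dosages numeric matrix, individuals in rows, SNPs in columns; the
#'   column order must match `snps` and entries must lie in [0, 2].
#' @return An object of class `LdPanel`.
#' @export
ld_panel <- function(snps, dosages) {
  snps <- as.data.frame(snps)
  req <- c("snp_id", "chr", "pos", "a1", "a2", "freq")
  miss <- setdiff(req, names(snps))
  if (length(miss))
    stop("LD panel SNP table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id in LD panel: ",
         snps$snp_id[duplicated(snps$snp_id)][1L], call. = FALSE)
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(snps))
    stop("dosage matrix has ", ncol(dosages), " columns but ", nrow(snps),
         " SNPs are described", call. = FALSE)
  if (min(dosages) < 0 || max(dosages) > 2)
    stop("dosages must lie in [0, 2]", call. = FALSE)
  colnames(dosages) <- snps$snp_id
  sdv <- apply(dosages, 2L, stats::sd)
  if (any(sdv == 0))
    stop("constant dosage column(s) in LD panel: ",
         paste(snps$snp_id[sdv == 0], collapse = ", "), call. = FALSE)
  structure(list(snps = snps, dosages = dosages), class = "LdPanel")
}

#' @export
print.LdPanel <- function(x, ...) {
  cat("<LdPanel> ", nrow(x$dosages), " individuals x ", nrow(x$snps),
      " SNPs (chr ", paste(unique(x$snps$chr), collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Empirical A1 frequencies of a panel
#' @param panel an [ld_panel()].
#' @return Named numeric vector of sample A1 frequencies.
#' @export
panel_freq <- function(panel) {
  f <- colMeans(panel$dosages) / 2
  stats::setNames(f, panel$snps$snp_id)
}

#' Panel SNP-SNP correlation submatrix
#'
#' @param panel an [ld_panel()].
#' @param snp_ids SNPs to include, in the requested order.
#' @param ridge diagonal stabilization added before renormalizing back to a
#'   correlation matrix; 0 disables.
#' @return Correlation matrix over `snp_ids`.
#' @export
panel_cor <- function(panel, snp_ids = panel$snps$snp_id, ridge = 0) {
  idx <- match(snp_ids, panel$snps$snp_id)
  if (anyNA(idx))
    stop("SNP(s) absent from panel: ",
         paste(snp_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  R <- stats::cor(panel$dosages[, idx, drop = FALSE])
  ridge_cor(R, ridge)
}

#' Drop low-MAF SNPs from a panel
#' @param panel an [ld_panel()].
#' @param maf_min minimum empirical minor-allele frequency to keep.
#' @return Filtered `LdPanel`.
#' @export
filter_maf <- function(panel, maf_min = 0.01) {
  f <- panel_freq(panel)
  keep <- pmin(f, 1 - f) >= maf_min
  if (!any(keep)) stop("no SNPs survive the MAF filter", call. = FALSE)
  ld_panel(panel$snps[keep, , drop = FALSE],
           panel$dosages[, keep, drop = FALSE])
}

#' Write / read an LD panel as plain-text tables
#'
#' The panel is stored as `<prefix>.snps.tsv` (metadata) and
#' `<prefix>.dosages.tsv` (dense individuals x SNPs matrix, tab-delimited,
#' SNP ids as header).
#'
#' @param panel an [ld_panel()].
#' @param prefix path prefix for the two files.
#' @return `write_ld_panel` returns the two paths invisibly;
#'   `read_ld_panel` returns an `LdPanel`.
#' @export
write_ld_panel <- function(panel, prefix) {
  ps <- paste0(prefix, ".snps.tsv")
  pd <- paste0(prefix, ".dosages.tsv")
  data.table::fwrite(panel$snps, ps, sep = "\t")
  data.table::fwrite(as.data.frame(panel$dosages), pd, sep = "\t")
  invisible(c(ps, pd))
}

#' @rdname write_ld_panel
#' @export
read_ld_panel <- function(prefix) {
  ps <- paste0(prefix, ".snps.tsv")
  pd <- paste0(prefix, ".dosages.tsv")
  for (p in c(ps, pd))
    if (!file.exists(p)) stop("LD panel file not found: ", p, call. = FALSE)
  snps <- as.data.frame(data.table::fread(ps))
  dos <- as.matrix(data.table::fread(pd))
  ld_panel(snps, dos)
}
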