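#' GWAS summary statistics for one trait
#'
#' Per-SNP marginal association records: effect allele A1, other allele A2,
#' A1 frequency, effect size per A1 allele with its standard error, z-score
#' and per-SNP sample size.  Invariants are enforced at construction:
#' unique SNP ids, `0 < freq < 1`, `n >= 1`, `se > 0` where present, and
#' `z = beta/se` within 1e-6 where both are present.
#'
#' @param trait_id trait label.
#' @param records data.frame with columns `snp_id`, `chr`, `pos`, `a1`,
#'   `a2`, `freq`, `beta`, `se`, `z`, `n` (`chr`/`pos`/`freq`/`beta`/`se`
#'   may be `NA` in the summary-only dialect).
#' @return Object of class `GwasSumstats`.
#' @export
gwas_sumstats <- function(trait_id, records) {
  records <- as.data.frame(records)
  req <- c("snp_id", "chr", "pos", "a1", "a2", "freq", "beta", "se", "z", "n")
  for (col in setdiff(req, names(records))) records[[col]] <- NA
  records <- records[, req]
  if (nrow(records) == 0L)
    stop("summary statistics for '", trait_id, "' are empty", call. = FALSE)
  dup <- records$snp_id[duplicated(records$snp_id)]
  if (length(dup))
    stop("duplicate snp_id in sumstats: ", dup[1L], call. = FALSE)
  fr <- records$freq[!is.na(records$freq)]
  if (length(fr) && (min(fr) <= 0 || max(fr) >= 1))
    stop("freq_A1 must lie strictly in (0, 1)", call. = FALSE)
  if (any(!is.na(records$se) & records$se <= 0))
    stop("standard errors must be > 0", call. = FALSE)
  if (any(!is.na(records$n) & records$n < 1))
    stop("per-SNP sample size must be >= 1", call. = FALSE)
  both <- !is.na(records$beta) & !is.na(records$se) & !is.na(records$z)
  if (any(both)) {
    dev <- abs(records$z[both] - records$beta[both] / records$se[both])
    if (max(dev) >= 1e-6)
      stop("z inconsistent with beta/se (max deviation ",
           format(max(dev)), ")", call. = FALSE)
  }
  if (any(is.na(records$z)))
    stop("z must be present for every SNP", call. = FALSE)
  structure(list(trait_id = trait_id, records = records),
            class = "GwasSumstats")
}

#' @export
print.GwasSumstats <- function(x, ...) {
  cat("<GwasSumstats> trait ", x$trait_id, ": ", nrow(x$records),
      " SNPs\n", sep = "")
  invisible(x)
}

.dialect_cols <- list(
  fusion_sumstats = c(SNP = "snp_id", A1 = "a1", A2 = "a2", Z = "z", N = "n"),
  full = c(SNP = "snp_id", CHR = "chr", POS = "pos", A1 = "a1", A2 = "a2",
           FREQ = "freq", BETA = "beta", SE = "se", Z = "z", N = "n")
)

#' Read GWAS summary statistics
#'
#' Two tab-delimited dialects are supported: `fusion_sumstats`
#' (SNP, A1, A2, Z, N — beta/se left unset) and `full`
#' (adds CHR, POS, FREQ, BETA, SE).
#'
#' @param path file path.
#' @param dialect `"full"` or `"fusion_sumstats"`.
#' @param trait_id trait label; defaults to the file stem.
#' @param n_study study-level sample size used when the `fusion_sumstats`
#'   file carries no usable N column.
#' @return A [gwas_sumstats()] object.
#' @export
read_gwas_sumstats <- function(path, dialect = c("full", "fusion_sumstats"),
                               trait_id = NULL, n_study = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- as.data.frame(data.table::fread(path, sep = "\t"))
  cols <- .dialect_cols[[dialect]]
  need <- names(cols)
  if (dialect == "fusion_sumstats" && !is.null(n_study))
    need <- setdiff(need, "N")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("sumstats file ", path, " (dialect ", dialect,
         ") is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rec <- data.frame(snp_id = raw$SNP)
  for (i in seq_along(cols)) {
    src <- names(cols)[i]
    rec[[cols[[i]]]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  if (dialect == "fusion_sumstats") {
    if (!is.null(n_study)) rec$n <- n_study
    if (all(is.na(rec$n)))
      stop("fusion_sumstats dialect without N requires n_study", call. = FALSE)
  }
  gwas_sumstats(trait_id %||% sub("\\.[^.]*$", "", basename(path)), rec)
}

#' Write GWAS summary statistics
#' @param sumstats a [gwas_sumstats()] object.
#' @param path output path (tab-delimited).
#' @param dialect see [read_gwas_sumstats()].
#' @export
write_gwas_sumstats <- function(sumstats, path,
                                dialect = c("full", "fusion_sumstats")) {
  dialect <- match.arg(dialect)
  cols <- .dialect_cols[[dialect]]
  out <- stats::setNames(sumstats$records[, unname(cols)], names(cols))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

.AMBIGUOUS <- c(AT = TRUE, TA = TRUE, CG = TRUE, GC = TRUE)

#' Harmonize summary statistics to an LD panel
#'
#' Restricts the sumstats to SNPs shared with the panel (matched by snp_id
#' plus the allele pair, never by position alone) and aligns the effect
#' allele with the panel's A1: where A1/A2 are swapped the sign of beta and
#' z is flipped and the frequency replaced by its complement.
#' Strand-ambiguous pairs (A/T, C/G) are dropped when `drop_ambiguous` is
#' set; SNPs whose allele pair cannot be reconciled are dropped and
#' counted.  No strand-complement rescue is attempted: the SNP identifier
#' plus the literal allele pair is authoritative.
#'
#' @param sumstats a [gwas_sumstats()] object.
#' @param panel an [ld_panel()].
#' @param drop_ambiguous drop strand-ambiguous SNPs (default `TRUE`).
#' @return A harmonized `GwasSumstats` restricted to shared SNPs in panel
#'   order, with an attribute `harmonization` holding drop/flip counts.
#' @export
harmonize_alleles <- function(sumstats, panel, drop_ambiguous = TRUE) {
  rec <- sumstats$records
  idx <- match(panel$snps$snp_id, rec$snp_id)
  keep <- which(!is.na(idx))
  if (length(keep) == 0L)
    stop("no overlapping SNPs between sumstats '", sumstats$trait_id,
         "' and panel", call. = FALSE)
  rec <- rec[idx[keep], , drop = FALSE]
  pan <- panel$snps[keep, , drop = FALSE]
  n_shared <- nrow(rec)

  su_pair <- toupper(paste0(rec$a1, rec$a2))
  ambiguous <- !is.na(.AMBIGUOUS[su_pair])
  a1 <- toupper(rec$a1); a2 <- toupper(rec$a2)
  p1 <- toupper(pan$a1); p2 <- toupper(pan$a2)
  same <- a1 == p1 & a2 == p2
  swap <- a1 == p2 & a2 == p1

  reconcilable <- same | swap
  drop_amb <- ambiguous & drop_ambiguous & reconcilable
  irrec <- !reconcilable
  keep_row <- reconcilable & !drop_amb

  flip <- swap & keep_row
  rec$beta[flip] <- -rec$beta[flip]
  rec$z[flip] <- -rec$z[flip]
  rec$freq[flip] <- 1 - rec$freq[flip]
  rec$a1 <- pan$a1
  rec$a2 <- pan$a2
  rec$chr <- pan$chr
  rec$pos <- pan$pos
  rec$freq <- ifelse(is.na(rec$freq), pan$freq, rec$freq)

  out <- gwas_sumstats(sumstats$trait_id, rec[keep_row, , drop = FALSE])
  attr(out, "harmonization") <- list(
    n_input = nrow(sumstats$records), n_shared = n_shared,
    n_flipped = sum(flip), n_ambiguous_dropped = sum(drop_amb),
    n_irreconcilable = sum(irrec))
  out
}
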