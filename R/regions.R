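#' Merge significant features into genomic regions
#'
#' Features join one region iff their padded gene spans overlap, closed
#' under transitivity (recursive merging to a fixpoint); overlap is
#' closed-interval, so touching endpoints merge.  Any feature whose padded
#' span intersects the MHC span is absorbed into the single fixed MHC
#' region.  Region ids are assigned by genomic order after merging.
#'
#' @param features data.frame of significant feature spans across all
#'   traits: columns `feature_id`, `tissue`, `chr`, `start`, `stop`.
#' @param pad padding in bp added to each side (default 500 kb).
#' @param mhc_span `(chr, start, stop)` of the MHC, default chromosome 6,
#'   25.5-34 Mb; `NULL` disables MHC absorption.
#' @return data.frame of class `GenomicRegion` rows: `region_id`, `chr`,
#'   `start`, `stop` (hull of the padded member spans, clamped at 1; the
#'   MHC region keeps its fixed span), `n_features`, `members`
#'   (semicolon-joined `feature_id@tissue`), `is_mhc`.
#' @export
merge_regions <- function(features, pad = 5e5,
                          mhc_span = c(6, 25.5e6, 34e6)) {
  features <- as.data.frame(features)
  req <- c("feature_id", "tissue", "chr", "start", "stop")
  miss <- setdiff(req, names(features))
  if (length(miss))
    stop("features missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (pad < 0) stop("pad must be >= 0", call. = FALSE)
  if (any(features$start > features$stop))
    stop("malformed span: start > stop for ",
         features$feature_id[features$start > features$stop][1L],
         call. = FALSE)
  if (nrow(features) == 0L)
    return(data.frame(region_id = integer(), chr = numeric(),
                      start = numeric(), stop = numeric(),
                      n_features = integer(), members = character(),
                      is_mhc = logical()))
  features <- unique(features[, req])
  lo <- pmax(features$start - pad, 1)
  hi <- features$stop + pad
  in_mhc <- rep(FALSE, nrow(features))
  if (!is.null(mhc_span))
    in_mhc <- features$chr == mhc_span[1L] & lo <= mhc_span[3L] &
      hi >= mhc_span[2L]

  regions <- list()
  add_region <- function(chr, start, stop, members, is_mhc = FALSE)
    regions[[length(regions) + 1L]] <<- list(chr = chr, start = start,
                                             stop = stop, members = members,
                                             is_mhc = is_mhc)
  if (any(in_mhc)) {
    add_region(mhc_span[1L], mhc_span[2L], mhc_span[3L],
               paste(features$feature_id[in_mhc], features$tissue[in_mhc],
                     sep = "@"), is_mhc = TRUE)
  }
  rest <- which(!in_mhc)
  for (ch in unique(features$chr[rest])) {
    ix <- rest[features$chr[rest] == ch]
    ord <- ix[order(lo[ix], hi[ix])]
    cur <- ord[1L]; cur_lo <- lo[cur]; cur_hi <- hi[cur]; mem <- cur
    flush <- function()
      add_region(ch, cur_lo, cur_hi,
                 paste(features$feature_id[mem], features$tissue[mem],
                       sep = "@"))
    for (i in ord[-1L]) {
      if (lo[i] <= cur_hi) {        # closed-interval overlap (touch merges)
        cur_hi <- max(cur_hi, hi[i])
        mem <- c(mem, i)
      } else {
        flush()
        cur <- i; cur_lo <- lo[i]; cur_hi <- hi[i]; mem <- i
      }
    }
    flush()
  }
  chr <- vapply(regions, `[[`, numeric(1L), "chr")
  start <- vapply(regions, `[[`, numeric(1L), "start")
  ord <- order(chr, start)
  out <- data.frame(
    region_id = seq_along(ord), chr = chr[ord], start = start[ord],
    stop = vapply(regions, `[[`, numeric(1L), "stop")[ord],
    n_features = vapply(regions, function(r) length(r$members),
                        integer(1L))[ord],
    members = vapply(regions, function(r)
      paste(sort(r$members), collapse = ";"), character(1L))[ord],
    is_mhc = vapply(regions, `[[`, logical(1L), "is_mhc")[ord])
  class(out) <- c("GenomicRegion", class(out))
  out
}

.region_members <- function(region_row)
  strsplit(region_row$members, ";", fixed = TRUE)[[1L]]

#' Assemble region x trait colocalization support
#'
#' A region-trait pair is supported iff at least one member feature is
#' xWAS-significant for the trait and at least one of its colocalization
#' pairs reaches the H4 reporting threshold.  Supported regions whose
#' traits' minimal regional GWAS p-values all exceed `gwas_sig` are flagged
#' as detected through TWAS/PWAS only.
#'
#' @param regions output of [merge_regions()].
#' @param xwas_results data.frame of xWAS rows for all traits (as from
#'   [run_xwas_screen()], with `trait_id` and `significant`).
#' @param coloc_results data.frame with one row per evaluated signal pair:
#'   columns `feature_id`, `tissue`, `trait_id`, `pp_h4`.
#' @param gwas_list named list of [gwas_sumstats()] per trait (used for
#'   regional minimal GWAS p-values); optional.
#' @param pp4 H4 support threshold (default 0.8).
#' @param gwas_sig genome-wide significance level (default 5e-8).
#' @return List with `support` (region x trait table: `supported`,
#'   `xwas_only`, `best_gwas_p`, `twas_pwas_only`) and `venn` (counts of
#'   supported regions per nonempty trait subset).
#' @export
assemble_trait_support <- function(regions, xwas_results, coloc_results,
                                   gwas_list = NULL, pp4 = 0.8,
                                   gwas_sig = 5e-8) {
  traits <- sort(unique(xwas_results$trait_id))
  xkey <- paste(xwas_results$feature_id, xwas_results$tissue, sep = "@")
  ckey <- if (nrow(coloc_results))
    paste(coloc_results$feature_id, coloc_results$tissue, sep = "@")
  else character()
  bad <- setdiff(ckey, xkey)
  if (length(bad))
    stop("coloc result keyed by unknown feature: ", bad[1L], call. = FALSE)

  rows <- list()
  for (i in seq_len(nrow(regions))) {
    mem <- .region_members(regions[i, ])
    for (tr in traits) {
      xs <- xwas_results$trait_id == tr & xkey %in% mem &
        xwas_results$significant
      cs <- if (nrow(coloc_results))
        coloc_results$trait_id == tr & ckey %in% mem &
          coloc_results$pp_h4 >= pp4
      else logical()
      best_p <- NA_real_
      if (!is.null(gwas_list) && tr %in% names(gwas_list)) {
        rec <- gwas_list[[tr]]$records
        inr <- !is.na(rec$chr) & rec$chr == regions$chr[i] &
          rec$pos >= regions$start[i] & rec$pos <= regions$stop[i]
        if (any(inr)) best_p <- min(z_to_p(rec$z[inr]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = regions$region_id[i], trait_id = tr,
        n_xwas_significant = sum(xs), n_coloc_supported = sum(cs),
        supported = any(xs) && any(cs),
        xwas_only = any(xs) && !any(cs), best_gwas_p = best_p)
    }
  }
  support <- do.call(rbind, rows)

  # TWAS/PWAS-only flag: all supported traits of the region miss GWAS
  # significance
  support$twas_pwas_only <- FALSE
  for (rid in unique(support$region_id)) {
    sel <- support$region_id == rid & support$supported
    if (any(sel) && all(is.na(support$best_gwas_p[sel]) |
                          support$best_gwas_p[sel] > gwas_sig))
      support$twas_pwas_only[support$region_id == rid & support$supported] <-
        TRUE
  }

  # Venn counts over all nonempty trait subsets
  subsets <- unlist(lapply(seq_along(traits), function(k)
    utils::combn(traits, k, paste, collapse = "+", simplify = FALSE)))
  venn <- stats::setNames(integer(length(subsets)), subsets)
  for (rid in unique(support$region_id)) {
    sup <- sort(support$trait_id[support$region_id == rid &
                                   support$supported])
    if (length(sup))
      venn[paste(sup, collapse = "+")] <-
        venn[paste(sup, collapse = "+")] + 1L
  }
  list(support = support,
       venn = data.frame(trait_subset = names(venn),
                         n_regions = as.integer(venn)))
}
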