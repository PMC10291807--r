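#' Cis prediction weight model for one molecular feature
#'
#' SNP weights predicting a standardized molecular feature (a transcript in
#' a tissue, or a plasma protein aptamer) from A1 dosages, together with the
#' feature's gene span and the cross-validated prediction accuracy.
#'
#' @param feature_id feature label (gene symbol or aptamer id).
#' @param modality `"expression"` or `"protein"`.
#' @param tissue tissue label.
#' @param chr,start,stop gene span (1-based inclusive bp).
#' @param entries data.frame with columns `snp_id`, `a1`, `a2`, `weight`
#'   (effect of one A1 dosage SD on the standardized feature).
#' @param training_r2 cross-validated prediction r-squared in [-1, 1].
#' @param untrainable flag set when no penalty achieved positive
#'   cross-validated prediction correlation; such models carry no entries.
#' @return Object of class `WeightModel`.
#' @export
weight_model <- function(feature_id, modality = c("expression", "protein"),
                         tissue, chr, start, stop, entries,
                         training_r2 = NA_real_, untrainable = FALSE) {
  modality <- match.arg(modality)
  if (start > stop) stop("gene span start > stop", call. = FALSE)
  entries <- as.data.frame(entries)
  req <- c("snp_id", "a1", "a2", "weight")
  miss <- setdiff(req, names(entries))
  if (length(miss))
    stop("weight entries missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(entries$snp_id))
    stop("duplicate snp_id in weight model ", feature_id, call. = FALSE)
  if (!untrainable && (nrow(entries) == 0L || all(entries$weight == 0)))
    stop("weight model ", feature_id,
         " has no nonzero weight and is not flagged untrainable",
         call. = FALSE)
  if (!is.na(training_r2) && (training_r2 < -1 || training_r2 > 1))
    stop("training_r2 must lie in [-1, 1]", call. = FALSE)
  structure(list(feature_id = feature_id, modality = modality,
                 tissue = tissue, chr = chr, start = start, stop = stop,
                 entries = entries[, req], training_r2 = training_r2,
                 untrainable = untrainable),
            class = "WeightModel")
}

#' @export
print.WeightModel <- function(x, ...) {
  cat("<WeightModel> ", x$feature_id, " [", x$modality, ", ", x$tissue,
      "] chr", x$chr, ":", x$start, "-", x$stop, ", ",
      sum(x$entries$weight != 0), " nonzero weights, cv r2 = ",
      signif(x$training_r2, 3), if (x$untrainable) " (untrainable)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Write / read a per-feature weight file
#'
#' Tab-delimited, two stanzas: a one-row header table
#' (FEATURE, TISSUE, MODALITY, CHR, START, STOP, TRAINING_R2, UNTRAINABLE)
#' followed by the SNP table (SNP, A1, A2, WEIGHT).
#'
#' @param model a [weight_model()].
#' @param path output path.
#' @export
write_weight_model <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("FEATURE", "TISSUE", "MODALITY", "CHR", "START", "STOP",
                     "TRAINING_R2", "UNTRAINABLE"), collapse = "\t"), con)
  writeLines(paste(c(model$feature_id, model$tissue, model$modality,
                     model$chr, model$start, model$stop,
                     sprintf("%.12e", model$training_r2),
                     as.integer(model$untrainable)), collapse = "\t"), con)
  writeLines(paste(c("SNP", "A1", "A2", "WEIGHT"), collapse = "\t"), con)
  if (nrow(model$entries))
    writeLines(paste(model$entries$snp_id, model$entries$a1,
                     model$entries$a2, sprintf("%.12e", model$entries$weight),
                     sep = "\t"), con)
  invisible(path)
}

#' @rdname write_weight_model
#' @export
read_weight_model <- function(path) {
  if (!file.exists(path)) stop("weight file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L)
    stop("malformed weight file: ", path, call. = FALSE)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  val <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  meta <- stats::setNames(as.list(val), hdr)
  need <- c("FEATURE", "TISSUE", "MODALITY", "CHR", "START", "STOP",
            "TRAINING_R2", "UNTRAINABLE")
  miss <- setdiff(need, hdr)
  if (length(miss))
    stop("weight file ", path, " missing header field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  snp_hdr <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (!identical(snp_hdr, c("SNP", "A1", "A2", "WEIGHT")))
    stop("weight file ", path, " has malformed SNP table header",
         call. = FALSE)
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    entries <- data.frame(snp_id = parts[, 1L], a1 = parts[, 2L],
                          a2 = parts[, 3L], weight = as.numeric(parts[, 4L]))
  } else {
    entries <- data.frame(snp_id = character(), a1 = character(),
                          a2 = character(), weight = numeric())
  }
  weight_model(meta$FEATURE, meta$MODALITY, meta$TISSUE,
               chr = as.integer(meta$CHR), start = as.numeric(meta$START),
               stop = as.numeric(meta$STOP), entries = entries,
               training_r2 = as.numeric(meta$TRAINING_R2),
               untrainable = as.integer(meta$UNTRAINABLE) == 1L)
}

#' Write / read a weight manifest
#'
#' The manifest is a TSV (FEATURE, TISSUE, MODALITY, FILE) listing one
#' weight file per feature x tissue, with paths relative to the manifest.
#'
#' @param models list of [weight_model()] objects.
#' @param dir directory to populate; created if needed.
#' @return `write_weight_manifest` returns the manifest path;
#'   `read_weight_manifest` returns a list of `WeightModel`s.
#' @export
write_weight_manifest <- function(models, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(models, function(m) {
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_",
                      paste(m$feature_id, m$tissue, sep = ".")), ".wgt.tsv")
    write_weight_model(m, file.path(dir, fn))
    data.frame(FEATURE = m$feature_id, TISSUE = m$tissue,
               MODALITY = m$modality, FILE = fn)
  })
  manifest <- file.path(dir, "manifest.tsv")
  data.table::fwrite(do.call(rbind, rows), manifest, sep = "\t")
  invisible(manifest)
}

#' @rdname write_weight_manifest
#' @export
read_weight_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!all(c("FEATURE", "TISSUE", "FILE") %in% names(man)))
    stop("manifest must have FEATURE, TISSUE, FILE columns", call. = FALSE)
  lapply(seq_len(nrow(man)), function(i)
    read_weight_model(file.path(dirname(path), man$FILE[i])))
}
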