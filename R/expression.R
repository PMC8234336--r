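# TPM expression-matrix loading and expression-pattern classification.

#' Load a genes x tissues TPM matrix from TSV
#'
#' First column = gene IDs, header row = tissue labels. Cells must be
#' non-negative numbers; violations are reported with their row/column.
#' When `tissues` is given, columns are checked against it and reordered
#' to that canonical order.
#'
#' @param path TSV file.
#' @param tissues optional expected tissue labels (canonical order).
#' @return numeric matrix (genes x tissues).
#' @export
load_tpm <- function(path, tissues = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("TPM table needs a gene column plus tissues")
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  rownames(m) <- genes
  bad <- which(is.na(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid TPM value at gene '", genes[bad[1, 1]], "', tissue '",
         colnames(m)[bad[1, 2]], "'")
  }
  if (!is.null(tissues)) {
    missing <- setdiff(tissues, colnames(m))
    if (length(missing)) {
      stop("missing tissue column(s): ", paste(missing, collapse = ", "))
    }
    m <- m[, tissues, drop = FALSE]
  }
  m
}

#' Classify genes into expression-pattern categories
#'
#' A gene is expressed in a tissue when its (median) TPM exceeds `tau`.
#' Categories are mutually exclusive and exhaustive: `ubiquitous`
#' (expressed in every tissue), `silent` (in none), `tissue_specific` (in
#' exactly one), `other` (the remainder). Classification always uses raw
#' TPM; the log2(TPM+1) transform is for display only.
#'
#' @param tpm numeric matrix (genes x tissues), e.g. from [load_tpm()].
#' @param tau expression threshold on TPM (default 0: any positive TPM
#'   counts as expressed, the only rule under which a "not expressed"
#'   gene has all-zero medians).
#' @return list with `profiles` (data.frame gene_id, category,
#'   specific_tissue, n_expressed) and `counts` (named vector over the
#'   four categories).
#' @export
classify_expression <- function(tpm, tau = 0) {
  stopifnot(is.matrix(tpm), tau >= 0)
  expressed <- tpm > tau
  k <- rowSums(expressed)
  nt <- ncol(tpm)
  category <- ifelse(
    k == nt, "ubiquitous",
    ifelse(k == 0, "silent", ifelse(k == 1, "tissue_specific", "other"))
  )
  specific <- rep(NA_character_, nrow(tpm))
  one <- which(k == 1)
  if (length(one)) {
    specific[one] <- colnames(tpm)[apply(expressed[one, , drop = FALSE], 1,
                                         which)]
  }
  lv <- c("ubiquitous", "silent", "tissue_specific", "other")
  list(
    profiles = data.frame(
      gene_id = rownames(tpm), category = category,
      specific_tissue = specific, n_expressed = as.integer(k),
      stringsAsFactors = FALSE
    ),
    counts = setNames(as.integer(table(factor(category, levels = lv))), lv)
  )
}

#' Per-tissue and per-breadth expression membership counts
#'
#' @param tpm numeric matrix (genes x tissues).
#' @param tau expression threshold (see [classify_expression()]).
#' @return list with `per_tissue` (named vector: genes expressed in each
#'   tissue) and `per_k` (named vector over k = 0..T: genes expressed in
#'   exactly k tissues; sums to the gene total).
#' @export
tissue_membership_counts <- function(tpm, tau = 0) {
  stopifnot(is.matrix(tpm), tau >= 0)
  expressed <- tpm > tau
  k <- rowSums(expressed)
  per_k <- table(factor(k, levels = 0:ncol(tpm)))
  list(
    per_tissue = setNames(as.integer(colSums(expressed)), colnames(tpm)),
    per_k = setNames(as.integer(per_k), names(per_k))
  )
}

#' Display transform for expression heatmaps
#'
#' @param tpm numeric matrix.
#' @return log2(TPM + 1) matrix.
#' @export
log_tpm <- function(tpm) log2(tpm + 1)
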