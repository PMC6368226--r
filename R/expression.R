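#' Expression matrix container
#'
#' A light container for a probesets-by-samples matrix of log2-scale
#' expression values (intensities or log2 ratios), with an optional
#' probeset-to-gene-symbol mapping. Probeset IDs are the matrix rownames,
#' sample IDs the colnames; both must be unique and the matrix must be
#' complete (no missing values).
#'
#' @param values Numeric matrix, probesets x samples, with unique rownames
#'   and colnames and no missing entries.
#' @param gene_symbols Optional character vector of gene symbols aligned to
#'   the rows; unmapped probesets carry the empty string. Many probesets may
#'   share one symbol.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, gene_symbols = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must carry probeset rownames and sample colnames")
  dup_p <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_p))
    stopf("duplicated probeset IDs: %s", paste(dup_p, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stopf("duplicated sample IDs: %s", paste(dup_s, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stopf("expression values must be complete and finite")
  if (is.null(gene_symbols)) gene_symbols <- rep("", nrow(values))
  if (length(gene_symbols) != nrow(values))
    stopf("`gene_symbols` must align with the matrix rows")
  gene_symbols <- as.character(gene_symbols)
  gene_symbols[is.na(gene_symbols)] <- ""
  structure(list(values = values, gene_symbols = gene_symbols),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Probeset and sample identifiers
#' @param m An `expr_matrix`.
#' @return Character vector of IDs.
#' @export
probeset_ids <- function(m) rownames(m$values)

#' @rdname probeset_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probesets x %d samples\n",
              nrow(x$values), ncol(x$values)))
  n_sym <- sum(nzchar(x$gene_symbols))
  cat(sprintf("  gene symbols mapped: %d/%d\n", n_sym, nrow(x$values)))
  invisible(x)
}

# row subset preserving symbol alignment
subset_probesets <- function(m, ids) {
  idx <- match(ids, probeset_ids(m))
  if (anyNA(idx))
    stopf("probesets absent from matrix: %s",
          paste(ids[is.na(idx)], collapse = ", "))
  expr_matrix(m$values[idx, , drop = FALSE], m$gene_symbols[idx])
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample IDs with the first column holding
#' probeset IDs. Values must be numeric and complete; duplicate probeset or
#' sample IDs and non-numeric cells are ingestion errors.
#'
#' @param path Path to the TSV file.
#' @param mapping_path Optional two-column TSV (probeset_id, gene_symbol);
#'   probesets without a mapping get an empty symbol.
#' @return An [expr_matrix].
#' @export
read_expression_matrix <- function(path, mapping_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("expression file needs >= 1 sample column: %s", path)
  ids <- df[[1]]
  samp <- colnames(df)[-1]
  dup_p <- unique(ids[duplicated(ids)])
  if (length(dup_p))
    stopf("duplicated probeset IDs in %s: %s", path, paste(dup_p, collapse = ", "))
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s))
    stopf("duplicated sample IDs in %s: %s", path, paste(dup_s, collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(samp),
                 dimnames = list(ids, samp))
  for (j in seq_along(samp)) {
    col <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (anyNA(col)) {
      i <- which(is.na(col))[1L]
      stopf("non-numeric or missing value at probeset '%s', sample '%s' in %s",
            ids[i], samp[j], path)
    }
    vals[, j] <- col
  }
  symbols <- NULL
  if (!is.null(mapping_path)) {
    map <- utils::read.delim(mapping_path, header = TRUE, check.names = FALSE,
                             colClasses = "character", stringsAsFactors = FALSE)
    symbols <- map[[2]][match(ids, map[[1]])]
  }
  expr_matrix(vals, symbols)
}

#' Write an expression matrix to TSV
#'
#' Values are written with full double precision (`%.17g`) so a
#' write-then-read round trip is bit-exact.
#'
#' @param m An [expr_matrix].
#' @param path Output file path.
#' @param mapping_path Optional path for the probeset-to-symbol map.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, mapping_path = NULL) {
  vals <- m$values
  header <- paste(c("probeset_id", colnames(vals)), collapse = "\t")
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(rownames(vals)[i], sprintf("%.17g", vals[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  if (!is.null(mapping_path)) {
    writeLines(c("probeset_id\tgene_symbol",
                 paste(rownames(vals), m$gene_symbols, sep = "\t")),
               mapping_path)
  }
  invisible(path)
}

#' Shift samples onto the median reference sample
#'
#' Additive per-sample scaling on the log2 scale: the reference is the
#' sample whose median intensity is closest to the median of the per-sample
#' medians, and every sample is shifted so its median matches the
#' reference's. A documented stand-in for normalization against the median
#' sample; probeset order is unchanged and the operation is idempotent.
#'
#' @param m An [expr_matrix] of log2 intensities.
#' @return The scaled [expr_matrix].
#' @export
median_reference_scale <- function(m) {
  if (ncol(m$values) < 2) {
    warnf("single-sample matrix: median reference scaling is a no-op")
    return(m)
  }
  meds <- apply(m$values, 2, stats::median)
  target <- meds[which.min(abs(meds - stats::median(meds)))]
  out <- sweep(m$values, 2, meds - target, "-")
  expr_matrix(out, m$gene_symbols)
}

#' Remove additive batch means (optional de-batching stand-in)
#'
#' Per probeset, centers each batch on the probeset's grand mean. A simple
#' additive stand-in for empirical-Bayes batch correction, off by default in
#' the pipeline.
#'
#' @param m An [expr_matrix].
#' @param batch Character/factor of batch labels, one per sample.
#' @return The adjusted [expr_matrix].
#' @export
remove_batch_means <- function(m, batch) {
  batch <- as.character(batch)
  if (length(batch) != ncol(m$values))
    stopf("`batch` must have one label per sample")
  out <- m$values
  grand <- rowMeans(out)
  for (b in unique(batch)) {
    idx <- which(batch == b)
    bm <- rowMeans(out[, idx, drop = FALSE])
    out[, idx] <- out[, idx, drop = FALSE] - (bm - grand)
  }
  expr_matrix(out, m$gene_symbols)
}

#' Log2 ratios versus untreated controls
#'
#' For each sample of a unit (cell line), subtracts the mean of that unit's
#' untreated-control samples probeset-wise, turning log2 intensities into
#' log2 ratios versus the untreated baseline. Untreated controls themselves
#' are ratioed against their own mean, so the mean control profile maps to
#' zero.
#'
#' @param m An [expr_matrix] of log2 intensities.
#' @param ann Sample annotation data frame with columns `sample_id`,
#'   `unit_id`, `treatment` ("untreated"/"treated").
#' @return An [expr_matrix] of log2 ratios with the same IDs.
#' @export
compute_log_ratios <- function(m, ann) {
  ann <- validate_annotation(ann, m)
  out <- m$values
  for (u in unique(ann$unit_id)) {
    su <- ann$sample_id[ann$unit_id == u]
    ctrl <- ann$sample_id[ann$unit_id == u & ann$treatment == "untreated"]
    if (!length(ctrl))
      stopf("unit '%s' has no untreated control samples", u)
    base <- rowMeans(m$values[, ctrl, drop = FALSE])
    out[, su] <- m$values[, su, drop = FALSE] - base
  }
  expr_matrix(out, m$gene_symbols)
}

#' Autoscale probeset rows
#'
#' Centers every probeset row to mean zero and scales to unit sample
#' standard deviation across samples (the scaling used for PCA). Rows with
#' zero variance are dropped with a warning rather than erroring, since
#' subsetting a small cohort to signature probesets can produce them.
#'
#' @param m An [expr_matrix].
#' @return The autoscaled [expr_matrix] (possibly with fewer rows).
#' @export
autoscale <- function(m) {
  mu <- rowMeans(m$values)
  sdv <- apply(m$values, 1, stats::sd)
  keep <- sdv > 1e-12
  if (!all(keep))
    warnf("dropping %d zero-variance probeset(s): %s", sum(!keep),
          paste(utils::head(rownames(m$values)[!keep], 5), collapse = ", "))
  if (!any(keep)) stopf("all probesets have zero variance")
  vals <- (m$values[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  expr_matrix(vals, m$gene_symbols[keep])
}

#' Principal component analysis of samples
#'
#' Singular value decomposition of the samples-by-probesets matrix (the
#' transpose of the container), intended for already-autoscaled data so the
#' PCA is on correlation scale. Loadings are the right singular vectors
#' (probesets x components, unit norm); scores are the sample projections
#' `autoscaled-data x loadings`. For determinism each loading column is
#' flipped so its largest-magnitude entry is positive (scores flip with it;
#' downstream signature orientation overrides this base convention).
#'
#' @param m An [expr_matrix], normally autoscaled.
#' @param n_components Number of components to return; at most
#'   `min(n_probesets, n_samples)`.
#' @return A list of class `emt_pca` with elements `loadings`
#'   (probesets x components), `scores` (samples x components) and
#'   `pct_variance` (percent variance per returned component).
#' @export
pca <- function(m, n_components = 2L) {
  X <- t(m$values)
  k_max <- min(dim(X))
  if (n_components < 1 || n_components > k_max)
    stopf("n_components must be in [1, %d]", k_max)
  sv <- svd(X)
  V <- sv$v
  U <- sv$u
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) {
      V[, k] <- -V[, k]
      U[, k] <- -U[, k]
    }
  }
  tot <- sum(sv$d^2)
  pct <- if (tot > 0) 100 * sv$d^2 / tot else rep(0, length(sv$d))
  loadings <- V[, seq_len(n_components), drop = FALSE]
  rownames(loadings) <- rownames(m$values)
  colnames(loadings) <- paste0("PC", seq_len(n_components))
  scores <- X %*% loadings
  rownames(scores) <- colnames(m$values)
  colnames(scores) <- colnames(loadings)
  structure(list(loadings = loadings, scores = scores,
                 pct_variance = pct[seq_len(n_components)]),
            class = "emt_pca")
}

#' @export
print.emt_pca <- function(x, ...) {
  cat(sprintf("PCA: %d component(s), %d features, %d samples\n",
              ncol(x$loadings), nrow(x$loadings), nrow(x$scores)))
  cat("  % variance:", paste(sprintf("%.1f", x$pct_variance), collapse = ", "),
      "\n")
  invisible(x)
}
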