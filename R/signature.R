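#' Construct a signature object
#'
#' A signature is an ordered table of probeset entries, each carrying the
#' gene symbol, the cell-line-derived direction sign (+1 up-regulated in
#' EMT, -1 down-regulated) and a provenance flag (`algorithmic` from the
#' pruning filter, `curated` from the include-list).
#'
#' @param entries Data frame with columns `probeset_id`, `gene_symbol`,
#'   `direction`, `provenance`.
#' @param name Label for the signature.
#' @return Data frame of class `emt_signature`.
#' @export
new_signature <- function(entries, name = "signature") {
  need <- c("probeset_id", "gene_symbol", "direction", "provenance")
  miss <- setdiff(need, colnames(entries))
  if (length(miss))
    stopf("signature entries missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(entries$probeset_id))
    stopf("duplicated probeset IDs in signature")
  if (any(!entries$direction %in% c(-1L, 1L)))
    stopf("signature directions must be +1 or -1")
  entries <- entries[, need]
  rownames(entries) <- NULL
  structure(entries, class = c("emt_signature", "data.frame"), name = name)
}

#' @export
print.emt_signature <- function(x, ...) {
  cat(sprintf("EMT signature '%s': %d probesets, %d genes (%d up, %d down)\n",
              attr(x, "name") %||% "signature", nrow(x),
              length(unique(x$gene_symbol)), sum(x$direction > 0),
              sum(x$direction < 0)))
  invisible(x)
}

#' Read/write a signature TSV
#'
#' Columns: probeset_id, gene_symbol, direction, provenance.
#' @param path File path.
#' @param name Signature label (read only).
#' @return An `emt_signature` (read) or `path` invisibly (write).
#' @export
read_signature <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  df$direction <- as.integer(df$direction)
  new_signature(df, name = name)
}

#' @rdname read_signature
#' @param sig An `emt_signature`.
#' @export
write_signature <- function(sig, path) {
  utils::write.table(sig, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged reference signature (synthetic probeset IDs)
#'
#' The final translated 105-probeset signature covering 77 genes. Gene
#' symbols and directions reproduce the published table; the probeset IDs
#' are synthetic placeholders (the original array IDs are not published),
#' and the assignment of second probesets to 28 of the genes is likewise a
#' documented placeholder.
#'
#' @return An `emt_signature` with 105 entries over 77 genes.
#' @export
reference_signature <- function() {
  read_signature(system.file("extdata", "tgfb_emt_signature_synthetic_ids.tsv",
                             package = "emtsig"),
                 name = "TGFB-EMT (reference, synthetic probeset IDs)")
}

#' Packaged curated include-list (synthetic probeset IDs)
#'
#' The seven curated probesets of general EMT-related biological interest
#' spanning six genes (DDR1, LTBP1, PDGFB, SMURF1, SNAI1, TGFBR1); LTBP1
#' contributes two probesets here (which gene carries the second probeset is
#' not published — a documented assumption). Probeset IDs are synthetic.
#'
#' @return Data frame `probeset_id`, `gene_symbol`.
#' @export
curated_probesets <- function() {
  utils::read.delim(system.file("extdata", "curated_probesets_synthetic.tsv",
                                package = "emtsig"),
                    header = TRUE, stringsAsFactors = FALSE)
}

#' Keep the strongest categorized probesets
#'
#' A candidate survives iff (a) at least one of its three experimental
#' phenotype comparisons shows complete separation; (b) the worst (smallest
#' |difference|) of the three comparisons still reaches the 2-fold log2
#' threshold; and (c) on that same worst comparison both the Welch t and
#' Mann-Whitney p-values fall below the cutoff (optionally required on all
#' three comparisons).
#'
#' @param categories Output of [categorize_probesets()].
#' @param stats_by_comparison Named list of [compare_groups()] frames for
#'   the three phenotype comparisons of the candidates (for EMT-related
#'   candidates: EMT vs no-EMT, EMT vs other, EMT vs untreated), computed
#'   with `tests = TRUE`.
#' @param cfg A [filter_config].
#' @param category Which category supplies the candidates.
#' @return Character vector of retained probeset IDs.
#' @export
strongest_filter <- function(categories, stats_by_comparison,
                             cfg = filter_config(),
                             category = "EMT-related") {
  cand <- categories$probeset_id[categories$category == category]
  if (length(stats_by_comparison) != 3)
    stopf("exactly three phenotype comparisons are required")
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    rows <- lapply(stats_by_comparison, function(s) {
      r <- s[s$probeset_id == p, , drop = FALSE]
      if (!nrow(r)) stopf("candidate '%s' missing from a comparison table", p)
      r
    })
    diffs <- vapply(rows, function(r) r$difference, numeric(1))
    seps <- vapply(rows, function(r) r$complete_separation, logical(1))
    tps <- vapply(rows, function(r) r$t_p, numeric(1))
    mps <- vapply(rows, function(r) r$mw_p, numeric(1))
    worst <- which.min(abs(diffs))
    p_ok <- if (cfg$p_on_all_three) {
      all(tps < cfg$strong_p_cutoff) && all(mps < cfg$strong_p_cutoff)
    } else {
      tps[worst] < cfg$strong_p_cutoff && mps[worst] < cfg$strong_p_cutoff
    }
    keep[i] <- any(seps) &&
      abs(diffs[worst]) >= cfg$strong_fold_threshold_log2 && p_ok
  }
  cand[keep]
}

#' Merge curated probesets into the selected set
#'
#' Takes the union of the algorithmically retained probesets and a curated
#' include-list; directions come from the categorization table, provenance
#' records how each entry got in (an entry that is both stays
#' `algorithmic`).
#'
#' @param selected Character vector of algorithmically retained probesets.
#' @param curated Data frame `probeset_id`, `gene_symbol` (may be empty or
#'   `NULL`).
#' @param categories Output of [categorize_probesets()]; every probeset must
#'   appear here with a non-zero direction.
#' @param gene_symbols Named character vector mapping probeset IDs to
#'   symbols for the algorithmic entries.
#' @param name Signature label.
#' @return An `emt_signature`.
#' @export
add_curated <- function(selected, curated, categories, gene_symbols,
                        name = "cell-line signature") {
  dir_of <- function(ids) {
    idx <- match(ids, categories$probeset_id)
    if (anyNA(idx))
      stopf("probeset(s) absent from the category table: %s",
            paste(ids[is.na(idx)], collapse = ", "))
    d <- categories$direction[idx]
    if (any(d == 0))
      stopf("probeset(s) with direction 0 cannot enter a signature: %s",
            paste(ids[d == 0], collapse = ", "))
    d
  }
  ent <- data.frame(probeset_id = selected,
                    gene_symbol = unname(gene_symbols[selected]),
                    direction = if (length(selected)) dir_of(selected) else integer(0),
                    provenance = rep("algorithmic", length(selected)),
                    stringsAsFactors = FALSE)
  if (!is.null(curated) && nrow(curated)) {
    extra <- curated[!curated$probeset_id %in% selected, , drop = FALSE]
    if (nrow(extra)) {
      ent <- rbind(ent, data.frame(
        probeset_id = extra$probeset_id,
        gene_symbol = extra$gene_symbol,
        direction = dir_of(extra$probeset_id),
        provenance = "curated", stringsAsFactors = FALSE))
    }
  }
  ent$gene_symbol[is.na(ent$gene_symbol)] <- ""
  new_signature(ent, name = name)
}

#' Translation filter across tumor cohorts
#'
#' Tests whether each signature probeset behaves in human tumors as it did
#' in the cell lines. Per cohort the expression matrix is subset to the
#' signature probesets, autoscaled and decomposed by PCA; PC1 is oriented so
#' that the majority of loading signs match the signature directions (the
#' whole component is flipped otherwise, which makes the decision invariant
#' to a global sign flip of the cohort). A probeset "agrees" in a cohort iff
#' the sign of its oriented PC1 loading equals its signature direction (a
#' zero loading counts as disagreement). Probesets agreeing in at most
#' `min_agree_fraction` of the cohorts that could evaluate them are removed;
#' probesets evaluable in no cohort are retained (no evidence against
#' them). Cohorts sharing fewer than 3 signature probesets are skipped with
#' a warning.
#'
#' @param sig An `emt_signature`.
#' @param cohorts List of [expr_matrix] tumor cohorts (named if possible).
#' @param min_agree_fraction Removal threshold on the agreeing fraction
#'   (default 0.5: a strict-majority vote keeps a probeset).
#' @return List with elements `signature` (the filtered `emt_signature`) and
#'   `report` (a `translation_report` data frame: per-probeset oriented PC1
#'   loadings per cohort, agreement flags, counts and the removal decision).
#' @export
translation_filter <- function(sig, cohorts, min_agree_fraction = 0.5) {
  if (!length(cohorts)) stopf("at least one cohort is required")
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  n_p <- nrow(sig)
  agree <- matrix(NA, n_p, length(cohorts),
                  dimnames = list(sig$probeset_id, names(cohorts)))
  load_mat <- matrix(NA_real_, n_p, length(cohorts),
                     dimnames = dimnames(agree))
  used <- logical(length(cohorts))
  for (k in seq_along(cohorts)) {
    m <- cohorts[[k]]
    common <- intersect(sig$probeset_id, probeset_ids(m))
    if (length(common) < 3) {
      warnf("cohort '%s' shares only %d signature probesets; skipped",
            names(cohorts)[k], length(common))
      next
    }
    sub <- autoscale(subset_probesets(m, common))
    kept <- probeset_ids(sub)
    if (length(kept) < 3) {
      warnf("cohort '%s' has <3 variable signature probesets; skipped",
            names(cohorts)[k])
      next
    }
    used[k] <- TRUE
    pc <- pca(sub, n_components = 1L)
    l1 <- pc$loadings[, 1]
    dirs <- sig$direction[match(kept, sig$probeset_id)]
    n_match <- sum(sign(l1) == dirs)
    if (n_match < length(kept) - n_match) l1 <- -l1
    load_mat[kept, k] <- l1
    agree[kept, k] <- sign(l1) == dirs
  }
  if (!any(used)) stopf("all cohorts were skipped; translation impossible")
  n_eval <- rowSums(!is.na(agree))
  n_agree <- rowSums(agree, na.rm = TRUE)
  frac <- ifelse(n_eval > 0, n_agree / n_eval, NA_real_)
  removed <- n_eval > 0 & frac <= min_agree_fraction
  report <- data.frame(probeset_id = sig$probeset_id,
                       gene_symbol = sig$gene_symbol,
                       direction = sig$direction,
                       n_evaluated = n_eval, n_agree = n_agree,
                       agree_fraction = frac, removed = removed,
                       stringsAsFactors = FALSE)
  report <- cbind(report, as.data.frame(load_mat))
  rownames(report) <- NULL
  class(report) <- c("translation_report", "data.frame")
  out <- sig[!removed, , drop = FALSE]
  out <- new_signature(as.data.frame(out),
                       name = paste0(attr(sig, "name") %||% "signature",
                                     " (translated)"))
  list(signature = out, report = report)
}

#' Restrict a signature to an include-list of gene symbols
#'
#' Keeps signature entries whose symbol appears in `genes`, preserving
#' order. Listed symbols absent from the signature warn rather than error.
#'
#' @param sig An `emt_signature`.
#' @param genes Character vector of gene symbols.
#' @return The restricted `emt_signature`.
#' @export
apply_include_list <- function(sig, genes) {
  missing <- setdiff(genes, sig$gene_symbol)
  if (length(missing))
    warnf("include-list symbol(s) not in signature: %s",
          paste(missing, collapse = ", "))
  keep <- sig$gene_symbol %in% genes
  if (!any(keep)) warnf("include-list leaves an empty signature")
  out <- as.data.frame(sig)[keep, , drop = FALSE]
  if (!nrow(out)) {
    out <- out # empty frame keeps columns
    rownames(out) <- NULL
    return(structure(out, class = c("emt_signature", "data.frame"),
                     name = paste0(attr(sig, "name") %||% "signature",
                                   " (restricted)")))
  }
  new_signature(out, name = paste0(attr(sig, "name") %||% "signature",
                                   " (restricted)"))
}
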