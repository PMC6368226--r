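#' Derive an EMT signature from a cell-line experiment
#'
#' The fitting function of the package. Starting from log2 intensities and
#' a cell-line annotation it (1) computes log2 ratios versus each line's
#' untreated controls, (2) runs the seven-comparison fold-change screen and
#' categorizes probesets as EMT-, no-EMT- or TGF-beta-related (conflicts
#' removed), (3) prunes the EMT-related probesets with the complete
#' separation / 2-fold / dual-test rule, (4) merges the curated
#' include-list, and (5) optionally applies the tumor-cohort translation
#' filter. Funnel counts are recorded at every stage.
#'
#' @param m An [expr_matrix] of log2 intensities (or ratios, see
#'   `is_ratios`).
#' @param ann Cell-line annotation (see [validate_annotation()]).
#' @param config A [filter_config].
#' @param curated Optional curated include-list data frame (`probeset_id`,
#'   `gene_symbol`); entries must be categorized with non-zero direction.
#' @param cohorts Optional list of tumor-cohort [expr_matrix] objects for
#'   the translation filter.
#' @param min_agree_fraction Translation removal threshold (see
#'   [translation_filter()]).
#' @param is_ratios Set `TRUE` when `m` already holds log2 ratios.
#' @return An object of class `emt_signature_fit` with components
#'   `signature` (the final `emt_signature`), `categories`, `calls`,
#'   `screen_stats`, `pruning_stats`, `translation` (report or `NULL`),
#'   `funnel` (named stage counts), `config`.
#' @seealso [predict.emt_signature_fit()] to score cohorts,
#'   [coef.emt_signature_fit()] for the signed entries.
#' @export
derive_signature <- function(m, ann, config = filter_config(),
                             curated = NULL, cohorts = NULL,
                             min_agree_fraction = 0.5, is_ratios = FALSE) {
  ann <- validate_annotation(ann, m)
  ratios <- if (is_ratios) m else compute_log_ratios(m, ann)
  scheme <- group_scheme(ann)
  comps <- enumerate_comparisons(scheme)

  # screen: means only; tests are deferred to the pruning candidates
  screen_stats <- lapply(comps, function(cp)
    compare_groups(ratios, cp$experimental, cp$reference, tests = FALSE))
  calls <- vapply(screen_stats, call_de, integer(nrow(ratios$values)),
                  cfg = config)
  rownames(calls) <- probeset_ids(ratios)
  categories <- categorize_probesets(calls)

  emt_cmp <- c("EMT_vs_noEMT", "EMT_vs_other", "EMT_vs_untreated")
  cand <- categories$probeset_id[categories$category == "EMT-related"]
  pruning_stats <- NULL
  selected <- character(0)
  if (length(cand)) {
    cand_ratios <- subset_probesets(ratios, cand)
    pruning_stats <- lapply(comps[emt_cmp], function(cp)
      compare_groups(cand_ratios, cp$experimental, cp$reference, tests = TRUE))
    selected <- strongest_filter(categories, pruning_stats, cfg = config)
  }
  syms <- stats::setNames(m$gene_symbols, probeset_ids(m))
  sig <- add_curated(selected, curated, categories, syms)

  funnel <- c(probesets = nrow(ratios$values),
              categorized_emt = length(cand),
              conflict = sum(categories$category == "conflict"),
              strongest = length(selected),
              with_curated = nrow(sig))
  translation <- NULL
  if (!is.null(cohorts) && length(cohorts)) {
    tr <- translation_filter(sig, cohorts,
                             min_agree_fraction = min_agree_fraction)
    sig <- tr$signature
    translation <- tr$report
    funnel <- c(funnel, translated = nrow(sig))
  }
  structure(list(signature = sig, categories = categories, calls = calls,
                 screen_stats = screen_stats, pruning_stats = pruning_stats,
                 translation = translation, funnel = funnel,
                 config = config, scheme = scheme),
            class = "emt_signature_fit")
}

#' @export
print.emt_signature_fit <- function(x, ...) {
  cat("EMT signature derivation\n")
  cat(sprintf("  screen groups: %d EMT / %d no-EMT / %d untreated samples (%d excluded)\n",
              length(x$scheme$emt), length(x$scheme$no_emt),
              length(x$scheme$untreated), length(x$scheme$excluded)))
  f <- x$funnel
  cat(sprintf("  funnel: %d probesets -> %d EMT-related (%d conflicts) -> %d strongest -> %d with curated",
              f[["probesets"]], f[["categorized_emt"]], f[["conflict"]],
              f[["strongest"]], f[["with_curated"]]))
  if ("translated" %in% names(f))
    cat(sprintf(" -> %d translated", f[["translated"]]))
  cat("\n")
  print(x$signature)
  invisible(x)
}

#' @export
summary.emt_signature_fit <- function(object, ...) {
  cat_tab <- table(object$categories$category)
  structure(list(funnel = object$funnel, categories = cat_tab,
                 config = object$config,
                 n_genes = length(unique(object$signature$gene_symbol)),
                 signature = object$signature),
            class = "summary.emt_signature_fit")
}

#' @export
print.summary.emt_signature_fit <- function(x, ...) {
  cat("Category counts:\n")
  print(x$categories)
  cat("Funnel:\n")
  print(x$funnel)
  cat(sprintf("Thresholds: screen >= %.3f log2, pruning >= %.3f log2, p < %g\n",
              x$config$fold_threshold_log2,
              x$config$strong_fold_threshold_log2, x$config$strong_p_cutoff))
  cat(sprintf("Final signature: %d probesets, %d genes\n",
              nrow(x$signature), x$n_genes))
  invisible(x)
}

#' Signature entries of a fitted derivation
#'
#' @param object An `emt_signature_fit`.
#' @param ... Unused.
#' @return Data frame of signature entries with directions.
#' @export
coef.emt_signature_fit <- function(object, ...) {
  as.data.frame(object$signature)
}

#' Score a new cohort with a fitted signature
#'
#' @param object An `emt_signature_fit`.
#' @param newdata An [expr_matrix] cohort.
#' @param split `"none"` for scores only, `"median"` or `"kmeans"` to add
#'   high/low groups.
#' @param seed Seed for the k-means split.
#' @param ... Unused.
#' @return A `scored_cohort`.
#' @export
predict.emt_signature_fit <- function(object, newdata,
                                      split = c("none", "median", "kmeans"),
                                      seed = 1L, ...) {
  split <- match.arg(split)
  switch(split,
         none = score_cohort(newdata, object$signature),
         median = median_split(score_cohort(newdata, object$signature)),
         kmeans = kmeans_split(newdata, object$signature, seed = seed))
}
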