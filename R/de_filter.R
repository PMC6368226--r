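#' Differential-expression filter configuration
#'
#' Thresholds for the fold-change screen and the strongest-probeset pruning
#' step, on the log2 scale: 0.585 is a 1.5-fold change, 1.0 a 2-fold
#' change; 0.002 is the dual-test p-value cutoff applied at pruning (no
#' p-value enters the initial screen).
#'
#' @param fold_threshold_log2 Screen threshold on |group-mean difference|
#'   (inclusive). Default 0.585.
#' @param strong_fold_threshold_log2 Pruning threshold applied to the worst
#'   of the three phenotype comparisons. Default 1.0.
#' @param strong_p_cutoff Both the Welch t and Mann-Whitney p-values on the
#'   worst comparison must fall strictly below this. Default 0.002.
#' @param p_on_all_three If `TRUE`, the dual-test condition is required on
#'   all three comparisons rather than the worst only.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(fold_threshold_log2 = 0.585,
                          strong_fold_threshold_log2 = 1.0,
                          strong_p_cutoff = 0.002,
                          p_on_all_three = FALSE) {
  if (fold_threshold_log2 <= 0 || strong_fold_threshold_log2 <= 0 ||
      strong_p_cutoff <= 0)
    stopf("all filter thresholds must be positive")
  structure(list(fold_threshold_log2 = fold_threshold_log2,
                 strong_fold_threshold_log2 = strong_fold_threshold_log2,
                 strong_p_cutoff = strong_p_cutoff,
                 p_on_all_three = isTRUE(p_on_all_three)),
            class = "filter_config")
}

#' Group scheme for the cell-line experiment
#'
#' Derives the three disjoint analysis groups from the annotation:
#' `untreated` (untreated samples of all non-excluded lines), `emt`
#' (TGF-beta-treated samples of EMT-responder lines) and `no_emt` (treated
#' samples of non-responder lines). Constitutively mesenchymal lines are
#' excluded from every group. The TGF-beta group used downstream is the
#' union of `emt` and `no_emt`.
#'
#' @param ann Cell-line annotation with `phenotype_class` in
#'   `"EMT-responder"`, `"non-EMT"`, `"constitutively-mesenchymal"`.
#' @return A list of class `group_scheme` with character sample-ID vectors
#'   `emt`, `no_emt`, `untreated`, `excluded`.
#' @export
group_scheme <- function(ann) {
  ann <- validate_annotation(ann)
  if (!"phenotype_class" %in% colnames(ann))
    stopf("annotation needs a phenotype_class column")
  known <- c("EMT-responder", "non-EMT", "constitutively-mesenchymal",
             "untreated-control", "not-applicable")
  bad <- setdiff(unique(ann$phenotype_class), known)
  if (length(bad))
    stopf("unknown phenotype_class value(s): %s", paste(bad, collapse = ", "))
  excl_units <- unique(ann$unit_id[ann$phenotype_class ==
                                     "constitutively-mesenchymal"])
  keep <- !(ann$unit_id %in% excl_units)
  scheme <- list(
    emt = ann$sample_id[keep & ann$treatment == "treated" &
                          ann$phenotype_class == "EMT-responder"],
    no_emt = ann$sample_id[keep & ann$treatment == "treated" &
                             ann$phenotype_class == "non-EMT"],
    untreated = ann$sample_id[keep & ann$treatment == "untreated"],
    excluded = ann$sample_id[!keep])
  structure(scheme, class = "group_scheme")
}

#' The seven two-group comparisons
#'
#' Enumerates the fixed comparison scheme of the screen: EMT vs no-EMT,
#' EMT vs other, EMT vs untreated, no-EMT vs EMT, no-EMT vs other,
#' no-EMT vs untreated and TGF-beta (EMT + no-EMT) vs untreated. "Other"
#' means all non-excluded samples outside the experimental group.
#'
#' @param scheme A [group_scheme].
#' @return Named list of 7 comparisons, each with `experimental` and
#'   `reference` sample-ID vectors.
#' @export
enumerate_comparisons <- function(scheme) {
  all_s <- c(scheme$emt, scheme$no_emt, scheme$untreated)
  tgfb <- c(scheme$emt, scheme$no_emt)
  cmp <- list(
    EMT_vs_noEMT      = list(experimental = scheme$emt,
                             reference = scheme$no_emt),
    EMT_vs_other      = list(experimental = scheme$emt,
                             reference = setdiff(all_s, scheme$emt)),
    EMT_vs_untreated  = list(experimental = scheme$emt,
                             reference = scheme$untreated),
    noEMT_vs_EMT      = list(experimental = scheme$no_emt,
                             reference = scheme$emt),
    noEMT_vs_other    = list(experimental = scheme$no_emt,
                             reference = setdiff(all_s, scheme$no_emt)),
    noEMT_vs_untreated = list(experimental = scheme$no_emt,
                              reference = scheme$untreated),
    TGFB_vs_untreated = list(experimental = tgfb,
                             reference = scheme$untreated))
  for (nm in names(cmp)) {
    if (!length(cmp[[nm]]$experimental) || !length(cmp[[nm]]$reference))
      stopf("comparison '%s' has an empty group", nm)
  }
  cmp
}

# Welch t p-value with the degenerate-variance edge handled
welch_p <- function(x, y) {
  tryCatch(stats::t.test(x, y)$p.value,
           error = function(e) if (mean(x) == mean(y)) 1 else 0)
}

# Mann-Whitney p: exact when both n <= 10 (ties fall back to the normal
# approximation inside wilcox.test), continuity-corrected approximation
# otherwise
mw_p <- function(x, y) {
  exact <- length(x) <= 10 && length(y) <= 10
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Two-group statistics per probeset
#'
#' For each probeset computes the experimental and reference group means of
#' the log2 ratios, their difference, a strict complete-separation flag (no
#' overlap between the two groups' values) and, optionally, two-sided Welch
#' t and Mann-Whitney U p-values. Groups of size one get p-values of 1 with
#' a warning (the difference is still computed).
#'
#' @param ratios An [expr_matrix] of log2 ratios.
#' @param experimental,reference Disjoint, non-empty sample-ID vectors.
#' @param tests Compute p-values? The screen itself only needs means, so the
#'   pipeline defers testing to the pruning candidates.
#' @return Data frame with one row per probeset: `probeset_id`,
#'   `mean_experimental`, `mean_reference`, `difference`,
#'   `complete_separation`, `t_p`, `mw_p`.
#' @export
compare_groups <- function(ratios, experimental, reference, tests = TRUE) {
  if (!length(experimental) || !length(reference))
    stopf("both groups must be non-empty")
  if (length(intersect(experimental, reference)))
    stopf("experimental and reference groups overlap")
  E <- ratios$values[, experimental, drop = FALSE]
  R <- ratios$values[, reference, drop = FALSE]
  me <- rowMeans(E)
  mr <- rowMeans(R)
  min_e <- apply(E, 1, min); max_e <- apply(E, 1, max)
  min_r <- apply(R, 1, min); max_r <- apply(R, 1, max)
  sep <- (min_e > max_r) | (max_e < min_r)
  n <- nrow(ratios$values)
  t_p <- rep(NA_real_, n)
  mwp <- rep(NA_real_, n)
  if (tests) {
    if (ncol(E) < 2 || ncol(R) < 2) {
      warnf("a group has a single sample; p-values set to 1")
      t_p <- mwp <- rep(1, n)
    } else {
      for (i in seq_len(n)) {
        t_p[i] <- welch_p(E[i, ], R[i, ])
        mwp[i] <- mw_p(E[i, ], R[i, ])
      }
    }
  }
  data.frame(probeset_id = rownames(ratios$values),
             mean_experimental = me, mean_reference = mr,
             difference = me - mr, complete_separation = sep,
             t_p = t_p, mw_p = mwp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential-expression call for one comparison
#'
#' A probeset is called differentially expressed when the experimental
#' group mean and the group-mean difference agree in sign and the absolute
#' difference reaches the (inclusive) log2 threshold; the call carries the
#' common sign.
#'
#' @param stats Data frame from [compare_groups()].
#' @param cfg A [filter_config].
#' @return Integer vector of directions in `{-1, 0, +1}` aligned to
#'   `stats$probeset_id`.
#' @export
call_de <- function(stats, cfg = filter_config()) {
  thr <- cfg$fold_threshold_log2
  up <- stats$mean_experimental > 0 & stats$difference > 0 &
    abs(stats$difference) >= thr
  dn <- stats$mean_experimental < 0 & stats$difference < 0 &
    abs(stats$difference) >= thr
  ifelse(up, 1L, ifelse(dn, -1L, 0L))
}

#' Categorize probesets from the seven comparison calls
#'
#' A probeset is EMT-related when its three EMT-experimental comparisons
#' (EMT vs no-EMT, EMT vs other, EMT vs untreated) share one non-zero
#' direction and every non-zero call among the no-EMT-experimental
#' comparisons (if present) points the opposite way; no-EMT-related is the
#' symmetric rule. TGF-beta-related requires the three versus-untreated
#' calls (EMT, no-EMT and TGF-beta vs untreated) to share one non-zero
#' direction. A probeset meeting both the EMT and no-EMT criteria is a
#' `conflict` and is excluded downstream; EMT- (or no-EMT-) related takes
#' precedence over TGF-beta-related so the categories partition the
#' probesets, with dual memberships recorded in the `"tgfb_overlap"`
#' attribute.
#'
#' @param calls Integer matrix, probesets x 7 comparisons, with the
#'   comparison names of [enumerate_comparisons()] as colnames.
#' @return Data frame `probeset_id`, `category`, `direction` with attribute
#'   `tgfb_overlap` (IDs also meeting the TGF-beta rule).
#' @export
categorize_probesets <- function(calls) {
  need <- c("EMT_vs_noEMT", "EMT_vs_other", "EMT_vs_untreated",
            "noEMT_vs_EMT", "noEMT_vs_other", "noEMT_vs_untreated",
            "TGFB_vs_untreated")
  miss <- setdiff(need, colnames(calls))
  if (length(miss))
    stopf("missing comparison(s): %s", paste(miss, collapse = ", "))
  emt_c <- calls[, c("EMT_vs_noEMT", "EMT_vs_other", "EMT_vs_untreated"),
                 drop = FALSE]
  no_c <- calls[, c("noEMT_vs_EMT", "noEMT_vs_other", "noEMT_vs_untreated"),
                drop = FALSE]
  u_c <- calls[, c("EMT_vs_untreated", "noEMT_vs_untreated",
                   "TGFB_vs_untreated"), drop = FALSE]

  consistent <- function(primary, other) {
    d <- primary[, 1]
    ok <- d != 0 & primary[, 2] == d & primary[, 3] == d
    # any non-zero call on the other phenotype must oppose d
    opp <- rowSums(other != 0 & other != -d) == 0
    list(ok = ok & opp, dir = d)
  }
  emt <- consistent(emt_c, no_c)
  noe <- consistent(no_c, emt_c)
  tg_d <- u_c[, 1]
  tg <- tg_d != 0 & u_c[, 2] == tg_d & u_c[, 3] == tg_d

  category <- rep("none", nrow(calls))
  direction <- rep(0L, nrow(calls))
  category[tg] <- "TGFB-related"
  direction[tg] <- tg_d[tg]
  category[noe$ok] <- "no-EMT-related"
  direction[noe$ok] <- noe$dir[noe$ok]
  category[emt$ok] <- "EMT-related"
  direction[emt$ok] <- emt$dir[emt$ok]
  both <- emt$ok & noe$ok
  category[both] <- "conflict"
  direction[both] <- 0L

  ids <- rownames(calls) %||% as.character(seq_len(nrow(calls)))
  out <- data.frame(probeset_id = ids, category = category,
                    direction = direction, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "tgfb_overlap") <- ids[(emt$ok | noe$ok) & tg & !both]
  out
}
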