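#' Score a cohort on the signature's first principal component
#'
#' Subsets the cohort to the signature probesets, autoscales, runs PCA and
#' takes the PC1 sample scores as the signature score. The component is
#' oriented from the loadings alone — never from outcome data: if the
#' correlation between the PC1 loadings and the signature direction signs is
#' negative, scores and loadings are flipped together, so a high score
#' always means "more mesenchymal".
#'
#' @param m An [expr_matrix] cohort.
#' @param sig An `emt_signature`; at least 3 of its probesets must be
#'   present (and non-constant) in `m`.
#' @return A data frame of class `scored_cohort` with columns `sample_id`
#'   and `score`, and attributes `orientation_sign`, `loadings`,
#'   `pct_variance`, `n_probesets_used`.
#' @export
score_cohort <- function(m, sig) {
  common <- intersect(sig$probeset_id, probeset_ids(m))
  if (length(common) < 3) {
    missing <- setdiff(sig$probeset_id, probeset_ids(m))
    stopf("only %d signature probesets overlap the cohort (missing: %s%s)",
          length(common), paste(utils::head(missing, 10), collapse = ", "),
          if (length(missing) > 10) ", ..." else "")
  }
  sub <- autoscale(subset_probesets(m, common))
  kept <- probeset_ids(sub)
  if (length(kept) < 3)
    stopf("fewer than 3 variable signature probesets in the cohort")
  pc <- pca(sub, n_components = 1L)
  l1 <- pc$loadings[, 1]
  dirs <- sig$direction[match(kept, sig$probeset_id)]
  s <- suppressWarnings(stats::cor(l1, dirs))
  if (is.na(s)) s <- sum(l1 * dirs)
  orientation <- if (s < 0) -1L else 1L
  scores <- orientation * pc$scores[, 1]
  out <- data.frame(sample_id = sample_ids(m), score = unname(scores),
                    stringsAsFactors = FALSE)
  structure(out, class = c("scored_cohort", "data.frame"),
            orientation_sign = orientation,
            loadings = orientation * l1,
            pct_variance = pc$pct_variance[1],
            n_probesets_used = length(kept))
}

#' @export
print.scored_cohort <- function(x, ...) {
  cat(sprintf("scored cohort: %d samples (PC1 %.1f%% variance, %d probesets, orientation %+d)\n",
              nrow(x), attr(x, "pct_variance"), attr(x, "n_probesets_used"),
              attr(x, "orientation_sign")))
  if ("group" %in% colnames(x))
    cat(sprintf("  groups: %d high / %d low (%s split)\n",
                sum(x$group == "high"), sum(x$group == "low"),
                attr(x, "split_method") %||% "?"))
  invisible(x)
}

#' Median split of signature scores
#'
#' Samples scoring strictly above the cohort median are `high`; the median
#' itself and ties go `low`.
#'
#' @param scored A `scored_cohort` (or numeric score vector).
#' @return The `scored_cohort` with a `group` column (or a character vector
#'   for numeric input).
#' @export
median_split <- function(scored) {
  s <- if (is.data.frame(scored)) scored$score else scored
  if (length(s) < 2) stopf("need at least 2 samples to split")
  if (diff(range(s)) == 0) stopf("all scores equal; no stratification possible")
  grp <- ifelse(s > stats::median(s), "high", "low")
  if (!is.data.frame(scored)) return(grp)
  scored$group <- grp
  attr(scored, "split_method") <- "median"
  scored
}

#' Two-cluster k-means split on signature-gene expression
#'
#' Runs k = 2 k-means (best of `restarts` random initializations under a
#' fixed seed) on the autoscaled signature-gene expression, then labels the
#' cluster with the higher mean PC1 signature score `high`, so the labels do
#' not depend on arbitrary cluster indices.
#'
#' @param m An [expr_matrix] cohort (>= 4 samples).
#' @param sig An `emt_signature`.
#' @param restarts Number of k-means restarts (default 10).
#' @param seed RNG seed for the clustering.
#' @return A `scored_cohort` with a `group` column.
#' @export
kmeans_split <- function(m, sig, restarts = 10L, seed = 1L) {
  if (ncol(m$values) < 4) stopf("need at least 4 samples for k-means split")
  scored <- score_cohort(m, sig)
  common <- intersect(sig$probeset_id, probeset_ids(m))
  X <- t(autoscale(subset_probesets(m, common))$values)
  if (nrow(unique(X)) < 2)
    stopf("degenerate data: all samples identical on signature genes")
  km <- with_seed(seed,
                  stats::kmeans(X, centers = 2L, nstart = as.integer(restarts)))
  mean_by_cluster <- tapply(scored$score, km$cluster, mean)
  high_cl <- as.integer(names(which.max(mean_by_cluster)))
  scored$group <- ifelse(km$cluster == high_cl, "high", "low")
  attr(scored, "split_method") <- "kmeans"
  attr(scored, "withinss") <- sum(km$withinss)
  scored
}
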