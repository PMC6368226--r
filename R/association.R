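#' Two-group comparison of signature scores
#'
#' Two-sided Welch t-test of PC1 signature scores between two label
#' classes (e.g. metastasis present vs absent at surgery).
#'
#' @param scores Numeric score vector.
#' @param labels Vector coercible to a two-level factor, aligned to
#'   `scores`; each class needs at least 2 samples.
#' @return List: `statistic`, `p_value`, `means` (named by class),
#'   `classes`.
#' @export
score_group_ttest <- function(scores, labels) {
  f <- factor(labels)
  if (nlevels(f) != 2)
    stopf("labels must have exactly 2 classes (got %d)", nlevels(f))
  n <- table(f)
  if (any(n < 2))
    stopf("class '%s' has fewer than 2 samples", names(n)[which.min(n)])
  x <- scores[f == levels(f)[1]]
  y <- scores[f == levels(f)[2]]
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       means = stats::setNames(c(mean(x), mean(y)), levels(f)),
       classes = levels(f))
}

#' Wild-type versus mutant score comparison per gene
#'
#' Applies [score_group_ttest()] (or a two-sided Wilcoxon rank-sum test) to
#' every `mut_<GENE>` column of the annotation. Columns with a single class
#' (all wild-type or all mutant) are skipped with a warning.
#'
#' @param scores Numeric score vector aligned to `ann` rows.
#' @param ann Annotation data frame carrying 0/1 `mut_<GENE>` columns (or a
#'   plain 0/1 mutation data frame whose column names are gene symbols).
#' @param test `"t"` (Welch, default) or `"wilcox"`.
#' @return Data frame: `gene`, `n_mutant`, `mean_wt`, `mean_mutant`,
#'   `statistic`, `p_value`.
#' @export
mutation_score_comparison <- function(scores, ann, test = c("t", "wilcox")) {
  test <- match.arg(test)
  mut <- extract_mutation_table(ann)
  if (!ncol(mut))
    return(data.frame(gene = character(0), n_mutant = integer(0),
                      mean_wt = numeric(0), mean_mutant = numeric(0),
                      statistic = numeric(0), p_value = numeric(0)))
  rows <- lapply(colnames(mut), function(g) {
    flag <- mut[[g]]
    if (length(unique(flag)) < 2 || min(table(flag)) < 2) {
      warnf("mutation column '%s' has a single class (or <2 per class); skipped", g)
      return(NULL)
    }
    wt <- scores[flag == 0]
    mu <- scores[flag == 1]
    res <- if (test == "t") stats::t.test(mu, wt)
           else suppressWarnings(stats::wilcox.test(mu, wt))
    data.frame(gene = g, n_mutant = sum(flag == 1), mean_wt = mean(wt),
               mean_mutant = mean(mu), statistic = unname(res$statistic),
               p_value = res$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), n_mutant = integer(0),
                      mean_wt = numeric(0), mean_mutant = numeric(0),
                      statistic = numeric(0), p_value = numeric(0))
  rownames(out) <- NULL
  out
}

# accept either mut_-prefixed annotation columns or a bare 0/1 table
extract_mutation_table <- function(ann) {
  cols <- grep("^mut_", colnames(ann), value = TRUE)
  if (length(cols)) {
    mut <- ann[, cols, drop = FALSE]
    colnames(mut) <- sub("^mut_", "", cols)
  } else {
    is01 <- vapply(ann, function(x) all(x %in% c(0, 1)), logical(1))
    mut <- ann[, is01, drop = FALSE]
  }
  mut
}

#' Per-gene mutation enrichment between high and low clusters
#'
#' For each gene, builds the 2x2 table of cluster membership (high/low)
#' against mutation status and computes the two-sided Fisher exact p-value
#' (small-p-values definition: the sum of probabilities of all tables, with
#' the observed margins, no more likely than the observed one) together
#' with the sample odds ratio (infinite when a zero cell forces it) and a
#' Benjamini-Hochberg q-value reported alongside the nominal p.
#'
#' @param groups Character vector of `"high"`/`"low"` cluster labels.
#' @param ann Annotation (or bare 0/1 table) with mutation columns as in
#'   [mutation_score_comparison()].
#' @return Data frame of class `enrichment_result`: `gene`, `high_mutant`,
#'   `high_wt`, `low_mutant`, `low_wt`, `odds_ratio`, `p_value`, `q_value`,
#'   ordered by p-value.
#' @export
fisher_enrichment <- function(groups, ann) {
  if (!all(groups %in% c("high", "low")))
    stopf("groups must be 'high'/'low'")
  if (!any(groups == "high") || !any(groups == "low"))
    stopf("both clusters must be non-empty")
  mut <- extract_mutation_table(ann)
  if (!ncol(mut))
    return(structure(data.frame(gene = character(0)),
                     class = c("enrichment_result", "data.frame")))
  rows <- lapply(colnames(mut), function(g) {
    flag <- mut[[g]]
    a <- sum(groups == "high" & flag == 1)
    b <- sum(groups == "high" & flag == 0)
    cc <- sum(groups == "low" & flag == 1)
    d <- sum(groups == "low" & flag == 0)
    tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    or <- if (b * cc == 0) {
      if (a * d == 0) NA_real_ else Inf
    } else (a * d) / (b * cc)
    data.frame(gene = g, high_mutant = a, high_wt = b, low_mutant = cc,
               low_wt = d, odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}
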