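one_row_stats <- function(id, diff, sep, t_p = 1e-4, mw_p = 1e-3) {
  data.frame(probeset_id = id, mean_experimental = diff, mean_reference = 0,
             difference = diff, complete_separation = sep, t_p = t_p,
             mw_p = mw_p, stringsAsFactors = FALSE)
}

cats_of <- function(ids, category = "EMT-related", direction = 1L) {
  data.frame(probeset_id = ids, category = category, direction = direction,
             stringsAsFactors = FALSE)
}

test_that("strongest filter needs separation, 2-fold worst case and dual p", {
  cats <- cats_of("p1")
  keep <- strongest_filter(cats, list(
    one_row_stats("p1", 1.4, TRUE, 1e-4, 1e-3),
    one_row_stats("p1", 1.2, FALSE),
    one_row_stats("p1", 1.05, FALSE, 1e-4, 1e-3)))
  expect_equal(keep, "p1")

  # worst comparison below the 2-fold cutoff
  keep2 <- strongest_filter(cats, list(
    one_row_stats("p1", 1.4, TRUE), one_row_stats("p1", 1.2, TRUE),
    one_row_stats("p1", 0.9, TRUE)))
  expect_length(keep2, 0)

  # no complete separation anywhere
  keep3 <- strongest_filter(cats, list(
    one_row_stats("p1", 1.4, FALSE), one_row_stats("p1", 1.2, FALSE),
    one_row_stats("p1", 1.05, FALSE)))
  expect_length(keep3, 0)

  # dual-test condition on the worst comparison
  keep4 <- strongest_filter(cats, list(
    one_row_stats("p1", 1.4, TRUE),
    one_row_stats("p1", 1.2, TRUE),
    one_row_stats("p1", 1.05, TRUE, t_p = 1e-4, mw_p = 0.002)))
  expect_length(keep4, 0)

  expect_error(strongest_filter(cats, list(
    one_row_stats("p2", 1, TRUE), one_row_stats("p1", 1, TRUE),
    one_row_stats("p1", 1, TRUE))), "missing")
})

test_that("raising the pruning threshold never enlarges the selection", {
  set.seed(7)
  ids <- sprintf("p%02d", 1:30)
  stats <- lapply(1:3, function(k)
    one_row_stats(ids, runif(30, 0.5, 2.5), sample(c(TRUE, FALSE), 30, TRUE),
                  runif(30, 0, 0.004), runif(30, 0, 0.004)))
  k1 <- strongest_filter(cats_of(ids), stats,
                         filter_config(strong_fold_threshold_log2 = 1.0))
  k2 <- strongest_filter(cats_of(ids), stats,
                         filter_config(strong_fold_threshold_log2 = 1.4))
  expect_true(all(k2 %in% k1))
})

test_that("curated probesets merge with recorded provenance", {
  ids <- sprintf("a%03d", 1:128)
  cats <- cats_of(c(ids, sprintf("c%d", 1:7)))
  syms <- setNames(toupper(cats$probeset_id), cats$probeset_id)
  cur <- data.frame(probeset_id = sprintf("c%d", 1:7),
                    gene_symbol = sprintf("CG%d", 1:7))
  sig <- add_curated(ids, cur, cats, syms)
  expect_equal(nrow(sig), 135)
  expect_equal(sum(sig$provenance == "curated"), 7)

  # already-selected curated entry stays algorithmic, no duplicate
  cur2 <- data.frame(probeset_id = c("a001", "c1"),
                     gene_symbol = c("A001", "CG1"))
  sig2 <- add_curated(ids, cur2, cats, syms)
  expect_equal(nrow(sig2), 129)
  expect_equal(sig2$provenance[sig2$probeset_id == "a001"], "algorithmic")

  # empty curated list is the identity
  sig3 <- add_curated(ids, NULL, cats, syms)
  expect_equal(sig3$probeset_id, ids)

  expect_error(add_curated(ids, data.frame(probeset_id = "zz",
                                           gene_symbol = "Z"), cats, syms),
               "zz")
})

test_that("translation keeps concordant and removes anti-correlated probesets", {
  sig <- toy_signature(12)
  z <- withr_seed(31, rnorm(80))
  cohort <- toy_cohort(sig, z, seed = 32)
  tr <- translation_filter(sig, list(cohort))
  expect_equal(sum(tr$report$removed), 0)
  expect_equal(nrow(tr$signature), nrow(sig))

  # one probeset generated against its claimed direction, three cohorts
  gen_sig <- sig
  gen_sig$direction[1] <- -gen_sig$direction[1]
  cohorts <- lapply(1:3, function(k)
    toy_cohort(gen_sig, withr_seed(40 + k, rnorm(80)), seed = 50 + k))
  tr2 <- translation_filter(sig, cohorts)
  expect_true(tr2$report$removed[1])
  expect_false(any(tr2$report$removed[-1]))
  expect_equal(tr2$report$n_evaluated[1], 3)

  # global sign flip of a cohort changes no removal decision
  flipped <- lapply(cohorts, function(m) expr_matrix(-m$values, m$gene_symbols))
  tr3 <- translation_filter(sig, flipped)
  expect_equal(tr3$report$removed, tr2$report$removed)

  # cohort ordering does not matter
  tr4 <- translation_filter(sig, rev(cohorts))
  expect_equal(tr4$report$removed, tr2$report$removed)
  expect_equal(nrow(tr4$signature), nrow(tr2$signature))
})

test_that("translation skips small cohorts and never gains entries", {
  sig <- toy_signature(6)
  tiny <- make_expr(matrix(rnorm(4), 2, 2), probesets = c("sp1", "sp2"))
  good <- toy_cohort(sig, withr_seed(3, rnorm(40)), seed = 4)
  expect_warning(tr <- translation_filter(sig, list(tiny = tiny, ok = good)),
                 "skipped")
  expect_lte(nrow(tr$signature), nrow(sig))
  expect_error(suppressWarnings(translation_filter(sig, list(tiny))),
               "all cohorts")
})

test_that("include-list restriction preserves order and warns on misses", {
  sig <- reference_signature()
  some <- unique(sig$gene_symbol)[1:40]
  out <- apply_include_list(sig, some)
  expect_true(all(out$gene_symbol %in% some))
  expect_equal(out$probeset_id,
               sig$probeset_id[sig$gene_symbol %in% some])
  expect_warning(apply_include_list(sig, c(some[1], "NOT_A_GENE")),
                 "NOT_A_GENE")
  expect_warning(out0 <- apply_include_list(sig, character(0)), "empty")
  expect_equal(nrow(out0), 0)
  out_all <- apply_include_list(sig, unique(sig$gene_symbol))
  expect_equal(as.data.frame(out_all), as.data.frame(sig),
               ignore_attr = TRUE)
})
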