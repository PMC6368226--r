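scheme_of <- function(n_emt, n_noemt, n_untreated) {
  structure(list(emt = sprintf("e%d", seq_len(n_emt)),
                 no_emt = sprintf("n%d", seq_len(n_noemt)),
                 untreated = sprintf("u%d", seq_len(n_untreated)),
                 excluded = character(0)),
            class = "group_scheme")
}

test_that("the seven comparisons are enumerated with the right groups", {
  cmp <- enumerate_comparisons(scheme_of(4, 8, 13))
  expect_named(cmp, c("EMT_vs_noEMT", "EMT_vs_other", "EMT_vs_untreated",
                      "noEMT_vs_EMT", "noEMT_vs_other", "noEMT_vs_untreated",
                      "TGFB_vs_untreated"))
  expect_length(cmp$EMT_vs_other$reference, 21)
  expect_length(cmp$TGFB_vs_untreated$experimental, 12)
  expect_length(cmp$noEMT_vs_other$reference, 17)
  expect_error(enumerate_comparisons(scheme_of(4, 8, 0)), "empty")
})

test_that("group scheme excludes constitutively mesenchymal lines entirely", {
  ann <- toy_cellline_annotation()
  mes <- data.frame(sample_id = c("M1_U1", "M1_T1"), unit_id = "M1",
                    treatment = c("untreated", "treated"), time_hours = c(0, 24),
                    phenotype_class = "constitutively-mesenchymal")
  sc <- group_scheme(rbind(ann, mes))
  expect_setequal(sc$excluded, mes$sample_id)
  expect_false(any(mes$sample_id %in% c(sc$emt, sc$no_emt, sc$untreated)))
  expect_length(sc$emt, 2)
  expect_length(sc$no_emt, 3)
  expect_length(sc$untreated, 10)
})

test_that("compare_groups computes means, separation and test p-values", {
  vals <- rbind(c(1.2, 1.5, 0.3, 0.9),
                c(1.0, 2.0, 1.5, 2.5))
  m <- make_expr(vals, samples = c("a1", "a2", "b1", "b2"))
  st <- compare_groups(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(st$difference[1], 0.75)
  expect_true(st$complete_separation[1])
  expect_false(st$complete_separation[2])
  expect_equal(st$difference, st$mean_experimental - st$mean_reference,
               tolerance = 1e-10)
  expect_true(all(st$t_p >= 0 & st$t_p <= 1))

  # exact Mann-Whitney agrees with full enumeration of assignments
  m2 <- make_expr(matrix(c(1, 2, 3, 4, 5, 6), 1), samples = letters[1:6])
  st2 <- compare_groups(m2, c("a", "b", "c"), c("d", "e", "f"))
  expect_equal(st2$mw_p, 0.1)
  expect_equal(st2$mw_p, oracle_mw(c(1, 2, 3), c(4, 5, 6)))

  # identical groups: zero difference, no separation, p = 1
  m3 <- make_expr(matrix(c(1, 2, 3, 1, 2, 3), 1), samples = letters[1:6])
  st3 <- compare_groups(m3, c("a", "b", "c"), c("d", "e", "f"))
  expect_equal(st3$difference, 0)
  expect_false(st3$complete_separation)
  expect_equal(st3$t_p, 1)

  expect_error(compare_groups(m3, c("a", "b"), c("b", "c")), "overlap")
  expect_warning(compare_groups(m3, "a", c("b", "c")), "single sample")
})

test_that("call_de requires sign agreement and the inclusive 0.585 cutoff", {
  st <- data.frame(mean_experimental = c(0.9, 0.2, 0.585, -0.9, 0.5),
                   mean_reference = c(0.2, 0.9, 0, -0.2, 0.0))
  st$difference <- st$mean_experimental - st$mean_reference
  expect_equal(call_de(st), c(1L, 0L, 1L, -1L, 0L))
  # threshold boundary is inclusive, just below fails
  st2 <- data.frame(mean_experimental = 0.5849, mean_reference = 0,
                    difference = 0.5849)
  expect_equal(call_de(st2), 0L)
})

test_that("categorization applies the triple-consistency and conflict rules", {
  cols <- c("EMT_vs_noEMT", "EMT_vs_other", "EMT_vs_untreated",
            "noEMT_vs_EMT", "noEMT_vs_other", "noEMT_vs_untreated",
            "TGFB_vs_untreated")
  calls <- rbind(
    emt_up      = c(1, 1, 1, 0, 0, 0, 0),    # clean EMT-related, +1
    not_emt     = c(1, 1, 1, 0, 0, 1, 0),    # same-sign no-EMT call blocks
    emt_opp     = c(1, 1, 1, -1, 0, -1, 0),  # opposite no-EMT calls fine
    tgfb        = c(0, 0, 1, 0, 0, 1, 1),    # all three vs-untreated agree
    conflict    = c(1, 1, 1, -1, -1, -1, 0), # EMT and no-EMT both satisfied
    noemt_dn    = c(0, 0, 0, -1, -1, -1, 0),
    none        = c(1, 0, 1, 0, 0, 0, 0))
  colnames(calls) <- cols
  cat <- categorize_probesets(calls)
  expect_equal(cat$category,
               c("EMT-related", "none", "EMT-related", "TGFB-related",
                 "conflict", "no-EMT-related", "none"))
  expect_equal(cat$direction,
               c(1L, 0L, 1L, 1L, 0L, -1L, 0L))
  # direction is zero exactly for none/conflict
  expect_equal(cat$direction == 0, cat$category %in% c("none", "conflict"))
  expect_error(categorize_probesets(calls[, -1]), "missing comparison")
})

test_that("categorization is invariant to probeset order and EMT beats TGFB", {
  cols <- c("EMT_vs_noEMT", "EMT_vs_other", "EMT_vs_untreated",
            "noEMT_vs_EMT", "noEMT_vs_other", "noEMT_vs_untreated",
            "TGFB_vs_untreated")
  set.seed(42)
  calls <- matrix(sample(c(-1L, 0L, 1L), 200 * 7, replace = TRUE), 200, 7,
                  dimnames = list(sprintf("p%03d", 1:200), cols))
  cat1 <- categorize_probesets(calls)
  perm <- sample(200)
  cat2 <- categorize_probesets(calls[perm, ])
  expect_equal(cat2[order(match(cat2$probeset_id, cat1$probeset_id)), ],
               cat1, ignore_attr = TRUE)
  # a probeset meeting both the EMT and TGFB rules is reported EMT-related
  both <- matrix(c(1, 1, 1, 0, 0, 1, 1), 1,
                 dimnames = list("dual", cols))
  # same-sign no-EMT-vs-untreated call blocks EMT; flip it to opposite
  both2 <- matrix(c(1, 1, 1, 0, 0, 0, 1), 1, dimnames = list("dual", cols))
  expect_equal(categorize_probesets(both)$category, "TGFB-related")
  expect_equal(categorize_probesets(both2)$category, "EMT-related")
})

test_that("a single seeded cell-line simulation screens planted EMT genes", {
  sim <- simulate_cellline_experiment(seed = 101)
  fit <- derive_signature(sim$expression, sim$annotation)
  emt <- sim$truth$probeset_id[sim$truth$class %in% c("emt_up", "emt_down")]
  called <- fit$categories$probeset_id[fit$categories$category == "EMT-related"]
  expect_gt(mean(emt %in% called), 0.9)
  expect_lt(mean(!called %in% emt), 0.1)
  # planted signs recovered
  idx <- match(intersect(called, emt), fit$categories$probeset_id)
  tru <- sim$truth$direction[match(fit$categories$probeset_id[idx],
                                   sim$truth$probeset_id)]
  expect_equal(fit$categories$direction[idx], tru)
})
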