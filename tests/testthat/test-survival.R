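cohort_ann <- function(n, n_baseline_met = 0, os_time = NULL, os_event = NULL,
                       met_time = NULL, met_event = NULL) {
  data.frame(sample_id = sprintf("P%03d", seq_len(n)),
             os_time = os_time %||% rep(50, n),
             os_event = os_event %||% rep(0L, n),
             met_time = met_time %||% rep(50, n),
             met_event = met_event %||% rep(0L, n),
             baseline_metastasis = rep(c(1L, 0L),
                                       c(n_baseline_met, n - n_baseline_met)),
             stringsAsFactors = FALSE)
}

test_that("MFS excludes baseline metastases and takes the earlier event", {
  ann <- cohort_ann(136, n_baseline_met = 3)
  expect_equal(nrow(build_endpoint(ann, "MFS")), 133)
  expect_equal(nrow(build_endpoint(ann, "OS")), 136)

  one <- cohort_ann(1, os_time = 40, os_event = 0, met_time = 20,
                    met_event = 1)
  rec <- build_endpoint(one, "MFS")
  expect_equal(rec$time, 20)
  expect_equal(rec$event, 1L)

  # death before metastasis is still an MFS event
  two <- cohort_ann(1, os_time = 15, os_event = 1, met_time = 30,
                    met_event = 0)
  rec2 <- build_endpoint(two, "MFS")
  expect_equal(rec2$time, 15)
  expect_equal(rec2$event, 1L)

  # administrative censoring at the horizon
  late <- cohort_ann(1, os_time = 72, os_event = 1, met_time = 80,
                     met_event = 0)
  rec3 <- build_endpoint(late, "MFS", horizon_months = 60)
  expect_equal(rec3$time, 60)
  expect_equal(rec3$event, 0L)

  bad <- cohort_ann(2, os_time = c(10, -1))
  expect_error(build_endpoint(bad, "OS"), "P002")
  expect_error(build_endpoint(cohort_ann(2)[, 1:3], "MFS"), "met_time")
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # toy 1: two events
  k1 <- km_estimate(data.frame(time = c(1, 2), event = c(1, 1)))
  expect_equal(km_surv_at(k1, 1), 0.5)
  expect_equal(km_surv_at(k1, 2), 0)
  # toy 2: censor then event
  k2 <- km_estimate(data.frame(time = c(1, 2), event = c(0, 1)))
  expect_equal(km_surv_at(k2, 2), 0)
  # toy 3: event/censoring tie, events first
  k3 <- km_estimate(data.frame(time = c(1, 1, 2), event = c(1, 0, 1)))
  expect_equal(km_surv_at(k3, 1), 2 / 3)
  expect_equal(km_surv_at(k3, 2), 0)
  # no events: flat at 1
  k4 <- km_estimate(data.frame(time = c(3, 5), event = c(0, 0)))
  expect_equal(km_surv_at(k4, 5), 1)
  # curve invariants
  expect_true(all(diff(k3$surv) <= 0))
  expect_true(all(diff(k3$n_risk) < 0))
})

test_that("without censoring the KM curve is the empirical survival function", {
  set.seed(17)
  tt <- round(rexp(40, 0.05), 1)
  k <- km_estimate(data.frame(time = tt, event = 1L))
  orc <- oracle_km(tt, rep(1, 40))
  for (i in seq_len(nrow(orc))) {
    expect_equal(km_surv_at(k, orc$time[i]), orc$surv[i], tolerance = 1e-12)
    expect_equal(orc$surv[i], mean(tt > orc$time[i]), tolerance = 1e-12)
  }
})

test_that("log-rank matches the manual O/E/V table and is symmetric", {
  a <- data.frame(time = c(1, 2, 3), event = 1L)
  b <- data.frame(time = c(4, 5, 6), event = 1L)
  lr <- logrank_test(a, b)
  orc <- oracle_logrank(c(a$time, b$time), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(lr$chisq, orc$chisq, tolerance = 1e-10)
  expect_equal(lr$p_value, orc$p, tolerance = 1e-10)

  swapped <- logrank_test(b, a)
  expect_equal(swapped$chisq, lr$chisq, tolerance = 1e-12)
  expect_equal(swapped$p_value, lr$p_value, tolerance = 1e-12)

  same <- data.frame(time = c(2, 4, 6), event = c(1L, 0L, 1L))
  ident <- logrank_test(same, same)
  expect_equal(ident$chisq, 0, tolerance = 1e-12)
  expect_equal(ident$p_value, 1, tolerance = 1e-12)

  none <- data.frame(time = c(1, 2), event = 0L)
  z <- logrank_test(none, none)
  expect_equal(z$chisq, 0)
  expect_equal(z$p_value, 1)
})

test_that("log-rank agrees with the oracle on 50 seeded random datasets", {
  for (k in 1:50) {
    set.seed(300 + k)
    n <- sample(20:60, 1)
    time <- round(rexp(n, 0.04), 2)
    event <- rbinom(n, 1, 0.8)
    grp <- rbinom(n, 1, 0.5)
    if (sum(event) == 0 || length(unique(grp)) < 2) next
    a <- data.frame(time = time[grp == 0], event = event[grp == 0])
    b <- data.frame(time = time[grp == 1], event = event[grp == 1])
    lr <- logrank_test(a, b)
    orc <- oracle_logrank(time, event, grp)
    expect_equal(lr$p_value, orc$p, tolerance = 1e-6)
  }
})

test_that("delta_surv reports high-minus-low in percentage points", {
  hi <- km_estimate(data.frame(time = c(10, 20, 30, 40, 50),
                               event = c(1, 1, 0, 0, 0)))
  expect_equal(delta_surv(hi, hi, 36), 0)
  # S_high(36) = 0.60 vs S_low(36) = 0.85
  hi2 <- km_estimate(data.frame(time = c(rep(30, 8), rep(70, 12)),
                                event = c(rep(1, 8), rep(0, 12))))
  lo2 <- km_estimate(data.frame(time = c(rep(30, 3), rep(70, 17)),
                                event = c(rep(1, 3), rep(0, 17))))
  expect_equal(km_surv_at(hi2, 36), 0.60)
  expect_equal(km_surv_at(lo2, 36), 0.85)
  expect_equal(delta_surv(hi2, lo2, 36), -25.0)
  # KM locality: re-timing follow-up beyond t changes nothing at t
  lo3 <- km_estimate(data.frame(time = c(rep(30, 3), rep(70, 10), rep(90, 7)),
                                event = c(rep(1, 3), rep(0, 17))))
  expect_equal(delta_surv(hi2, lo3, 36), delta_surv(hi2, lo2, 36))
  expect_error(delta_surv(hi2, lo2, 80), "beyond")
})

test_that("stage subsetting leaves other records' contributions untouched", {
  set.seed(23)
  ann <- cohort_ann(60, os_time = round(rexp(60, 0.02), 1),
                    os_event = rbinom(60, 1, 0.6),
                    met_time = round(rexp(60, 0.03), 1),
                    met_event = rbinom(60, 1, 0.4))
  ann$stage <- rep(c("I", "II"), 30)
  recs <- build_endpoint(ann, "MFS")
  sub <- build_endpoint(ann[ann$stage == "I", ], "MFS")
  expect_equal(sub, recs[recs$sample_id %in%
                           ann$sample_id[ann$stage == "I"], ],
               ignore_attr = TRUE)
})
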