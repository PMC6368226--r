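#' Default pipeline configuration
#'
#' A single nested configuration covering every stage; all screening and
#' pruning thresholds (0.585, 1.0, 0.002), the survival horizons (36/60
#' months) and the translation vote (0.5) are named keys defaulting to
#' their standard values. `simulate` holds the [sim_config()] blocks; set
#' `n_translation_cohorts` to control how many synthetic tumor cohorts feed
#' the translation filter.
#'
#' @param ... Named overrides of the top-level keys.
#' @return A nested list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    filter = list(fold_threshold_log2 = 0.585,
                  strong_fold_threshold_log2 = 1.0,
                  strong_p_cutoff = 0.002),
    translation = list(n_translation_cohorts = 3L, min_agree_fraction = 0.5),
    survival = list(horizons_months = c(36, 60)),
    simulate = list(),
    stages = c("simulate", "derive", "translate", "score", "survive",
               "associate"))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Orchestrates the stages end to end on seeded synthetic data: simulate
#' the cell-line experiment, derive and prune the signature, translate it
#' against simulated tumor cohorts, score a held-out cohort, run the
#' median-split survival analyses (OS and MFS at the configured horizons)
#' and the colon/mutation association analyses. Fails fast with a
#' stage-labelled error; identical config and seed give an identical
#' report. When `out_dir` is given, artifacts (signature, scores, KM
#' tables, the JSON report and the resolved config) are written atomically
#' (temp file then rename).
#'
#' @param config A [pipeline_config()] list or the path to a YAML file with
#'   the same structure.
#' @param out_dir Optional output directory for artifacts.
#' @param seed Optional seed overriding `config$seed`.
#' @return A list of class `emt_run_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(pipeline_config(), config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  known <- c("simulate", "derive", "translate", "score", "survive",
             "associate")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stopf("unknown stage name(s): %s", paste(bad, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[stage %s] %s", name, conditionMessage(e)))
  }
  seed0 <- config$seed
  fcfg <- do.call(filter_config, config$filter)
  scfg <- do.call(sim_config, config$simulate)
  report <- list(seed = seed0, thresholds = config$filter,
                 version = as.character(utils::packageVersion("emtsig")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 stages = list())
  add_stage <- function(name, n_in, n_out, extra = list()) {
    report$stages[[name]] <<- c(list(n_in = n_in, n_out = n_out), extra)
  }

  cell <- NULL; fit <- NULL; sig <- NULL
  if ("simulate" %in% config$stages) {
    cell <- stage("simulate",
                  simulate_cellline_experiment(scfg, seed = derive_seed(seed0, 1)))
    add_stage("simulate", NA_integer_, nrow(cell$truth),
              list(n_samples = nrow(cell$annotation)))
  }
  if ("derive" %in% config$stages) {
    if (is.null(cell)) stopf("[stage derive] no simulated cell-line data")
    fit <- stage("derive",
                 derive_signature(cell$expression, cell$annotation,
                                  config = fcfg))
    sig <- fit$signature
    add_stage("derive", nrow(cell$truth), nrow(sig),
              list(funnel = as.list(fit$funnel)))
  }
  if ("translate" %in% config$stages) {
    if (is.null(sig)) stopf("[stage translate] no derived signature")
    ncoh <- config$translation$n_translation_cohorts
    cohorts <- stage("translate", lapply(seq_len(ncoh), function(k)
      simulate_tumor_cohort(scfg, sig, seed = derive_seed(seed0, 10 + k))$expression))
    tr <- stage("translate",
                translation_filter(sig, cohorts,
                                   config$translation$min_agree_fraction))
    add_stage("translate", nrow(sig), nrow(tr$signature),
              list(n_cohorts = ncoh,
                   removed = sum(tr$report$removed)))
    sig <- tr$signature
  }
  scored <- NULL; cohort <- NULL
  if ("score" %in% config$stages) {
    if (is.null(sig)) stopf("[stage score] no signature")
    cohort <- stage("score",
                    simulate_tumor_cohort(scfg, sig, seed = derive_seed(seed0, 20)))
    scored <- stage("score", median_split(score_cohort(cohort$expression, sig)))
    add_stage("score", nrow(sig), nrow(scored),
              list(orientation_sign = attr(scored, "orientation_sign"),
                   pct_variance_pc1 = attr(scored, "pct_variance")))
  }
  surv_out <- NULL
  if ("survive" %in% config$stages) {
    if (is.null(scored)) stopf("[stage survive] no scored cohort")
    need <- c("os_time", "os_event", "met_time", "met_event",
              "baseline_metastasis")
    miss <- setdiff(need, colnames(cohort$annotation))
    if (length(miss))
      stopf("[stage survive] annotation missing field(s): %s",
            paste(miss, collapse = ", "))
    surv_out <- stage("survive", {
      ann <- cohort$annotation
      ann$group <- scored$group[match(ann$sample_id, scored$sample_id)]
      lapply(stats::setNames(nm = c("OS", "MFS")), function(ep) {
        lapply(stats::setNames(nm = as.character(config$survival$horizons_months)),
               function(h) {
          rec <- build_endpoint(ann, ep, horizon_months = as.numeric(h))
          grp <- ann$group[match(rec$sample_id, ann$sample_id)]
          hi <- rec[grp == "high", , drop = FALSE]
          lo <- rec[grp == "low", , drop = FALSE]
          lr <- logrank_test(hi, lo)
          ds <- tryCatch(delta_surv(km_estimate(hi), km_estimate(lo),
                                    as.numeric(h)),
                         error = function(e) NA_real_)
          list(n = nrow(rec), n_high = nrow(hi), n_low = nrow(lo),
               chisq = lr$chisq, p_value = lr$p_value,
               delta_surv_pct = ds)
        })
      })
    })
    add_stage("survive", nrow(scored),
              surv_out$MFS[[1]]$n, list(results = surv_out))
  }
  assoc_out <- NULL
  if ("associate" %in% config$stages) {
    if (is.null(sig)) stopf("[stage associate] no signature")
    assoc_out <- stage("associate", {
      colon <- simulate_colon_cohort(scfg, sig, seed = derive_seed(seed0, 30))
      cs <- score_cohort(colon$expression, sig)
      colon_test <- score_group_ttest(cs$score,
                                      colon$annotation$baseline_metastasis)
      mutc <- simulate_mutation_cohort(scfg, sig, seed = derive_seed(seed0, 31))
      grp <- kmeans_split(mutc$expression, sig,
                          seed = derive_seed(seed0, 32))$group
      enr <- fisher_enrichment(grp, mutc$annotation)
      ms <- mutation_score_comparison(score_cohort(mutc$expression, sig)$score,
                                      mutc$annotation)
      list(colon_t = colon_test$statistic, colon_p = colon_test$p_value,
           enrichment = as.data.frame(enr),
           mutation_score = ms)
    })
    add_stage("associate", nrow(sig), nrow(assoc_out$enrichment),
              list(colon_p = assoc_out$colon_p))
  }

  report$signature <- if (!is.null(sig)) as.data.frame(sig) else NULL
  report <- structure(report, class = "emt_run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(sig))
      write_atomic(function(p) write_signature(sig, p),
                   file.path(out_dir, "signature.tsv"))
    if (!is.null(scored))
      write_atomic(function(p) utils::write.table(
        as.data.frame(scored), p, sep = "\t", quote = FALSE,
        row.names = FALSE), file.path(out_dir, "scores.tsv"))
    write_atomic(function(p) jsonlite::write_json(
      unclass(report), p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
      dataframe = "rows", force = TRUE),
      file.path(out_dir, "run_report.json"))
    write_atomic(function(p) yaml::write_yaml(config, p),
                 file.path(out_dir, "config_resolved.yaml"))
  }
  report
}

#' @export
print.emt_run_report <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d, version %s)\n", x$seed, x$version))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-10s in=%s out=%s\n", nm,
                ifelse(is.na(st$n_in), "-", st$n_in), st$n_out))
  }
  if (!is.null(x$stages$survive)) {
    mfs <- x$stages$survive$results$MFS
    for (h in names(mfs))
      cat(sprintf("  MFS @%sm: log-rank p = %.3g, delta = %.1f%%\n",
                  h, mfs[[h]]$p_value, mfs[[h]]$delta_surv_pct))
  }
  invisible(x)
}
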