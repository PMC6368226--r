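#' Simulation configuration
#'
#' Defaults describe the study conditions the generators emulate: a
#' 13-line TGF-beta time course (4 EMT-responder, 8 non-responder and one
#' constitutively mesenchymal line, two treated time points plus two
#' untreated controls per line), planted probeset classes with a 1.5 log2
#' treatment effect over 0.3-sd noise on a 1.0-sd per-line baseline; tumor
#' cohorts whose signature-gene expression tracks a standard-normal latent
#' EMT activity that also drives exponential metastasis and death clocks;
#' a 96-patient colon-style cohort with a +1 sd latent shift for patients
#' metastatic at surgery; and binary mutation tables with planted
#' cluster-dependent carrier probabilities.
#'
#' @param cellline,probesets,cohort,colon,mutation Named lists overriding
#'   individual defaults of the corresponding block.
#' @return Nested list of class `sim_config`.
#' @export
sim_config <- function(cellline = list(), probesets = list(),
                       cohort = list(), colon = list(), mutation = list()) {
  merge_block <- function(defaults, override) {
    bad <- setdiff(names(override), names(defaults))
    if (length(bad))
      stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
    utils::modifyList(defaults, override)
  }
  cfg <- list(
    cellline = merge_block(list(
      n_responder = 4L, n_nonresponder = 8L, n_mesenchymal = 1L,
      treated_times = c(24, 72), n_control_reps = 2L,
      baseline_mean = 8, baseline_sd = 1.0), cellline),
    probesets = merge_block(list(
      n_emt_up = 30L, n_emt_down = 30L, n_noemt = 15L, n_shared = 15L,
      n_null = 210L, effect_size = 1.5, noise_sd = 0.3), probesets),
    cohort = merge_block(list(
      n = 300L, beta = 1.0, noise_sd = 0.5, n_null_genes = 50L,
      baseline_mean = 8, baseline_hazard_death = 0.01,
      baseline_hazard_met = 0.02, gamma = 0.7, censor_max_months = 120,
      stage_probs = c(I = 0.5, II = 0.3, III = 0.2),
      baseline_met_prob = 0.02, baseline_met_n = NULL), cohort),
    colon = merge_block(list(n = 96L, met_prob = 0.25, shift = 1.0), colon),
    mutation = merge_block(list(
      genes = data.frame(
        gene = c("KEAP1", "HGF", "ZNF831", "TP53", "EGFR", "KRAS"),
        p_low = c(0.40, 0.40, 0.05, 0.20, 0.15, 0.25),
        p_high = c(0.05, 0.05, 0.40, 0.20, 0.15, 0.25),
        enriched = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
        stringsAsFactors = FALSE)), mutation))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  cl <- cfg$cellline; pr <- cfg$probesets; co <- cfg$cohort
  counts <- c(cl$n_responder, cl$n_nonresponder, cl$n_control_reps,
              length(cl$treated_times), co$n, cfg$colon$n)
  if (any(counts < 1)) stopf("simulation counts must be positive")
  if (cl$n_mesenchymal < 0 || pr$n_null < 0 || co$n_null_genes < 0)
    stopf("simulation counts must be non-negative")
  if (pr$noise_sd <= 0 || cl$baseline_sd <= 0 || co$noise_sd <= 0)
    stopf("simulation standard deviations must be positive")
  if (pr$effect_size < 0) stopf("effect size must be non-negative")
  probs <- c(co$baseline_met_prob, cfg$colon$met_prob,
             cfg$mutation$genes$p_low, cfg$mutation$genes$p_high)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (co$baseline_hazard_death <= 0 || co$baseline_hazard_met <= 0)
    stopf("baseline hazards must be positive")
  invisible(cfg)
}

planted_probesets <- function(pr) {
  mk <- function(prefix, n) sprintf("%s_%03d", prefix, seq_len(n))
  data.frame(
    probeset_id = c(mk("EMTUP", pr$n_emt_up), mk("EMTDN", pr$n_emt_down),
                    mk("NOEMT", pr$n_noemt), mk("SHARED", pr$n_shared),
                    mk("NULLP", pr$n_null)),
    class = rep(c("emt_up", "emt_down", "no_emt", "shared_tgfb", "null"),
                c(pr$n_emt_up, pr$n_emt_down, pr$n_noemt, pr$n_shared,
                  pr$n_null)),
    direction = rep(c(1L, -1L, 1L, 1L, 0L),
                    c(pr$n_emt_up, pr$n_emt_down, pr$n_noemt, pr$n_shared,
                      pr$n_null)),
    stringsAsFactors = FALSE)
}

#' Simulate the multi-cell-line TGF-beta time course
#'
#' Generates log2 intensities as per-line, per-probeset Gaussian baselines
#' plus planted treatment effects plus noise. EMT probesets respond (with
#' their planted sign) only in treated samples of responder lines; shared
#' TGF-beta probesets respond in all treated lines; no-EMT probesets
#' respond only in treated non-responder lines; constitutively mesenchymal
#' lines carry the mesenchymal shift on EMT probesets in both untreated and
#' treated samples. Data come out already on a common scale, so no
#' normalization is needed before computing log ratios.
#'
#' @param cfg A [sim_config].
#' @param seed Integer seed; same seed, same output bit for bit.
#' @return List: `expression` ([expr_matrix]), `annotation` (data frame),
#'   `truth` (per-probeset planted class/direction).
#' @export
simulate_cellline_experiment <- function(cfg = sim_config(), seed = 1L) {
  validate_sim_config(cfg)
  cl <- cfg$cellline; pr <- cfg$probesets
  truth <- planted_probesets(pr)
  lines <- data.frame(
    unit_id = c(sprintf("RSP%d", seq_len(cl$n_responder)),
                sprintf("NRS%d", seq_len(cl$n_nonresponder)),
                if (cl$n_mesenchymal > 0)
                  sprintf("MES%d", seq_len(cl$n_mesenchymal))),
    phenotype_class = rep(c("EMT-responder", "non-EMT",
                            "constitutively-mesenchymal"),
                          c(cl$n_responder, cl$n_nonresponder,
                            cl$n_mesenchymal)),
    stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(seq_len(nrow(lines)), function(i) {
    u <- lines$unit_id[i]
    rbind(
      data.frame(sample_id = sprintf("%s_U0_r%d", u,
                                     seq_len(cl$n_control_reps)),
                 unit_id = u, treatment = "untreated", time_hours = 0,
                 phenotype_class = lines$phenotype_class[i],
                 stringsAsFactors = FALSE),
      data.frame(sample_id = sprintf("%s_T%d", u, cl$treated_times),
                 unit_id = u, treatment = "treated",
                 time_hours = cl$treated_times,
                 phenotype_class = lines$phenotype_class[i],
                 stringsAsFactors = FALSE))
  }))
  rownames(samples) <- NULL
  n_p <- nrow(truth); n_s <- nrow(samples)
  vals <- with_seed(seed, {
    base_line <- matrix(stats::rnorm(n_p * nrow(lines), cl$baseline_mean,
                                     cl$baseline_sd),
                        n_p, nrow(lines), dimnames = list(NULL, lines$unit_id))
    eff <- matrix(0, n_p, n_s)
    treated <- samples$treatment == "treated"
    resp <- samples$phenotype_class == "EMT-responder"
    nonr <- samples$phenotype_class == "non-EMT"
    mes <- samples$phenotype_class == "constitutively-mesenchymal"
    is_emt <- truth$class %in% c("emt_up", "emt_down")
    eff[is_emt, treated & resp] <- truth$direction[is_emt] * pr$effect_size
    eff[is_emt, mes] <- truth$direction[is_emt] * pr$effect_size
    eff[truth$class == "shared_tgfb", treated] <- pr$effect_size
    eff[truth$class == "no_emt", treated & nonr] <- pr$effect_size
    base_line[, samples$unit_id] + eff +
      matrix(stats::rnorm(n_p * n_s, 0, pr$noise_sd), n_p, n_s)
  })
  dimnames(vals) <- list(truth$probeset_id, samples$sample_id)
  list(expression = expr_matrix(vals, gene_symbols = truth$probeset_id),
       annotation = samples, truth = truth)
}

# latent-activity expression block shared by the cohort generators:
# signature genes track direction * beta * z, null genes are pure noise
cohort_expression <- function(sig, z, co) {
  n <- length(z)
  sig_vals <- co$baseline_mean + outer(sig$direction * co$beta, z) +
    matrix(stats::rnorm(nrow(sig) * n, 0, co$noise_sd), nrow(sig), n)
  ids <- sig$probeset_id
  syms <- sig$gene_symbol
  if (co$n_null_genes > 0) {
    null_ids <- sprintf("NULLG_%03d", seq_len(co$n_null_genes))
    null_vals <- co$baseline_mean +
      matrix(stats::rnorm(co$n_null_genes * n, 0, co$noise_sd),
             co$n_null_genes, n)
    sig_vals <- rbind(sig_vals, null_vals)
    ids <- c(ids, null_ids)
    syms <- c(syms, null_ids)
  }
  dimnames(sig_vals) <- list(ids, sprintf("P%04d", seq_len(n)))
  expr_matrix(sig_vals, gene_symbols = syms)
}

#' Simulate a tumor cohort with latent-activity-driven survival
#'
#' Each patient carries a standard-normal latent EMT activity z. Signature
#' genes express `direction * beta * z` plus noise; null genes are noise.
#' Metastasis and death are two exponential clocks with log-hazards
#' `log(h0) + gamma * z` (the metastasis clock on an earlier scale), with
#' independent uniform censoring, so higher latent activity means both a
#' higher signature score and worse outcomes.
#'
#' @param cfg A [sim_config].
#' @param sig An `emt_signature` supplying the probesets/directions.
#' @param seed Integer seed.
#' @return List: `expression`, `annotation` (clinical fields in months),
#'   `truth` (per-patient z and hazards).
#' @export
simulate_tumor_cohort <- function(cfg = sim_config(), sig = reference_signature(),
                                  seed = 1L) {
  validate_sim_config(cfg)
  if (!nrow(sig)) stopf("signature must be non-empty")
  co <- cfg$cohort
  with_seed(seed, {
    n <- co$n
    z <- stats::rnorm(n)
    m <- cohort_expression(sig, z, co)
    rate_d <- co$baseline_hazard_death * exp(co$gamma * z)
    rate_m <- co$baseline_hazard_met * exp(co$gamma * z)
    t_death <- stats::rexp(n, rate_d)
    t_met <- stats::rexp(n, rate_m)
    t_cens <- stats::runif(n, 0, co$censor_max_months)
    os_time <- pmin(t_death, t_cens)
    os_event <- as.integer(t_death <= t_cens)
    met_time <- pmin(t_met, t_death, t_cens)
    met_event <- as.integer(t_met <= pmin(t_death, t_cens))
    base_met <- if (!is.null(co$baseline_met_n)) {
      flags <- integer(n)
      flags[sample.int(n, co$baseline_met_n)] <- 1L
      flags
    } else stats::rbinom(n, 1, co$baseline_met_prob)
    stage <- sample(names(co$stage_probs), n, replace = TRUE,
                    prob = co$stage_probs)
    ann <- data.frame(sample_id = sample_ids(m),
                      unit_id = sample_ids(m), treatment = "untreated",
                      os_time = os_time, os_event = os_event,
                      met_time = met_time, met_event = met_event,
                      baseline_metastasis = base_met, stage = stage,
                      stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = sample_ids(m), z = z,
                        hazard_death = rate_d, hazard_met = rate_m,
                        t_death = t_death, t_met = t_met,
                        stringsAsFactors = FALSE)
    list(expression = m, annotation = ann, truth = truth)
  })
}

#' Simulate a colon-style cohort with baseline metastasis labels
#'
#' Patients metastatic at the time of surgery draw their latent activity
#' from a distribution shifted upward by `shift` standard deviations, so
#' their signature scores run higher.
#'
#' @param cfg A [sim_config].
#' @param sig An `emt_signature`.
#' @param seed Integer seed.
#' @return List: `expression`, `annotation` (with `baseline_metastasis`),
#'   `truth` (latent z).
#' @export
simulate_colon_cohort <- function(cfg = sim_config(), sig = reference_signature(),
                                  seed = 1L) {
  validate_sim_config(cfg)
  if (!nrow(sig)) stopf("signature must be non-empty")
  co <- cfg$cohort; cn <- cfg$colon
  with_seed(seed, {
    n <- cn$n
    met <- stats::rbinom(n, 1, cn$met_prob)
    z <- stats::rnorm(n) + cn$shift * met
    co$n <- n
    m <- cohort_expression(sig, z, co)
    ann <- data.frame(sample_id = sample_ids(m), unit_id = sample_ids(m),
                      treatment = "untreated", baseline_metastasis = met,
                      stringsAsFactors = FALSE)
    list(expression = m, annotation = ann,
         truth = data.frame(sample_id = sample_ids(m), z = z,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a mutation cohort with planted cluster-specific enrichment
#'
#' Expression and latent activity as in [simulate_tumor_cohort()]. For each
#' configured gene, carrier probability depends on the sign of z (the proxy
#' for the eventual high/low score cluster): planted-enriched genes use
#' `p_low` when z < 0 and `p_high` otherwise; null genes use one constant
#' probability.
#'
#' @param cfg A [sim_config].
#' @param sig An `emt_signature`.
#' @param seed Integer seed.
#' @return List: `expression`, `annotation` (with `mut_<GENE>` columns),
#'   `truth` (z plus per-gene enrichment status).
#' @export
simulate_mutation_cohort <- function(cfg = sim_config(),
                                     sig = reference_signature(), seed = 1L) {
  validate_sim_config(cfg)
  if (!nrow(sig)) stopf("signature must be non-empty")
  co <- cfg$cohort; mg <- cfg$mutation$genes
  with_seed(seed, {
    n <- co$n
    z <- stats::rnorm(n)
    m <- cohort_expression(sig, z, co)
    ann <- data.frame(sample_id = sample_ids(m), unit_id = sample_ids(m),
                      treatment = "untreated", stringsAsFactors = FALSE)
    for (i in seq_len(nrow(mg))) {
      p <- ifelse(z < 0, mg$p_low[i], mg$p_high[i])
      ann[[paste0("mut_", mg$gene[i])]] <- stats::rbinom(n, 1, p)
    }
    list(expression = m, annotation = ann,
         truth = list(z = stats::setNames(z, sample_ids(m)),
                      genes = mg))
  })
}
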