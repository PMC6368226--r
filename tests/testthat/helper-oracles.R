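# Independent oracles, kept deliberately naive: enumeration and manual
# tables, never the package's own code paths.

# two-sided log-rank from the O/E/V table over distinct event times
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# manual product-limit over distinct times (events before censorings)
oracle_km <- function(time, event) {
  tt <- sort(unique(time))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    n_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = tt, surv = out)
}

# two-sided Fisher exact p by enumerating all tables with the observed
# margins (small-p-values definition)
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  xs <- max(0, k - r2):min(k, r1)
  probs <- dhyper(xs, r1, r2, k)
  p_obs <- dhyper(a, r1, r2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating all group assignments of
# the pooled observations (doubled one-tail, capped at 1)
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(xi) {
    xs <- pooled[xi]
    ys <- pooled[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  us <- apply(idx, 2, function(cols) u_of(cols))
  u_obs <- u_of(seq_len(n1))
  lower <- mean(us <= u_obs + 1e-9)
  upper <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# quick builders -------------------------------------------------------

make_expr <- function(values, probesets = NULL, samples = NULL,
                      symbols = NULL) {
  values <- as.matrix(values)
  rownames(values) <- probesets %||%
    (rownames(values) %||% paste0("p", seq_len(nrow(values))))
  colnames(values) <- samples %||%
    (colnames(values) %||% paste0("s", seq_len(ncol(values))))
  emtsig::expr_matrix(values, symbols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny 5-probeset signature for scoring tests
toy_signature <- function(n = 5) {
  dirs <- rep_len(c(1L, -1L), n)
  emtsig::new_signature(data.frame(
    probeset_id = paste0("sp", seq_len(n)),
    gene_symbol = paste0("G", seq_len(n)),
    direction = dirs, provenance = "algorithmic",
    stringsAsFactors = FALSE), name = "toy")
}

# cohort expression tracking a given latent z under a signature
toy_cohort <- function(sig, z, beta = 1, noise_sd = 0.3, seed = 1) {
  n <- length(z)
  vals <- withr_seed(seed, {
    outer(sig$direction * beta, z) +
      matrix(rnorm(nrow(sig) * n, 0, noise_sd), nrow(sig), n)
  })
  dimnames(vals) <- list(sig$probeset_id, sprintf("c%03d", seq_len(n)))
  emtsig::expr_matrix(vals, sig$gene_symbol)
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# annotation for a small cell-line design
toy_cellline_annotation <- function() {
  units <- data.frame(
    unit_id = c("R1", "R2", "N1", "N2", "N3"),
    phenotype_class = c("EMT-responder", "EMT-responder", "non-EMT",
                        "non-EMT", "non-EMT"),
    stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(units)), function(i) {
    data.frame(sample_id = paste0(units$unit_id[i], c("_U1", "_U2", "_T1")),
               unit_id = units$unit_id[i],
               treatment = c("untreated", "untreated", "treated"),
               time_hours = c(0, 0, 24),
               phenotype_class = units$phenotype_class[i],
               stringsAsFactors = FALSE)
  }))
}
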