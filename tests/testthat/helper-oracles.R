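# Independent oracles used to cross-check the package implementations.
# These are written as literal, step-by-step translations of the defining
# formulas, deliberately sharing no code with the package.

# Brute-force ssGSEA enrichment score: walk the gene list ordered by
# decreasing rank and accumulate P_in - P_out term by term.
oracle_es <- function(expression, set_genes, alpha) {
  stopifnot(!is.null(names(expression)))
  r <- rank(expression, ties.method = "average")
  ord <- order(-r, names(expression), method = "radix")
  genes <- names(expression)[ord]
  n <- length(genes)
  in_set <- genes %in% set_genes
  denom_in <- 0
  for (g in genes[in_set]) denom_in <- denom_in + r[g]^alpha
  n_out <- n - sum(in_set)
  es <- 0
  p_in <- 0
  p_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      p_in <- p_in + r[genes[i]]^alpha / denom_in
    } else {
      p_out <- p_out + 1 / n_out
    }
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Two-group log-rank statistic accumulated at each distinct event time:
# O - E for group A with the hypergeometric variance.
oracle_logrank_chisq <- function(time, event, group) {
  lev <- sort(unique(group))
  stopifnot(length(lev) == 2L)
  event_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & group == lev[1])
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & group == lev[1])
    o_minus_e <- o_minus_e + (d_a - d * n_a / n)
    if (n > 1) {
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
  }
  (o_minus_e)^2 / v
}

# AUC by exhaustive enumeration of event/non-event pairs; ties count 1/2.
oracle_auc_pairs <- function(score, outcome) {
  cases <- score[outcome == 1]
  controls <- score[outcome == 0]
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(cases) * length(controls))
}

# Breslow log partial likelihood for a single numeric covariate, evaluated
# on a grid; returns the grid argmax.
oracle_cox_grid <- function(time, event, x, grid = seq(-3, 3, by = 0.001)) {
  logpl <- vapply(grid, function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }, numeric(1))
  grid[which.max(logpl)]
}

# Pearson r and two-sided P computed straight from the covariance formula
# and the t transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  r <- sxy / sqrt(sxx * syy)
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE))
}

# Random expression matrix with named genes/samples.
random_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

# One reference synthetic cohort shared across tests (computed lazily once).
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    cohort <- generate_cohort(sim_params(seed = 42))
    scores <- score_matrix(cohort$expr,
                           list(cohort$pair$drivers, cohort$pair$suppressors))
    cohort$activity <- suppressMessages(
      compute_rfl(scores["drivers", ], scores["suppressors", ])
    )
    .cohort_cache$cohort <- cohort
  }
  .cohort_cache$cohort
}
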