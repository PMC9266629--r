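#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function under right censoring.
#'
#' @param time positive follow-up times.
#' @param event event indicators (1 = death/progression, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` — the step function evaluated at every distinct observed time.
#' @export
km_estimate <- function(time, event) {
  check_surv_input(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

check_surv_input <- function(time, event) {
  if (length(time) == 0L) stop("no survival records")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (anyNA(time) || anyNA(event)) stop("missing values in survival records")
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  invisible(TRUE)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (hypergeometric variance at each distinct
#' event time), compared against chi-square with 1 df; two-sided.
#'
#' @param time,event survival records for all samples.
#' @param group two-level grouping vector aligned with `time`.
#' @return list with `chisq`, `p`, and per-group observed/expected counts.
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  group <- as.character(group)
  if (length(group) != length(time)) stop("group not aligned with time")
  lev <- unique(group[!is.na(group)])
  if (length(lev) != 2L) stop("log-rank test needs exactly 2 non-empty groups")
  if (sum(event) == 0) stop("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Minimum-P cutoff scan for RFL survival stratification
#'
#' Every distinct observed RFL value between the 10th and 90th percentile
#' (linear-interpolation quantiles) is tried as a cutoff; samples with RFL
#' strictly above the cutoff form the high group. The cutoff with the lowest
#' log-rank P is selected, with ties broken toward the cutoff closest to the
#' median RFL. The hazard ratio of high vs low at the selected cutoff comes
#' from a univariate Cox fit. Minimum-P selection inflates type I error; an
#' optional label-permutation adjustment (`n_perm > 0`) re-runs the full scan
#' on permuted survival labels and reports how often a permuted minimum P
#' undercuts the observed one. It is off by default and never silently
#' applied.
#'
#' @param rfl numeric RFL vector (NA = undefined, excluded).
#' @param time,event survival records aligned with `rfl`.
#' @param lo,hi percentile window bounds (defaults 0.10 and 0.90).
#' @param n_perm number of label permutations for the adjusted P (0 = off).
#' @return list of class `cutoff_scan` with `best_cutoff`, `best_p`,
#'   `hazard_ratio` (high vs low), `hr_p` (Wald), `scanned`
#'   (data.frame cutoff/p), `groups` (labels at the best cutoff, aligned
#'   with the input), and `perm_p` (NA when `n_perm = 0`).
#' @export
scan_cutoff <- function(rfl, time, event, lo = 0.10, hi = 0.90, n_perm = 0) {
  check_surv_input(time[!is.na(rfl)], event[!is.na(rfl)])
  if (length(rfl) != length(time)) stop("rfl not aligned with survival records")
  ok <- !is.na(rfl)
  if (sum(ok) < 10L) stop("need at least 10 samples with defined RFL")
  if (sum(event[ok]) == 0) stop("need at least one event")
  r <- rfl[ok]; tt <- time[ok]; ev <- event[ok]
  if (stats::sd(r) == 0) stop("RFL is constant; no cutoff stratifies the cohort")
  win <- stats::quantile(r, probs = c(lo, hi), type = 7, names = FALSE)
  cand <- sort(unique(r[r >= win[1] & r <= win[2]]))
  cand <- cand[vapply(cand, function(v) any(r > v) && any(r <= v), logical(1))]
  if (length(cand) == 0L) stop("no candidate cutoff yields two non-empty groups")
  scan_one <- function(v, ev_use) {
    g <- ifelse(r > v, "high", "low")
    if (sum(ev_use) == 0) return(NA_real_)
    sd <- survival::survdiff(survival::Surv(tt, ev_use) ~ g)
    stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE)
  }
  ps <- vapply(cand, scan_one, numeric(1), ev_use = ev)
  best_p <- min(ps, na.rm = TRUE)
  at_min <- which(ps == best_p)
  med <- stats::median(r)
  best_i <- at_min[which.min(abs(cand[at_min] - med))]
  best_cutoff <- cand[best_i]
  g_best <- ifelse(r > best_cutoff, "high", "low")
  cx <- survival::coxph(survival::Surv(tt, ev) ~ I(g_best == "high"),
                        ties = "breslow")
  scx <- summary(cx)
  perm_p <- NA_real_
  if (n_perm > 0) {
    n_le <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(tt))
      tt_b <- tt[idx]; ev_b <- ev[idx]
      ps_b <- vapply(cand, function(v) {
        g <- ifelse(r > v, "high", "low")
        sd <- survival::survdiff(survival::Surv(tt_b, ev_b) ~ g)
        stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE)
      }, numeric(1))
      if (min(ps_b, na.rm = TRUE) <= best_p) n_le <- n_le + 1L
    }
    perm_p <- (1 + n_le) / (1 + n_perm)
  }
  groups <- rep(NA_character_, length(rfl))
  groups[ok] <- g_best
  structure(list(best_cutoff = best_cutoff, best_p = best_p,
                 hazard_ratio = unname(scx$conf.int[1, "exp(coef)"]),
                 hr_p = unname(scx$coefficients[1, "Pr(>|z|)"]),
                 scanned = data.frame(cutoff = cand, p = ps),
                 groups = groups, perm_p = perm_p),
            class = "cutoff_scan")
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximum with Breslow tie handling. Constant covariates
#' are dropped with a warning; categorical covariates are handled through the
#' usual treatment contrasts against their first level. The conventions for
#' flagging effects follow common practice: HR > 1 with P < 0.05 is adverse,
#' HR < 1 with P < 0.05 favorable.
#'
#' @param time,event survival records.
#' @param covariates data.frame of covariate columns (numeric or factor),
#'   one row per sample.
#' @return object of class `cox_fit`: `table` (coef, hr, se, z, p,
#'   direction per model term), `fit` (the underlying `coxph` object),
#'   `centers` (covariate means used for risk-score centering), `dropped`
#'   (names of constant covariates removed).
#' @export
cox_fit <- function(time, event, covariates) {
  check_surv_input(time, event)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(time)) stop("covariates not aligned with time")
  if (sum(event) < 2) stop("Cox fit needs at least 2 events")
  const <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) <= 1L,
                  logical(1))
  dropped <- names(covariates)[const]
  if (length(dropped) > 0L) {
    warning("dropping constant covariates: ", paste(dropped, collapse = ", "))
    covariates <- covariates[, !const, drop = FALSE]
  }
  if (ncol(covariates) == 0L) stop("no non-constant covariates to fit")
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                         ties = "breslow", x = TRUE)
  if (any(is.na(stats::coef(fit)))) {
    stop("Cox fit failed to estimate all coefficients (after ", fit$iter,
         " iterations); check covariate collinearity")
  }
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    se = s$coefficients[, "se(coef)"],
    z = s$coefficients[, "z"],
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL
  )
  tab$direction <- ifelse(tab$p >= 0.05, "ns",
                          ifelse(tab$hr > 1, "adverse", "favorable"))
  structure(list(table = tab, fit = fit, centers = fit$means,
                 dropped = dropped),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties)\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Centered Cox risk score
#'
#' The risk score of a sample is its centered linear predictor,
#' `RS = sum_k beta_k (x_k - center_k)`, with centers taken at the fitting
#' cohort's covariate means, so the mean RS over the fitting cohort is 0 and
#' RS > 0 means above-average modeled risk. Samples are grouped "high"
#' (RS > 0) vs "low" (RS <= 0).
#'
#' @param model a [cox_fit()] object.
#' @param covariates data.frame of the model's covariates for the samples to
#'   score (defaults to the fitting cohort).
#' @return data.frame of class `risk_model` with columns `rs` and `group`.
#' @export
risk_score <- function(model, covariates = NULL) {
  stopifnot(inherits(model, "cox_fit"))
  if (is.null(covariates)) {
    rs <- unname(model$fit$linear.predictors)
  } else {
    covariates <- as.data.frame(covariates)
    bad <- !stats::complete.cases(covariates)
    if (any(bad)) {
      stop("missing covariate values for samples: ",
           paste(utils::head(which(bad), 10), collapse = ", "))
    }
    rs <- unname(stats::predict(model$fit, newdata = covariates, type = "lp"))
  }
  structure(data.frame(rs = rs, group = ifelse(rs > 0, "high", "low"),
                       stringsAsFactors = FALSE),
            class = c("risk_model", "data.frame"))
}

#' ROC area under the curve for a binary outcome
#'
#' AUC is the probability that a randomly chosen event sample outscores a
#' randomly chosen non-event sample, with ties counting one half — computed
#' through the Mann-Whitney rank identity.
#'
#' @param score numeric risk scores.
#' @param outcome binary event indicators (0/1); both classes must occur.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(score, outcome) {
  if (length(score) != length(outcome)) stop("score and outcome lengths differ")
  if (anyNA(score) || anyNA(outcome)) stop("missing values in score/outcome")
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1")
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  r <- rank(score, ties.method = "average")
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
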