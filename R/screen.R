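#' Screen all genes for correlation with RFL
#'
#' Per-gene Pearson correlation between expression and RFL, with two-sided
#' P-values from `t = r * sqrt(n - 2) / sqrt(1 - r^2)`. Genes are classed
#' `positive` (r > threshold_r and P < threshold_p, both strict),
#' `negative` (r < -threshold_r and P < threshold_p) or `none`; constant
#' genes get NA statistics and class `none`.
#'
#' @param expr numeric genes x samples matrix.
#' @param rfl numeric RFL vector aligned with the matrix columns
#'   (NA entries excluded from every correlation).
#' @param cohort optional cohort label stored on the result.
#' @param threshold_r,threshold_p classification thresholds
#'   (defaults 0.3 and 0.05).
#' @return data.frame of class `screen_result` with columns `gene`, `n`,
#'   `r`, `p`, `class` and attribute `cohort`.
#' @export
correlate_genes <- function(expr, rfl, cohort = NA_character_,
                            threshold_r = 0.3, threshold_p = 0.05) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) != length(rfl)) stop("rfl not aligned with matrix samples")
  ok <- !is.na(rfl)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 samples with defined RFL")
  x <- t(expr[, ok, drop = FALSE])
  r <- suppressWarnings(as.vector(stats::cor(rfl[ok], x)))
  p <- vapply(r, function(ri) if (is.na(ri)) NA_real_ else pearson_p(ri, n),
              numeric(1))
  cls <- rep("none", length(r))
  cls[!is.na(r) & r > threshold_r & p < threshold_p] <- "positive"
  cls[!is.na(r) & r < -threshold_r & p < threshold_p] <- "negative"
  res <- data.frame(gene = rownames(expr), n = n, r = r, p = p, class = cls,
                    stringsAsFactors = FALSE)
  attr(res, "cohort") <- cohort
  attr(res, "threshold_r") <- threshold_r
  attr(res, "threshold_p") <- threshold_p
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Select markedly RFL-correlated genes from a screen
#'
#' Strict thresholds on both criteria: positively correlated genes satisfy
#' r > threshold_r and P < threshold_p; negative analogously. No
#' multiple-testing correction is applied by default, matching the screening
#' convention the thresholds come from; set `adjust = "BH"` for
#' Benjamini-Hochberg adjusted P-values instead.
#'
#' @param result a [correlate_genes()] result.
#' @param threshold_r,threshold_p selection thresholds.
#' @param adjust "none" (default) or "BH".
#' @return list with character vectors `positive` and `negative` (disjoint).
#' @export
select_correlated <- function(result, threshold_r = 0.3, threshold_p = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(result, "screen_result"))
  p <- result$p
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  ok <- !is.na(result$r) & !is.na(p)
  list(
    positive = result$gene[ok & result$r > threshold_r & p < threshold_p],
    negative = result$gene[ok & result$r < -threshold_r & p < threshold_p]
  )
}

#' Recurrently RFL-correlated genes across cohorts
#'
#' A gene is selected when it is markedly correlated, with a consistent
#' sign, in at least `min_cohorts` cohorts: its count in one direction must
#' reach `min_cohorts` while its count in the opposite direction is zero.
#'
#' @param selections named list, one entry per cohort, each a list with
#'   `positive` and `negative` gene id vectors (as from
#'   [select_correlated()]).
#' @param min_cohorts minimum number of supporting cohorts (default 7).
#' @return data.frame with columns `gene`, `n_positive`, `n_negative`,
#'   `direction` ("positive"/"negative"/"mixed"), `selected`; rows sorted
#'   by gene id, so the result is invariant to cohort ordering.
#' @export
recurrent_genes <- function(selections, min_cohorts = 7) {
  if (length(selections) < min_cohorts) {
    stop("need at least ", min_cohorts, " cohorts, got ", length(selections))
  }
  pos <- table(unlist(lapply(selections, function(s) unique(s$positive))))
  neg <- table(unlist(lapply(selections, function(s) unique(s$negative))))
  genes <- sort(unique(c(names(pos), names(neg))))
  if (length(genes) == 0L) {
    return(data.frame(gene = character(0), n_positive = integer(0),
                      n_negative = integer(0), direction = character(0),
                      selected = logical(0)))
  }
  n_pos <- as.integer(pos[genes]); n_pos[is.na(n_pos)] <- 0L
  n_neg <- as.integer(neg[genes]); n_neg[is.na(n_neg)] <- 0L
  direction <- ifelse(n_pos > 0 & n_neg > 0, "mixed",
                      ifelse(n_pos > 0, "positive", "negative"))
  selected <- (n_pos >= min_cohorts & n_neg == 0L) |
    (n_neg >= min_cohorts & n_pos == 0L)
  data.frame(gene = genes, n_positive = n_pos, n_negative = n_neg,
             direction = direction, selected = selected,
             stringsAsFactors = FALSE)
}

#' Jaccard overlap matrix between cohort gene sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`; the diagonal is 1 by
#' convention, and a pair of empty sets gives 0 with a warning.
#'
#' @param sets named list of character vectors (one gene set per cohort).
#' @return symmetric numeric matrix with entries in \[0, 1\].
#' @export
jaccard_matrix <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 cohorts")
  if (is.null(names(sets))) names(sets) <- paste0("cohort", seq_along(sets))
  sets <- lapply(sets, unique)
  k <- length(sets)
  m <- matrix(1, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      u <- length(union(sets[[i]], sets[[j]]))
      if (u == 0L) {
        warning("cohorts '", names(sets)[i], "' and '", names(sets)[j],
                "' both have empty sets; Jaccard defined as 0")
        m[i, j] <- m[j, i] <- 0
      } else {
        m[i, j] <- m[j, i] <- length(intersect(sets[[i]], sets[[j]])) / u
      }
    }
  }
  m
}
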