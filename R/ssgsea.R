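#' ssGSEA scoring parameters
#'
#' @param alpha rank-weighting exponent, >= 0. 0.25 is the conventional
#'   ssGSEA default; 0 gives the unweighted Kolmogorov-Smirnov walk.
#' @param normalize if `TRUE`, every enrichment score produced by a
#'   [score_matrix()] call is divided by the range (max - min) of all scores
#'   in that call. The RFL ratio is invariant to this rescaling (both
#'   activities are divided by the same positive constant), so it defaults
#'   to off; it only matters for cross-cohort comparability displays.
#' @param tie_method tie rule passed to [rank_transform()]; "average" is
#'   deterministic and standard.
#' @return an object of class `ssgsea_params`.
#' @export
ssgsea_params <- function(alpha = 0.25, normalize = FALSE,
                          tie_method = c("average", "min", "max")) {
  tie_method <- match.arg(tie_method)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("alpha must be a single non-negative number")
  }
  structure(list(alpha = alpha, normalize = isTRUE(normalize),
                 tie_method = tie_method),
            class = "ssgsea_params")
}

#' Within-sample rank transform
#'
#' ssGSEA operates on within-sample expression ranks, which is what makes the
#' scores invariant to any strictly increasing per-sample transform of the
#' expression values.
#'
#' @param x numeric expression vector over N >= 2 genes (names preserved).
#' @param tie_method how tied values are ranked.
#' @return ranks in \[1, N\], ascending with expression.
#' @export
rank_transform <- function(x, tie_method = c("average", "min", "max")) {
  tie_method <- match.arg(tie_method)
  if (length(x) < 2L) stop("need at least 2 genes to rank")
  if (anyNA(x)) stop("expression vector contains missing values")
  rank(x, ties.method = tie_method)
}

#' Single-sample enrichment score for one gene set
#'
#' Weighted Kolmogorov-Smirnov running sum over the gene list ordered by
#' decreasing within-sample rank: at position i,
#' `P_in(i) = sum(r_j^alpha; j <= i, g_j in S) / sum(r_g^alpha; g in S)` and
#' `P_out(i) = #(j <= i, g_j not in S) / (N - |S|)`; the score is
#' `ES = sum_i (P_in(i) - P_out(i))`. Genes with equal rank are walked in
#' lexicographic gene-id order so the result is deterministic.
#'
#' @param ranks named rank vector (as from [rank_transform()]) over all
#'   measured genes.
#' @param gene_set a [gene_set] or character vector of gene ids; intersected
#'   with the measured genes before scoring.
#' @param alpha rank-weighting exponent, >= 0.
#' @return the raw enrichment score (finite scalar).
#' @export
es_single <- function(ranks, gene_set, alpha = 0.25) {
  if (is.null(names(ranks))) stop("ranks must be named by gene id")
  set_genes <- if (inherits(gene_set, "gene_set")) gene_set$genes else
    unique(normalize_gene_ids(gene_set))
  n <- length(ranks)
  in_set <- toupper(names(ranks)) %in% set_genes
  n_in <- sum(in_set)
  if (n_in == 0L) stop("no gene of the set is measured")
  if (n_in == n) stop("gene set covers every measured gene; P_out is undefined")
  ord <- order(-ranks, names(ranks), method = "radix")
  hit <- in_set[ord]
  w <- (ranks[ord]^alpha) * hit
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!hit) / (n - n_in)
  sum(p_in - p_out)
}

#' ssGSEA scores for several gene sets across all samples
#'
#' @param expr numeric genes x samples matrix with unique gene row names and
#'   sample column names; no missing values.
#' @param sets list of [gene_set] objects (or character vectors) to score.
#' @param params an [ssgsea_params] object.
#' @return numeric sets x samples matrix of enrichment scores. Set genes
#'   absent from the matrix are intersected out (a message reports the count);
#'   a set with no measured gene is an error naming the set.
#' @export
score_matrix <- function(expr, sets, params = ssgsea_params()) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in matrix")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids in matrix")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (!inherits(params, "ssgsea_params")) stop("params must be ssgsea_params()")
  if (inherits(sets, "gene_set")) sets <- list(sets)
  set_names <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "gene_set")) s$name
    else if (!is.null(names(sets)[i]) && nzchar(names(sets)[i])) names(sets)[i]
    else paste0("set", i)
  }, character(1))
  measured <- toupper(rownames(expr))
  set_genes <- lapply(seq_along(sets), function(i) {
    g <- if (inherits(sets[[i]], "gene_set")) sets[[i]]$genes else
      unique(normalize_gene_ids(sets[[i]]))
    kept <- intersect(g, measured)
    if (length(kept) == 0L) {
      stop("gene set '", set_names[i], "' has no measured gene")
    }
    if (length(kept) < length(g)) {
      message("gene set '", set_names[i], "': ", length(g) - length(kept),
              " of ", length(g), " genes not measured; intersected out")
    }
    kept
  })
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr),
                   dimnames = list(set_names, colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- rank_transform(expr[, j], params$tie_method)
    for (i in seq_along(set_genes)) {
      scores[i, j] <- es_single(r, set_genes[[i]], params$alpha)
    }
  }
  if (params$normalize) {
    rng <- max(scores) - min(scores)
    if (rng == 0) stop("cannot range-normalize: all scores identical")
    scores <- scores / rng
  }
  scores
}
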