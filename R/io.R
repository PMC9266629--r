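#' Read a gene x sample expression matrix from TSV
#'
#' Expected layout: first column gene id, header row of sample ids, numeric
#' body. Gene ids are case-normalized; rows containing any missing value are
#' dropped with a message.
#'
#' @param path TSV path.
#' @return numeric genes x samples matrix.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column and >= 1 sample")
  genes <- normalize_gene_ids(df[[1]])
  if (length(genes) != nrow(df)) stop("empty gene ids in ", path)
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  bad <- apply(m, 1, anyNA)
  if (any(bad)) {
    message("dropping ", sum(bad), " genes with missing values from ", path)
    m <- m[!bad, , drop = FALSE]
  }
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr genes x samples matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Expected columns: `sample`, `time`, `event`, then optional covariate
#' columns (age, gender, race, stage, ...).
#'
#' @param path TSV path.
#' @return data.frame with validated `time` (> 0) and `event` (0/1).
#' @export
read_clinical_tsv <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("clinical table ", path, " lacks columns: ", paste(miss, collapse = ", "))
  }
  check_surv_input(df$time, df$event)
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in ", path)
  df
}

#' Write a data.frame as TSV (tab-separated, no quoting)
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
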