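#' Normalize gene identifiers
#'
#' Gene symbols are compared case-insensitively after trimming whitespace;
#' GMT files from different sources mix cases for the same symbol.
#'
#' @param x character vector of gene identifiers.
#' @return upper-cased, trimmed identifiers (empty tokens dropped).
#' @keywords internal
normalize_gene_ids <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

#' Construct a gene set
#'
#' @param name non-empty set label.
#' @param genes character vector of gene identifiers; duplicates are collapsed
#'   (first occurrence kept) and identifiers are case-normalized.
#' @return an object of class `gene_set` with elements `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  name <- trimws(as.character(name))
  if (length(name) != 1L || !nzchar(name)) {
    stop("gene set name must be a single non-empty string")
  }
  genes <- unique(normalize_gene_ids(genes))
  if (length(genes) == 0L) {
    stop("gene set '", name, "' has no genes")
  }
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' ignored. Duplicate genes within a line are collapsed and empty tokens
#' dropped; the order of sets in the file is preserved.
#'
#' @param path path to a GMT file.
#' @return a list of [gene_set] objects, named by set name.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, " in ", path,
           ": expected at least 3 tab-separated fields, got ", length(fields))
    }
    sets[[i]] <- gene_set(fields[[1]], fields[-(1:2)])
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a driver/suppressor gene-set pair with hygiene filters
#'
#' Applies the two signature-hygiene rules used when assembling ferroptosis
#' driver and suppressor signatures: genes that appear in both the driver and
#' the suppressor list are excluded from *both* lists (their role is
#' ambiguous), and, when a whitelist (e.g. protein-coding genes) is supplied,
#' genes outside it are removed. All exclusions are recorded so that any
#' further curation can be layered on top.
#'
#' @param drivers a [gene_set] of ferroptosis-promoting genes.
#' @param suppressors a [gene_set] of ferroptosis-preventing genes.
#' @param whitelist optional character vector of allowed gene identifiers
#'   (case-normalized before use); `NULL` disables the filter.
#' @return an object of class `gene_set_pair` with elements `drivers`,
#'   `suppressors`, `excluded_overlap`, `excluded_noncoding`.
#' @export
build_pair <- function(drivers, suppressors, whitelist = NULL) {
  stopifnot(inherits(drivers, "gene_set"), inherits(suppressors, "gene_set"))
  d <- drivers$genes
  s <- suppressors$genes
  overlap <- intersect(d, s)
  d <- setdiff(d, overlap)
  s <- setdiff(s, overlap)
  noncoding <- character(0)
  if (!is.null(whitelist)) {
    wl <- unique(normalize_gene_ids(whitelist))
    noncoding <- sort(unique(c(setdiff(d, wl), setdiff(s, wl))))
    d <- intersect(d, wl)
    s <- intersect(s, wl)
  }
  if (length(d) == 0L || length(s) == 0L) {
    stop("gene-set pair is empty after hygiene filters (drivers: ", length(d),
         ", suppressors: ", length(s), "); cannot score")
  }
  structure(
    list(
      drivers = gene_set(drivers$name, d),
      suppressors = gene_set(suppressors$name, s),
      excluded_overlap = sort(overlap),
      excluded_noncoding = noncoding
    ),
    class = "gene_set_pair"
  )
}

#' @export
print.gene_set_pair <- function(x, ...) {
  cat("gene_set_pair: ", length(x$drivers$genes), " drivers, ",
      length(x$suppressors$genes), " suppressors (",
      length(x$excluded_overlap), " overlap-excluded, ",
      length(x$excluded_noncoding), " whitelist-excluded)\n", sep = "")
  invisible(x)
}

#' Read a one-gene-per-line whitelist file
#'
#' @param path plain-text file, one gene identifier per line.
#' @return character vector of normalized identifiers.
#' @export
read_whitelist <- function(path) {
  if (!file.exists(path)) stop("whitelist file not found: ", path)
  unique(normalize_gene_ids(readLines(path, warn = FALSE)))
}
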