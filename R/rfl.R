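#' Compute the relative ferroptosis level (RFL)
#'
#' The RFL of a sample is its drive activity (ssGSEA score of the ferroptosis
#' driver signature) divided by its suppress activity (score of the suppressor
#' signature). Raw enrichment scores can be non-positive; a ratio over a
#' non-positive denominator has no "relative level" interpretation, so samples
#' with suppress activity <= 0 are flagged undefined (`rfl = NA`) and excluded
#' from downstream stages. The count of such samples is reported.
#'
#' @param drive numeric vector of drive activities, named by sample id.
#' @param suppress numeric vector of suppress activities over the same
#'   samples, in the same order.
#' @return a `data.frame` of class `activity_table` with columns `sample`,
#'   `drive`, `suppress`, `rfl` (NA where undefined) and `group`
#'   (NA until [assign_groups()] is applied).
#' @export
compute_rfl <- function(drive, suppress) {
  if (length(drive) != length(suppress)) {
    stop("drive and suppress vectors must have equal length")
  }
  samples <- names(drive)
  if (is.null(samples)) samples <- paste0("S", seq_along(drive))
  if (!is.null(names(suppress)) && !identical(samples, names(suppress))) {
    stop("drive and suppress vectors are named for different samples")
  }
  defined <- !is.na(drive) & !is.na(suppress) & suppress > 0
  if (!any(defined)) stop("RFL undefined for every sample (suppress <= 0)")
  rfl <- ifelse(defined, drive / suppress, NA_real_)
  n_undef <- sum(!defined)
  if (n_undef > 0L) {
    message(n_undef, " of ", length(drive),
            " samples have undefined RFL (suppress activity <= 0); excluded")
  }
  structure(
    data.frame(sample = samples, drive = as.numeric(drive),
               suppress = as.numeric(suppress), rfl = rfl,
               group = NA_character_, stringsAsFactors = FALSE),
    class = c("activity_table", "data.frame")
  )
}

#' Validate an RFL table against its component activities
#'
#' A well-behaved RFL should rise with drive activity and fall with suppress
#' activity. A cohort "passes" when the Pearson correlation of RFL with drive
#' exceeds +0.2 and with suppress is below -0.2 — cohorts violating either
#' bound are not suitable for RFL-based stratification (the mirror of the
#' exclusion rule applied to LUSC/PAAD/THCA-like cohorts).
#'
#' @param table an `activity_table` from [compute_rfl()].
#' @param min_abs_r the |0.2| bound on both component correlations.
#' @return a list with `r_drive`, `p_drive`, `r_suppress`, `p_suppress`,
#'   `n` (defined samples used) and logical `pass`; correlations that are
#'   undefined (constant component) yield `pass = FALSE` with NA entries.
#' @export
validate_rfl <- function(table, min_abs_r = 0.2) {
  stopifnot(inherits(table, "activity_table"))
  ok <- !is.na(table$rfl)
  if (sum(ok) < 3L) stop("need at least 3 samples with defined RFL")
  r_one <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(list(estimate = NA_real_, p.value = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  cd <- r_one(table$rfl[ok], table$drive[ok])
  cs <- r_one(table$rfl[ok], table$suppress[ok])
  pass <- !is.na(cd$estimate) && !is.na(cs$estimate) &&
    cd$estimate > min_abs_r && cs$estimate < -min_abs_r
  list(r_drive = cd$estimate, p_drive = cd$p.value,
       r_suppress = cs$estimate, p_suppress = cs$p.value,
       n = sum(ok), pass = pass)
}

#' Assign high/low RFL group labels at a cutoff
#'
#' Samples with RFL strictly greater than the cutoff are labelled "high",
#' the rest "low" (boundary samples go low). The cutoff must lie strictly
#' inside the observed range of defined RFL values so both groups are
#' non-empty.
#'
#' @param rfl numeric RFL vector (NA = undefined, left unlabelled).
#' @param cutoff the stratification threshold.
#' @return character vector of "high"/"low" labels (NA where rfl is NA).
#' @export
assign_groups <- function(rfl, cutoff) {
  ok <- !is.na(rfl)
  if (!any(ok)) stop("no defined RFL values")
  rng <- range(rfl[ok])
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff <= rng[1] || cutoff >= rng[2]) {
    stop("cutoff ", format(cutoff), " is not strictly inside the observed RFL range [",
         format(rng[1]), ", ", format(rng[2]), "]")
  }
  ifelse(ok, ifelse(rfl > cutoff, "high", "low"), NA_character_)
}

#' Pseudobulk aggregation of single-cell expression
#'
#' The per-patient pseudobulk profile is the arithmetic mean, gene by gene,
#' of the expression of that patient's cells, on the values exactly as
#' provided (no re-normalization).
#'
#' @param cell_matrix numeric cells x genes matrix with cell row names and
#'   gene column names.
#' @param cell_to_patient named character vector (or 2-column data.frame
#'   `cell`, `patient`) mapping every cell to a patient.
#' @return numeric genes x patients matrix; patients ordered by first
#'   appearance of their cells.
#' @export
pseudobulk <- function(cell_matrix, cell_to_patient) {
  stopifnot(is.matrix(cell_matrix), is.numeric(cell_matrix))
  if (is.null(rownames(cell_matrix))) stop("cell matrix must have cell row names")
  if (is.data.frame(cell_to_patient)) {
    map <- stats::setNames(as.character(cell_to_patient[[2]]),
                           as.character(cell_to_patient[[1]]))
  } else {
    map <- cell_to_patient
  }
  cells <- rownames(cell_matrix)
  missing <- setdiff(cells, names(map))
  if (length(missing) > 0L) {
    stop("unmapped cells: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  }
  patient <- map[cells]
  patients <- unique(patient)
  sums <- rowsum(cell_matrix, group = factor(patient, levels = patients))
  counts <- as.vector(table(factor(patient, levels = patients)))
  t(sums / counts)
}

#' Correlate RFL with per-sample numeric features
#'
#' Pearson correlation of RFL against each feature column (e.g. immune
#' infiltration, tumor purity, checkpoint expression), with two-sided
#' P-values from the t distribution with n - 2 degrees of freedom.
#'
#' @param rfl numeric RFL vector.
#' @param features data.frame (or matrix) of named per-sample numeric columns
#'   aligned with `rfl`.
#' @return data.frame with columns `feature`, `n`, `r`, `p`; constant
#'   features (or fewer than 3 complete pairs) give NA with a warning.
#' @export
correlate_rfl_with_features <- function(rfl, features) {
  features <- as.data.frame(features)
  if (nrow(features) != length(rfl)) stop("features not aligned with rfl")
  res <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    ok <- !is.na(rfl) & !is.na(x)
    n <- sum(ok)
    if (n < 3L) {
      warning("feature '", nm, "': fewer than 3 complete pairs")
      return(data.frame(feature = nm, n = n, r = NA_real_, p = NA_real_))
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(rfl[ok]) == 0) {
      warning("feature '", nm, "': constant input, correlation undefined")
      return(data.frame(feature = nm, n = n, r = NA_real_, p = NA_real_))
    }
    r <- stats::cor(rfl[ok], x[ok])
    p <- pearson_p(r, n)
    data.frame(feature = nm, n = n, r = r, p = p)
  })
  do.call(rbind, res)
}

#' Two-sided Pearson P-value from r and n via the t transform
#' @keywords internal
pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  if (abs(r) == 1) return(0)
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
}
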