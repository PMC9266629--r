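#' Read and validate a pipeline configuration file
#'
#' YAML key-value config. Common fields: `mode` ("synthetic-demo" or
#' "real-data"), `out_dir`, `seed`, `min_cohorts`, nested `ssgsea`
#' (`alpha`, `normalize`), `screen` (`threshold_r`, `threshold_p`), `scan`
#' (`lo`, `hi`), `max_risk_genes`. Synthetic-demo mode adds `n_cohorts` and
#' an optional `sim` block of [sim_params()] overrides; real-data mode adds
#' `gmt` (path; first set = drivers, second = suppressors, unless
#' `driver_set`/`suppressor_set` name them), optional `whitelist`, and a
#' `cohorts` list of `{name, expression, clinical}` path entries.
#'
#' @param path YAML config path.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a config list (as from [yaml::read_yaml()]).
#' @export
validate_pipeline_config <- function(cfg) {
  need <- function(field) {
    if (is.null(cfg[[field]])) stop("config field '", field, "' is missing")
    cfg[[field]]
  }
  mode <- need("mode")
  if (!mode %in% c("synthetic-demo", "real-data")) {
    stop("config field 'mode' must be 'synthetic-demo' or 'real-data'")
  }
  need("out_dir")
  cfg$seed <- as.integer(if (is.null(cfg$seed)) 1L else cfg$seed)
  if (is.na(cfg$seed)) stop("config field 'seed' is not an integer")
  cfg$min_cohorts <- if (is.null(cfg$min_cohorts)) 7L else as.integer(cfg$min_cohorts)
  cfg$max_risk_genes <- if (is.null(cfg$max_risk_genes)) 25L else
    as.integer(cfg$max_risk_genes)
  sc <- cfg$scan
  cfg$scan <- list(lo = if (is.null(sc$lo)) 0.10 else sc$lo,
                   hi = if (is.null(sc$hi)) 0.90 else sc$hi)
  if (!(cfg$scan$lo > 0 && cfg$scan$lo < cfg$scan$hi && cfg$scan$hi < 1)) {
    stop("config field 'scan' must satisfy 0 < lo < hi < 1")
  }
  sg <- cfg$ssgsea
  cfg$ssgsea <- ssgsea_params(
    alpha = if (is.null(sg$alpha)) 0.25 else sg$alpha,
    normalize = isTRUE(sg$normalize)
  )
  sr <- cfg$screen
  cfg$screen <- list(
    threshold_r = if (is.null(sr$threshold_r)) 0.3 else sr$threshold_r,
    threshold_p = if (is.null(sr$threshold_p)) 0.05 else sr$threshold_p
  )
  if (mode == "synthetic-demo") {
    cfg$n_cohorts <- if (is.null(cfg$n_cohorts)) 9L else as.integer(cfg$n_cohorts)
    if (cfg$n_cohorts < 1) stop("config field 'n_cohorts' must be >= 1")
  } else {
    need("gmt")
    if (!file.exists(cfg$gmt)) stop("GMT path does not exist: ", cfg$gmt)
    cohorts <- need("cohorts")
    for (co in cohorts) {
      for (field in c("name", "expression", "clinical")) {
        if (is.null(co[[field]])) {
          stop("config field 'cohorts' entry lacks '", field, "'")
        }
      }
      for (field in c("expression", "clinical")) {
        if (!file.exists(co[[field]])) {
          stop("cohort '", co$name, "': path does not exist: ", co[[field]])
        }
      }
    }
    if (!is.null(cfg$whitelist) && !file.exists(cfg$whitelist)) {
      stop("whitelist path does not exist: ", cfg$whitelist)
    }
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full RFL analysis pipeline
#'
#' Orchestrates, per cohort: ssGSEA activity scoring, RFL computation and
#' validation, the minimum-P survival cutoff scan with Kaplan-Meier tables,
#' and the RFL-correlated gene screen. Cohorts are then merged for the
#' Jaccard overlap matrices, recurrence selection (skipped with a logged
#' notice when fewer than `min_cohorts` cohorts are available), and a
#' per-cohort multivariate Cox risk score over the recurrent genes
#' (signature genes excluded; capped at `max_risk_genes` by recurrence
#' support). Every output is TSV; a manifest and a plain-text run log are
#' written last. Reruns with the same config are byte-identical.
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()]) or a
#'   path to a YAML config file.
#' @return invisibly, a list with `out_dir`, `manifest`, `log`,
#'   `recurrence`, and `risk_summary`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- validate_pipeline_config(config)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) {
    log_lines[[length(log_lines) + 1L]] <<- paste0("INFO ", ...)
  }
  written <- character(0)
  emit <- function(df, rel) {
    p <- file.path(out, rel)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    write_tsv(df, p)
    written <<- c(written, rel)
    p
  }
  log_add("ferroscore ", as.character(utils::packageVersion("ferroscore")),
          " | mode=", config$mode, " | seed=", config$seed)
  log_add("config: alpha=", config$ssgsea$alpha,
          " normalize=", config$ssgsea$normalize,
          " screen_r=", config$screen$threshold_r,
          " screen_p=", config$screen$threshold_p,
          " scan=[", config$scan$lo, ",", config$scan$hi, "]",
          " min_cohorts=", config$min_cohorts)

  cohorts <- load_pipeline_cohorts(config, log_add)
  pair <- cohorts$pair
  log_add("gene-set pair: ", length(pair$drivers$genes), " drivers, ",
          length(pair$suppressors$genes), " suppressors; excluded overlap=",
          length(pair$excluded_overlap), " noncoding=",
          length(pair$excluded_noncoding))

  selections <- list()
  screen_list <- list()
  scan_rows <- list()
  for (co in cohorts$data) {
    nm <- co$name
    log_add("[", nm, "] ", nrow(co$expr), " genes x ", ncol(co$expr), " samples")
    scores <- score_matrix(co$expr, list(pair$drivers, pair$suppressors),
                           config$ssgsea)
    act <- suppressMessages(compute_rfl(scores["drivers", ], scores["suppressors", ]))
    n_undef <- sum(is.na(act$rfl))
    log_add("[", nm, "] undefined RFL: ", n_undef, " of ", nrow(act), " samples")
    val <- validate_rfl(act)
    log_add("[", nm, "] validation: r(rfl,drive)=", round(val$r_drive, 3),
            " r(rfl,suppress)=", round(val$r_suppress, 3),
            " pass=", val$pass)
    clin <- co$clinical[match(act$sample, co$clinical$sample), ]
    if (val$pass) {
      scan <- scan_cutoff(act$rfl, clin$time, clin$event,
                          lo = config$scan$lo, hi = config$scan$hi)
      act$group <- scan$groups
      log_add("[", nm, "] scan: best_cutoff=", signif(scan$best_cutoff, 6),
              " best_p=", signif(scan$best_p, 6),
              " HR(high vs low)=", signif(scan$hazard_ratio, 6))
      emit(scan$scanned, file.path(nm, "scan.tsv"))
      for (g in c("high", "low")) {
        keep <- !is.na(act$group) & act$group == g
        emit(km_estimate(clin$time[keep], clin$event[keep]),
             file.path(nm, paste0("km_", g, ".tsv")))
      }
      scan_rows[[nm]] <- data.frame(cohort = nm, best_cutoff = scan$best_cutoff,
                                    best_p = scan$best_p,
                                    hazard_ratio = scan$hazard_ratio,
                                    hr_p = scan$hr_p)
    } else {
      log_add("[", nm, "] validation failed; survival stratification skipped")
    }
    emit(act, file.path(nm, "activity.tsv"))
    screen <- correlate_genes(co$expr, act$rfl, cohort = nm,
                              threshold_r = config$screen$threshold_r,
                              threshold_p = config$screen$threshold_p)
    emit(screen, file.path(nm, "screen.tsv"))
    sel <- select_correlated(screen, config$screen$threshold_r,
                             config$screen$threshold_p)
    log_add("[", nm, "] screen: ", length(sel$positive), " positive, ",
            length(sel$negative), " negative correlated genes")
    selections[[nm]] <- sel
    screen_list[[nm]] <- screen
    cohorts$data[[nm]]$activity <- act
    cohorts$data[[nm]]$clinical_aligned <- clin
  }
  if (length(scan_rows) > 0L) {
    emit(do.call(rbind, scan_rows), "scan_summary.tsv")
  }

  if (length(selections) >= 2L) {
    jp <- jaccard_matrix(lapply(selections, `[[`, "positive"))
    jn <- jaccard_matrix(lapply(selections, `[[`, "negative"))
    emit(data.frame(cohort = rownames(jp), jp, check.names = FALSE),
         "jaccard_positive.tsv")
    emit(data.frame(cohort = rownames(jn), jn, check.names = FALSE),
         "jaccard_negative.tsv")
  }

  recurrence <- NULL
  risk_rows <- list()
  if (length(selections) >= config$min_cohorts) {
    recurrence <- recurrent_genes(selections, min_cohorts = config$min_cohorts)
    emit(recurrence, "recurrence.tsv")
    sel_genes <- recurrence[recurrence$selected, , drop = FALSE]
    signature <- c(pair$drivers$genes, pair$suppressors$genes)
    sel_genes <- sel_genes[!sel_genes$gene %in% signature, , drop = FALSE]
    support <- pmax(sel_genes$n_positive, sel_genes$n_negative)
    ord <- order(-support, sel_genes$gene, method = "radix")
    risk_genes <- sel_genes$gene[utils::head(ord, config$max_risk_genes)]
    log_add("recurrence: ", sum(recurrence$selected), " genes selected (",
            length(risk_genes), " non-signature genes used for risk models)")
    if (length(risk_genes) > 0L) {
      for (nm in names(cohorts$data)) {
        co <- cohorts$data[[nm]]
        ok <- !is.na(co$activity$rfl)
        covs <- as.data.frame(t(co$expr[risk_genes, ok, drop = FALSE]))
        fit <- cox_fit(co$clinical_aligned$time[ok],
                       co$clinical_aligned$event[ok], covs)
        rs <- risk_score(fit)
        auc <- roc_auc(rs$rs, co$clinical_aligned$event[ok])
        lr <- if (length(unique(rs$group)) == 2L) {
          logrank_test(co$clinical_aligned$time[ok],
                       co$clinical_aligned$event[ok], rs$group)$p
        } else NA_real_
        risk_rows[[nm]] <- data.frame(cohort = nm, n_genes = length(risk_genes),
                                      auc = auc, logrank_p = lr,
                                      mean_rs = mean(rs$rs),
                                      n_high = sum(rs$group == "high"),
                                      n_low = sum(rs$group == "low"))
        log_add("[", nm, "] risk model: AUC=", round(auc, 4),
                " logrank_p=", signif(lr, 6))
      }
      emit(do.call(rbind, risk_rows), "risk_summary.tsv")
    }
  } else {
    log_add("recurrence stage skipped: ", length(selections), " cohorts < ",
            "min_cohorts=", config$min_cohorts)
  }

  manifest <- sort(written)
  writeLines(manifest, file.path(out, "manifest.txt"))
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(list(out_dir = out, manifest = manifest, log = log_lines,
                 recurrence = recurrence,
                 risk_summary = if (length(risk_rows)) do.call(rbind, risk_rows)))
}

# Load (or generate and round-trip through the TSV readers) the cohorts and
# the driver/suppressor pair for a pipeline run.
load_pipeline_cohorts <- function(config, log_add) {
  data <- list()
  if (config$mode == "synthetic-demo") {
    sim_over <- if (is.null(config$sim)) list() else config$sim
    in_dir <- file.path(config$out_dir, "inputs")
    dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
    pair <- NULL
    for (i in seq_len(config$n_cohorts)) {
      nm <- sprintf("cohort%02d", i)
      params <- do.call(sim_params, c(sim_over, list(seed = config$seed + i)))
      cohort <- generate_cohort(params)
      cdir <- file.path(in_dir, nm)
      dir.create(cdir, showWarnings = FALSE)
      write_expression_tsv(cohort$expr, file.path(cdir, "expression.tsv"))
      write_tsv(cohort$clinical, file.path(cdir, "clinical.tsv"))
      if (is.null(pair)) {
        write_gmt(list(cohort$pair$drivers, cohort$pair$suppressors),
                  file.path(in_dir, "signatures.gmt"))
        sets <- read_gmt(file.path(in_dir, "signatures.gmt"))
        pair <- build_pair(sets[[1]], sets[[2]])
      }
      data[[nm]] <- list(
        name = nm,
        expr = read_expression_tsv(file.path(cdir, "expression.tsv")),
        clinical = read_clinical_tsv(file.path(cdir, "clinical.tsv"))
      )
      log_add("generated ", nm, " (sim seed ", params$seed, ")")
    }
  } else {
    sets <- read_gmt(config$gmt)
    drv <- if (!is.null(config$driver_set)) sets[[config$driver_set]] else sets[[1]]
    sup <- if (!is.null(config$suppressor_set)) sets[[config$suppressor_set]] else sets[[2]]
    if (is.null(drv) || is.null(sup)) stop("GMT does not contain the named driver/suppressor sets")
    wl <- if (!is.null(config$whitelist)) read_whitelist(config$whitelist)
    pair <- build_pair(drv, sup, whitelist = wl)
    for (co in config$cohorts) {
      data[[co$name]] <- list(
        name = co$name,
        expr = read_expression_tsv(co$expression),
        clinical = read_clinical_tsv(co$clinical)
      )
      log_add("loaded cohort ", co$name)
    }
  }
  list(data = data, pair = pair)
}
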