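#' Rank signal-positive terms
#'
#' Filters to rows flagged by the combined four-method criterion and
#' returns the top `n` by the chosen key: `"frequency"` (observed count
#' `a`) or `"ror"` (signal intensity). Ties are broken deterministically:
#' by descending ROR then ascending label under `"frequency"`, and by
#' descending count then ascending label under `"ror"`.
#'
#' @param estimates output of [signal_estimates()] (needs `is_signal`).
#' @param by ranking key.
#' @param n maximum number of rows returned.
#' @return the filtered, ordered data.frame.
#' @export
rank_signals <- function(estimates, by = c("frequency", "ror"), n = 30) {
  by <- match.arg(by)
  x <- estimates[which(estimates$is_signal), , drop = FALSE]
  if (nrow(x) == 0) return(x)
  ord <- if (by == "frequency") {
    order(-x$a, -x$ror, x$label)
  } else {
    order(-x$ror, -x$a, x$label)
  }
  out <- utils::head(x[ord, , drop = FALSE], n)
  rownames(out) <- NULL
  out
}

read_pt_soc_map <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("pt", "soc") %in% names(x)))
    return(x[, c("pt", "soc")])
  }
  m <- utils::read.csv(x, stringsAsFactors = FALSE)
  if (!all(c("pt", "soc") %in% names(m))) {
    stop("PT->SOC map must have columns 'pt' and 'soc'", call. = FALSE)
  }
  m[, c("pt", "soc")]
}

read_quarter_tables <- function(dir) {
  kinds <- c("DEMO", "DRUG", "REAC", "THER", "OUTC")
  out <- list()
  for (k in kinds) {
    files <- sort(list.files(dir, pattern = paste0("^", k, ".*\\.txt$"),
                             full.names = TRUE))
    if (length(files) == 0) {
      stop(sprintf("no %s*.txt files found in '%s'", k, dir), call. = FALSE)
    }
    out[[tolower(k)]] <- do.call(rbind, lapply(files, read_faers_table,
                                               table_kind = k))
  }
  out
}

#' Run the full signal-detection pipeline
#'
#' Orchestrates, from one configuration: optional simulation of a synthetic
#' corpus, ingestion of the FAERS-dialect quarterly files, deduplication,
#' primary-suspect selection, PT- and SOC-level contingency construction,
#' the four disproportionality statistics with the combined signal
#' criterion (MGPS prior fitted over all drug-event cells of the corpus),
#' ranked signal tables, Weibull time-to-onset analysis with the
#' sex-stratified Wilcoxon comparison, and the cohort descriptives. All
#' tabular outputs are written as CSV together with a `manifest.json`
#' recording the seed and every attrition count, so any number in the
#' bundle is reproducible from the configuration alone; rerunning with the
#' same configuration gives byte-identical files. A failure in any stage
#' aborts with the stage name and removes partial outputs.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   `output_dir` (required); either `input_dir` holding `DEMO*.txt` etc.
#'   or `simulate` (a list of [synthetic_config()] arguments);
#'   `drug_patterns` (character, default `"osilodrostat"`); `pt_to_soc`
#'   (data.frame or CSV path; defaults to the simulated vocabulary);
#'   `min_cases`, `ic_variant`, `yates`, `zero_day_value`, `top_n`, `seed`.
#' @return invisibly, the report bundle: list with `manifest`, `cases`,
#'   `descriptives`, `soc_table`, `pt_estimates`, `top_by_frequency`,
#'   `top_by_ror`, `tto` (fit, bins, by-sex comparison, exclusions) and
#'   `prior`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configurations requires the 'yaml' package",
           call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$output_dir)) stop("config$output_dir is required", call. = FALSE)
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(df, file) {
    p <- file.path(out_dir, file)
    data.table::fwrite(df, p, eol = "\n")
    written <<- c(written, p)
    p
  }

  seed <- config$seed %||% 1L
  sim <- NULL
  input_dir <- config$input_dir
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      args <- config$simulate
      args$seed <- args$seed %||% seed
      sc <- do.call(synthetic_config, args)
      ds <- generate_faers_dataset(sc)
      input_dir <- input_dir %||% file.path(out_dir, "input")
      write_faers_dataset(ds, input_dir)
      ds
    })
    input_dir <- input_dir %||% file.path(out_dir, "input")
  }
  if (is.null(input_dir)) {
    stop("config must provide either 'input_dir' or 'simulate'", call. = FALSE)
  }

  raw <- stage("ingest", read_quarter_tables(input_dir))

  cases_all <- stage("deduplicate", {
    deduplicate_cases(as_case_reports(raw$demo, raw$outc))
  })
  n_versions <- nrow(raw$demo)
  n_cases <- nrow(cases_all)

  patterns <- config$drug_patterns %||% "osilodrostat"
  index_ids <- stage("primary-suspect selection", {
    ids <- as.numeric(select_primary_suspect(raw$drug, patterns))
    intersect(ids, cases_all$primaryid)
  })
  if (length(index_ids) == 0) {
    stop("pipeline stage 'primary-suspect selection' failed: no reports match the drug patterns",
         call. = FALSE)
  }
  cases_index <- cases_all[cases_all$primaryid %in% index_ids, , drop = FALSE]

  events <- stage("contingency", {
    ev <- data.frame(primaryid = as.numeric(raw$reac$primaryid),
                     pt = raw$reac$pt, stringsAsFactors = FALSE)
    unique(ev[ev$primaryid %in% cases_all$primaryid, ])
  })
  pt_cells <- stage("contingency", build_pt_tables(events, index_ids))

  map <- stage("contingency", {
    if (!is.null(config$pt_to_soc)) read_pt_soc_map(config$pt_to_soc)
    else if (!is.null(sim)) sim$config$vocabulary
    else stop("a PT->SOC map is required when not simulating")
  })
  soc_cells <- stage("contingency", aggregate_soc(pt_cells, map))

  prior <- stage("mgps prior", {
    ps_rows <- raw$drug[toupper(trimws(raw$drug$role_cod)) == "PS", ]
    rd <- data.frame(primaryid = as.numeric(ps_rows$primaryid),
                     drug = toupper(ps_rows$drugname), stringsAsFactors = FALSE)
    rd <- rd[rd$primaryid %in% cases_all$primaryid, ]
    de_cells <- build_drug_event_cells(rd, events)
    fit_mgps_prior(de_cells)
  })

  min_cases <- config$min_cases %||% 3
  ic_variant <- config$ic_variant %||% "noren"
  yates <- config$yates %||% TRUE
  pt_est <- stage("signals", {
    signal_estimates(pt_cells, prior = prior, min_cases = min_cases,
                     ic_variant = ic_variant, yates = yates)
  })
  soc_est <- stage("signals", {
    signal_estimates(soc_cells, prior = prior, min_cases = min_cases,
                     ic_variant = ic_variant, yates = yates)
  })
  top_n <- config$top_n %||% 30
  top_freq <- rank_signals(pt_est, "frequency", top_n)
  top_ror <- rank_signals(pt_est, "ror", top_n)

  tto <- stage("time-to-onset", {
    ps_idx <- raw$drug[toupper(trimws(raw$drug$role_cod)) == "PS" &
                         as.numeric(raw$drug$primaryid) %in% index_ids, ]
    ther <- raw$ther
    if (!is.null(ther$dsg_drug_seq) && !is.null(ps_idx$drug_seq)) {
      key <- paste(as.numeric(ps_idx$primaryid), ps_idx$drug_seq)
      ther <- ther[paste(as.numeric(ther$primaryid), ther$dsg_drug_seq) %in% key, ]
    } else {
      ther <- ther[as.numeric(ther$primaryid) %in% index_ids, ]
    }
    lk <- link_onset(cases_index, ther,
                     zero_day_value = config$zero_day_value %||% 0.5)
    fit <- if (nrow(lk$onsets) >= 10) weibull_mle(lk$onsets$onset_days) else NULL
    dist <- if (nrow(lk$onsets) > 0) tto_distribution(lk$onsets$onset_days) else NULL
    by_sex <- tryCatch(
      compare_by_sex(lk$onsets$onset_days, lk$onsets$sex),
      error = function(e) NULL)
    list(onsets = lk$onsets, exclusions = lk$exclusions, fit = fit,
         dist = dist, by_sex = by_sex)
  })

  descr <- stage("descriptives", {
    summarize_cases(cases_index, outcomes = raw$outc)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    seed = seed,
    drug_patterns = patterns,
    counts = list(
      report_versions_read = n_versions,
      unique_cases = n_cases,
      duplicates_removed = n_versions - n_cases,
      index_cases = length(index_ids),
      index_events = sum(pt_cells$a),
      total_events = nrow(events),
      onset_records = nrow(tto$onsets),
      onset_excluded = as.list(tto$exclusions),
      cells_below_min_cases = sum(pt_cells$a < min_cases)
    ),
    options = list(min_cases = min_cases, ic_variant = ic_variant,
                   yates = yates, top_n = top_n)
  )

  stage("report", {
    emit(data.frame(metric = c("report_versions_read", "unique_cases",
                               "duplicates_removed", "index_cases"),
                    value = c(n_versions, n_cases, n_versions - n_cases,
                              length(index_ids))),
         "dedup_tally.csv")
    emit(soc_est, "soc_table.csv")
    emit(pt_est, "pt_estimates.csv")
    if (nrow(top_freq)) emit(top_freq, "pt_signals_by_frequency.csv")
    if (nrow(top_ror)) emit(top_ror, "pt_signals_by_ror.csv")
    emit(descr$freq, "descriptives.csv")
    if (!is.null(tto$dist)) emit(tto$dist$bins, "tto_bins.csv")
    if (!is.null(tto$fit)) {
      f <- tto$fit
      emit(data.frame(n = f$n, median_days = f$median_days,
                      q1 = f$iqr_days[1], q3 = f$iqr_days[2],
                      scale = f$scale, scale_lo = f$scale_ci[1],
                      scale_hi = f$scale_ci[2], shape = f$shape,
                      shape_lo = f$shape_ci[1], shape_hi = f$shape_ci[2],
                      failure_type = f$failure_type),
           "tto_weibull.csv")
    }
    emit(data.frame(reason = names(tto$exclusions),
                    n = as.integer(tto$exclusions)),
         "tto_exclusions.csv")
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <<- c(written, mp)
  })

  ok <- TRUE
  invisible(list(manifest = manifest, cases = cases_index,
                 descriptives = descr, soc_table = soc_est,
                 pt_estimates = pt_est, top_by_frequency = top_freq,
                 top_by_ror = top_ror, tto = tto, prior = prior))
}
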