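#' Default synthetic MedDRA-like vocabulary
#'
#' A flat preferred-term (PT) to system-organ-class (SOC) map with synthetic
#' labels (`pt_001` ...). Real MedDRA is licensed and is never shipped; any
#' analysis of real FAERS extracts must supply its own two-column map.
#'
#' @param n_pt number of preferred terms.
#' @param n_soc number of system organ classes; PTs are assigned round-robin.
#' @return data.frame with columns `pt` and `soc`.
#' @export
default_vocabulary <- function(n_pt = 50, n_soc = 5) {
  data.frame(
    pt  = sprintf("pt_%03d", seq_len(n_pt)),
    soc = sprintf("soc_%02d", ((seq_len(n_pt) - 1L) %% n_soc) + 1L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic FAERS generator
#'
#' Defines the study conditions emulated by [generate_faers_dataset()]: the
#' number of unique cases, the duplicate-version rate, demographic
#' missingness, the event vocabulary with per-PT background reporting
#' probabilities, planted drug-event signals for the index drug, and the
#' sex-specific Weibull law of onset times.
#'
#' Defaults mirror the structure of a real single-drug FAERS cohort:
#' sex missing in 83% and age in 85% of reports, mean events per case about
#' 3.5, about 60% of reports serious, onset times Weibull with shape 0.73
#' (decreasing hazard) around a scale of 187 days, shifted between the
#' sexes.
#'
#' @param n_reports number of unique cases (distinct CASEIDs).
#' @param duplicate_fraction proportion of cases emitted as 2-3 versions
#'   sharing a CASEID but with strictly increasing FDA_DT and PRIMARYID,
#'   emulating FAERS resubmissions.
#' @param sex_missing_rate,age_missing_rate proportion of cases whose sex /
#'   age field is blanked in DEMO (the ledger always keeps the truth).
#' @param vocabulary data.frame with columns `pt`, `soc`
#'   (see [default_vocabulary()]).
#' @param background_event_rates named per-PT marginal reporting
#'   probabilities, each in (0, 1); names must match `vocabulary$pt`. The
#'   default decays as 1/sqrt(rank) and is normalised so the expected number
#'   of events per case is 3.5.
#' @param planted_signals named numeric vector: for each named PT, the
#'   relative reporting rate lambda > 0 of that PT among index-drug cases
#'   (reporting probability becomes `lambda * background rate`, which must
#'   stay below 1). All other PTs occur independently of drug.
#' @param index_fraction proportion of cases whose primary-suspect drug is
#'   the index drug (`OSILODROSTAT` by default).
#' @param index_drug_name primary-suspect drug name for index cases.
#' @param n_background_drugs number of distinct comparator drug names.
#' @param female_fraction probability a case is truly female.
#' @param tto_scale_by_sex,tto_shape_by_sex named vectors
#'   (`female`, `male`) of Weibull scale (days) and shape for the true
#'   time-to-onset.
#' @param partial_start_date_fraction proportion of therapy start dates
#'   truncated to `YYYYMM` or `YYYY`, exercising partial-date exclusion.
#' @param event_date_missing_rate proportion of cases with a blank DEMO
#'   event date (FAERS onset information is mostly incomplete).
#' @param serious_rate proportion of cases carrying at least one OUTC row.
#' @param start_window character vector of two `YYYYMMDD` dates bounding the
#'   therapy start dates.
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical output tables.
#' @return validated object of class `faers_sim_config`.
#' @seealso [generate_faers_dataset()], [write_faers_dataset()]
#' @export
synthetic_config <- function(n_reports = 2000,
                             duplicate_fraction = 0.10,
                             sex_missing_rate = 0.83,
                             age_missing_rate = 0.85,
                             vocabulary = default_vocabulary(),
                             background_event_rates = NULL,
                             planted_signals = numeric(0),
                             index_fraction = 0.10,
                             index_drug_name = "OSILODROSTAT",
                             n_background_drugs = 20,
                             female_fraction = 0.735,
                             tto_scale_by_sex = c(female = 234.0, male = 140.4),
                             tto_shape_by_sex = c(female = 0.73, male = 0.73),
                             partial_start_date_fraction = 0.10,
                             event_date_missing_rate = 0.35,
                             serious_rate = 0.5983,
                             start_window = c("20200101", "20240630"),
                             seed = 1L) {
  if (!is.numeric(n_reports) || length(n_reports) != 1 || is.na(n_reports) ||
      n_reports < 1 || n_reports != floor(n_reports)) {
    stop_field("n_reports", "must be a positive integer")
  }
  check_prob(duplicate_fraction, "duplicate_fraction")
  check_prob(sex_missing_rate, "sex_missing_rate")
  check_prob(age_missing_rate, "age_missing_rate")
  check_prob(index_fraction, "index_fraction")
  check_prob(female_fraction, "female_fraction")
  check_prob(partial_start_date_fraction, "partial_start_date_fraction")
  check_prob(event_date_missing_rate, "event_date_missing_rate")
  check_prob(serious_rate, "serious_rate")
  if (!is.data.frame(vocabulary) ||
      !all(c("pt", "soc") %in% names(vocabulary)) ||
      anyDuplicated(vocabulary$pt)) {
    stop_field("vocabulary", "must be a data.frame with unique 'pt' and a 'soc' column")
  }
  if (is.null(background_event_rates)) {
    w <- 1 / sqrt(seq_len(nrow(vocabulary)))
    background_event_rates <- stats::setNames(3.5 * w / sum(w), vocabulary$pt)
    if (any(background_event_rates >= 1)) {
      background_event_rates <- pmin(background_event_rates, 0.95)
    }
  }
  check_prob(background_event_rates, "background_event_rates", open = TRUE)
  if (!setequal(names(background_event_rates), vocabulary$pt)) {
    stop_field("background_event_rates", "names must match vocabulary$pt")
  }
  background_event_rates <- background_event_rates[vocabulary$pt]
  if (length(planted_signals)) {
    check_positive(planted_signals, "planted_signals")
    if (is.null(names(planted_signals)) ||
        !all(names(planted_signals) %in% vocabulary$pt)) {
      stop_field("planted_signals", "must be named by PTs present in the vocabulary")
    }
    idx_rate <- planted_signals * background_event_rates[names(planted_signals)]
    if (any(idx_rate >= 1)) {
      stop_field("planted_signals",
                 "lambda times background rate must stay below 1 for every planted PT")
    }
  }
  for (nm in c("tto_scale_by_sex", "tto_shape_by_sex")) {
    v <- get(nm)
    if (!is.numeric(v) || !all(c("female", "male") %in% names(v)) ||
        any(v <= 0) || anyNA(v)) {
      stop_field(nm, "must be a positive named vector with entries 'female' and 'male'")
    }
  }
  if (!is.numeric(n_background_drugs) || n_background_drugs < 1) {
    stop_field("n_background_drugs", "must be a positive integer")
  }
  if (length(start_window) != 2 || anyNA(as.Date(start_window, "%Y%m%d"))) {
    stop_field("start_window", "must be two valid YYYYMMDD dates")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_field("seed", "must be a single integer")
  }
  structure(list(
    n_reports = as.integer(n_reports),
    duplicate_fraction = duplicate_fraction,
    sex_missing_rate = sex_missing_rate,
    age_missing_rate = age_missing_rate,
    vocabulary = vocabulary,
    background_event_rates = background_event_rates,
    planted_signals = planted_signals,
    index_fraction = index_fraction,
    index_drug_name = index_drug_name,
    n_background_drugs = as.integer(n_background_drugs),
    female_fraction = female_fraction,
    tto_scale_by_sex = tto_scale_by_sex,
    tto_shape_by_sex = tto_shape_by_sex,
    partial_start_date_fraction = partial_start_date_fraction,
    event_date_missing_rate = event_date_missing_rate,
    serious_rate = serious_rate,
    start_window = start_window,
    seed = as.integer(seed)
  ), class = "faers_sim_config")
}

#' Generate a synthetic FAERS-like dataset with known ground truth
#'
#' Simulates a spontaneous-report corpus in the FAERS quarterly-file dialect:
#' DEMO, DRUG, REAC, THER and OUTC tables plus a ground-truth ledger keyed by
#' PRIMARYID. Index-drug cases carry the primary-suspect (`PS`) role code;
#' planted-signal PTs are reported `lambda` times more often among index
#' cases while every other PT occurs independently of the drug, so the
#' generative relative reporting rate of each planted PT is known exactly.
#' Duplicate case versions differ only in FDA_DT and PRIMARYID (both
#' strictly increasing within a CASEID), making the keep-latest
#' deduplication rule observable.
#'
#' @param config a `faers_sim_config` from [synthetic_config()].
#' @return object of class `faers_dataset`: a list with elements
#'   `tables` (named list of data.frames `demo`, `drug`, `reac`, `ther`,
#'   `outc`), `ledger` (one row per PRIMARYID with the true sex, age, onset
#'   time in days, duplicate-group size and index-drug membership),
#'   `signals` (the planted PTs with their target lambda) and `config`.
#' @export
generate_faers_dataset <- function(config) {
  if (!inherits(config, "faers_sim_config")) {
    stop("config must be created by synthetic_config()", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_reports
  voc <- config$vocabulary
  rates <- config$background_event_rates
  K <- nrow(voc)

  caseid <- 100000000L + seq_len(n)
  n_index <- round(config$index_fraction * n)
  is_index <- rep(FALSE, n)
  if (n_index > 0) is_index[sample.int(n, n_index)] <- TRUE

  sex_true <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
  # ages consistent with an adult endocrine cohort; resample tails, then clamp
  age_true <- round(stats::rnorm(n, 49.66, 16.23))
  for (i in 1:5) {
    bad <- age_true < 16 | age_true > 87
    if (!any(bad)) break
    age_true[bad] <- round(stats::rnorm(sum(bad), 49.66, 16.23))
  }
  age_true <- pmin(pmax(age_true, 16), 87)

  drugname <- ifelse(is_index, config$index_drug_name,
                     sprintf("DRUG_%02d",
                             sample.int(config$n_background_drugs, n, replace = TRUE)))

  # event occurrence: independent Bernoulli per (case, PT); planted PTs get
  # probability lambda * rate among index cases only
  prob <- matrix(rates, nrow = n, ncol = K, byrow = TRUE)
  if (length(config$planted_signals)) {
    for (pt in names(config$planted_signals)) {
      j <- match(pt, voc$pt)
      prob[is_index, j] <- config$planted_signals[[pt]] * rates[[pt]]
    }
  }
  occ <- matrix(stats::runif(n * K) < prob, n, K)
  none <- which(rowSums(occ) == 0L)
  if (length(none)) {
    forced <- sample.int(K, length(none), replace = TRUE, prob = rates)
    occ[cbind(none, forced)] <- TRUE
  }

  # true onset times: sex-specific Weibull, in days (continuous truth)
  scl <- unname(config$tto_scale_by_sex[ifelse(sex_true == "F", "female", "male")])
  shp <- unname(config$tto_shape_by_sex[ifelse(sex_true == "F", "female", "male")])
  onset_true <- stats::rweibull(n, shape = shp, scale = scl)

  win <- as.Date(config$start_window, "%Y%m%d")
  start_date <- win[1] + sample.int(as.integer(win[2] - win[1]) + 1L, n,
                                    replace = TRUE) - 1L
  event_date <- start_date + round(onset_true)
  fda_base <- event_date + sample(3:60, n, replace = TRUE)

  event_missing <- stats::runif(n) < config$event_date_missing_rate
  start_partial <- stats::runif(n) < config$partial_start_date_fraction
  start_raw <- format_faers_date(start_date)
  trunc6 <- start_partial & stats::runif(n) < 0.5
  start_raw[start_partial] <- substr(start_raw[start_partial], 1, 4)
  start_raw[trunc6] <- paste0(start_raw[trunc6],
                              substr(format_faers_date(start_date[trunc6]), 5, 6))
  event_raw <- format_faers_date(event_date)
  event_raw[event_missing] <- ""

  sex_masked <- stats::runif(n) < config$sex_missing_rate
  age_masked <- stats::runif(n) < config$age_missing_rate
  occp <- sample(c("CN", "MD", "PH"), n, replace = TRUE,
                 prob = c(0.7829, 0.1447, 0.0724))
  ctries <- c("US", "JP", "FR", "CO", "PL", "DE", "GB", "CA")
  cwts <- c(0.8609, 0.0436, 0.0353, 0.0148, 0.0111, 0.0131, 0.0131, 0.0081)
  occr_country <- sample(ctries, n, replace = TRUE, prob = cwts)
  rept_country <- ifelse(stats::runif(n) < 0.97, occr_country,
                         sample(ctries, n, replace = TRUE, prob = cwts))

  serious <- stats::runif(n) < config$serious_rate
  # outcome codes conditional on seriousness (marginals of a real cohort)
  outc_p <- c(OT = 0.3219, HO = 0.2959, DE = 0.0993, LT = 0.0139, DS = 0.0028) /
    config$serious_rate
  outc_draw <- matrix(stats::runif(n * 5) < rep(outc_p, each = n), n, 5)
  outc_draw[!serious, ] <- FALSE
  fix <- serious & rowSums(outc_draw) == 0L
  outc_draw[fix, 1] <- TRUE

  # duplicate versions: same case content, new FDA_DT and PRIMARYID
  n_dup <- round(config$duplicate_fraction * n)
  n_versions <- rep(1L, n)
  if (n_dup > 0) n_versions[sample.int(n, n_dup)] <- sample(2:3, n_dup, replace = TRUE)
  case_row <- rep(seq_len(n), n_versions)
  version <- sequence(n_versions)
  primaryid <- caseid[case_row] * 100 + version
  fda_step <- sample(5:90, length(case_row), replace = TRUE)
  fda_date <- fda_base[case_row] + as.integer(
    stats::ave(fda_step, case_row, FUN = cumsum) - fda_step)

  sex_obs <- ifelse(sex_masked, "", sex_true)
  age_obs <- ifelse(age_masked, "", as.character(age_true))

  demo <- data.frame(
    primaryid = format(primaryid, scientific = FALSE, trim = TRUE),
    caseid = caseid[case_row],
    caseversion = version,
    event_dt = event_raw[case_row],
    fda_dt = format_faers_date(fda_date),
    age = age_obs[case_row],
    age_cod = ifelse(age_obs[case_row] == "", "", "YR"),
    sex = sex_obs[case_row],
    occp_cod = occp[case_row],
    reporter_country = rept_country[case_row],
    occr_country = occr_country[case_row],
    stringsAsFactors = FALSE
  )

  # DRUG: primary suspect row; some cases also carry a concomitant drug,
  # occasionally the index drug itself in a non-suspect role
  conc <- stats::runif(n) < 0.30
  conc_name <- sprintf("DRUG_%02d",
                       sample.int(config$n_background_drugs, n, replace = TRUE))
  conc_name[!is_index & stats::runif(n) < 0.02] <- config$index_drug_name
  drug_ps <- data.frame(
    primaryid = demo$primaryid, caseid = demo$caseid, drug_seq = 1L,
    role_cod = "PS", drugname = drugname[case_row],
    prod_ai = drugname[case_row], stringsAsFactors = FALSE
  )
  conc_rows <- conc[case_row]
  drug_c <- data.frame(
    primaryid = demo$primaryid[conc_rows], caseid = demo$caseid[conc_rows],
    drug_seq = 2L, role_cod = "C", drugname = conc_name[case_row][conc_rows],
    prod_ai = conc_name[case_row][conc_rows], stringsAsFactors = FALSE
  )
  drug <- rbind(drug_ps, drug_c)
  drug <- drug[order(as.numeric(drug$primaryid), drug$drug_seq), ]

  pair <- which(occ, arr.ind = TRUE)
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
  ver_of_case <- split(seq_along(case_row), case_row)
  reac_ver <- unlist(ver_of_case[pair[, 1]], use.names = FALSE)
  reac_pt_case <- rep(pair[, 2], vapply(ver_of_case[pair[, 1]], length, 1L))
  reac <- data.frame(
    primaryid = demo$primaryid[reac_ver],
    caseid = demo$caseid[reac_ver],
    pt = voc$pt[reac_pt_case],
    stringsAsFactors = FALSE
  )
  reac <- reac[order(as.numeric(reac$primaryid), reac$pt), ]

  ther <- data.frame(
    primaryid = demo$primaryid, caseid = demo$caseid,
    dsg_drug_seq = 1L, start_dt = start_raw[case_row],
    end_dt = "", stringsAsFactors = FALSE
  )

  outc_codes <- colnames(outc_draw) <- names(outc_p)
  op <- which(outc_draw, arr.ind = TRUE)
  outc_ver <- unlist(ver_of_case[op[, 1]], use.names = FALSE)
  outc_code_case <- rep(op[, 2], vapply(ver_of_case[op[, 1]], length, 1L))
  outc <- data.frame(
    primaryid = demo$primaryid[outc_ver],
    caseid = demo$caseid[outc_ver],
    outc_cod = outc_codes[outc_code_case],
    stringsAsFactors = FALSE
  )
  outc <- outc[order(as.numeric(outc$primaryid), outc$outc_cod), ]

  ledger <- data.frame(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    caseversion = version,
    n_versions = n_versions[case_row],
    is_final = version == n_versions[case_row],
    is_index = is_index[case_row],
    drugname = drugname[case_row],
    true_sex = sex_true[case_row],
    true_age = age_true[case_row],
    true_onset_days = onset_true[case_row],
    onset_days_dates = as.integer(event_date - start_date)[case_row],
    event_dt_complete = !event_missing[case_row],
    start_dt_complete = !start_partial[case_row],
    serious = serious[case_row],
    stringsAsFactors = FALSE
  )

  signals <- if (length(config$planted_signals)) {
    data.frame(pt = names(config$planted_signals),
               lambda = unname(config$planted_signals),
               background_rate = unname(rates[names(config$planted_signals)]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pt = character(0), lambda = numeric(0),
               background_rate = numeric(0))
  }

  rownames(demo) <- rownames(drug) <- rownames(reac) <- rownames(ther) <-
    rownames(outc) <- rownames(ledger) <- NULL
  structure(list(
    tables = list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc),
    ledger = ledger, signals = signals, config = config
  ), class = "faers_dataset")
}

#' Write a synthetic dataset as FAERS quarterly ASCII files
#'
#' Emits `DEMOyyQq.txt`, `DRUGyyQq.txt`, `REACyyQq.txt`, `THERyyQq.txt` and
#' `OUTCyyQq.txt` in the `'$'`-delimited FAERS dialect (header row, empty
#' string for missing fields, LF line endings), plus `ledger.csv` and
#' `planted_signals.csv`. Output is byte-identical for identical input.
#'
#' @param dataset a `faers_dataset` from [generate_faers_dataset()].
#' @param dir output directory (created if needed).
#' @param quarter quarter tag used in the file names, e.g. `"24Q3"`.
#' @return invisibly, the named vector of file paths written.
#' @export
write_faers_dataset <- function(dataset, dir, quarter = "24Q3") {
  stopifnot(inherits(dataset, "faers_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kinds <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
             ther = "THER", outc = "OUTC")
  paths <- character(0)
  for (k in names(kinds)) {
    p <- file.path(dir, paste0(kinds[[k]], quarter, ".txt"))
    data.table::fwrite(dataset$tables[[k]], p, sep = "$", quote = FALSE,
                       eol = "\n", na = "")
    paths[kinds[[k]]] <- p
  }
  lp <- file.path(dir, "ledger.csv")
  data.table::fwrite(dataset$ledger, lp, eol = "\n")
  sp <- file.path(dir, "planted_signals.csv")
  data.table::fwrite(dataset$signals, sp, eol = "\n")
  paths[c("ledger", "signals")] <- c(lp, sp)
  invisible(paths)
}

#' @export
print.faers_dataset <- function(x, ...) {
  n_case <- length(unique(x$ledger$caseid))
  cat("Synthetic FAERS-like dataset\n")
  cat(sprintf("  %d report versions, %d unique cases (%d index-drug)\n",
              nrow(x$ledger), n_case, sum(x$ledger$is_index & x$ledger$is_final)))
  cat(sprintf("  %d REAC rows over %d PTs; %d planted signal(s)\n",
              nrow(x$tables$reac), nrow(x$config$vocabulary), nrow(x$signals)))
  invisible(x)
}
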