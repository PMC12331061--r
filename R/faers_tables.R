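#' Read a FAERS quarterly ASCII table
#'
#' FAERS quarterly extracts are `'$'`-delimited text files with a header
#' row. Fields are read as text (dates in particular are kept raw so that
#' partial `YYYY`/`YYYYMM` values survive); empty fields become empty
#' strings. The row count of the file is preserved.
#'
#' @param path path to the file.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`, `"OUTC"`.
#' @return data.frame of character columns.
#' @export
read_faers_table <- function(path,
                             table_kind = c("DEMO", "DRUG", "REAC", "THER", "OUTC")) {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    stop(sprintf("empty input: %s table file '%s' has no content", table_kind, path),
         call. = FALSE)
  }
  x <- data.table::fread(path, sep = "$", colClasses = "character",
                         header = TRUE, quote = "", na.strings = NULL,
                         data.table = FALSE)
  if (nrow(x) == 0 && ncol(x) <= 1) {
    stop(sprintf("empty input: %s table file '%s' has a header but no rows or is not '$'-delimited",
                 table_kind, path), call. = FALSE)
  }
  mandatory <- switch(table_kind,
    DEMO = c("primaryid", "caseid", "fda_dt"),
    DRUG = c("primaryid", "role_cod", "drugname"),
    REAC = c("primaryid", "pt"),
    THER = c("primaryid", "start_dt"),
    OUTC = c("primaryid", "outc_cod"))
  names(x) <- tolower(names(x))
  miss <- setdiff(mandatory, names(x))
  if (length(miss)) {
    stop(sprintf("%s table '%s' lacks mandatory column(s): %s",
                 table_kind, path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Convert a raw DEMO table (plus optional OUTC rows) to case reports
#'
#' Normalises the fields used downstream: numeric `primaryid`/`caseid`,
#' sortable numeric `fda_date`, the raw event date with its
#' complete/partial/missing status, sex and reporter recoded to readable
#' levels, age converted to years from the FAERS `age_cod` unit, and
#' seriousness derived from the presence of OUTC rows.
#'
#' @param demo data.frame from [read_faers_table()] with kind `"DEMO"`.
#' @param outc optional OUTC data.frame; when supplied, `serious` is `TRUE`
#'   for reports with at least one outcome row, otherwise `NA`.
#' @return data.frame of case reports (one row per report version).
#' @export
as_case_reports <- function(demo, outc = NULL) {
  ev <- parse_faers_date(demo$event_dt %||% rep("", nrow(demo)))
  sex_raw <- toupper(trimws(demo$sex %||% rep("", nrow(demo))))
  sex <- rep("unknown", nrow(demo))
  sex[sex_raw == "F"] <- "female"
  sex[sex_raw == "M"] <- "male"
  occp <- toupper(trimws(demo$occp_cod %||% rep("", nrow(demo))))
  reporter <- c(CN = "consumer", MD = "physician", PH = "pharmacist",
                OT = "other", LW = "other", HP = "physician")[occp]
  reporter[is.na(reporter)] <- "unknown"

  age_num <- suppressWarnings(as.numeric(demo$age %||% rep(NA, nrow(demo))))
  cod <- toupper(trimws(demo$age_cod %||% rep("", nrow(demo))))
  age_years <- age_num
  age_years[cod == "MON"] <- age_num[cod == "MON"] / 12
  age_years[cod == "WK"]  <- age_num[cod == "WK"] / 52.18
  age_years[cod == "DY"]  <- age_num[cod == "DY"] / 365.25
  age_years[cod == "DEC"] <- age_num[cod == "DEC"] * 10
  age_years[!is.na(age_years) & age_years < 0] <- NA

  serious <- rep(NA, nrow(demo))
  if (!is.null(outc)) serious <- demo$primaryid %in% unique(outc$primaryid)

  data.frame(
    primaryid = as.numeric(demo$primaryid),
    caseid = as.numeric(demo$caseid),
    fda_date = suppressWarnings(as.numeric(demo$fda_dt)),
    event_dt_raw = ev$raw,
    event_date = ev$date,
    event_dt_status = ev$status,
    sex = sex,
    age_years = age_years,
    reporter = reporter,
    occurrence_country = demo$occr_country %||% rep(NA_character_, nrow(demo)),
    reporting_country = demo$reporter_country %||% rep(NA_character_, nrow(demo)),
    serious = serious,
    stringsAsFactors = FALSE
  )
}

#' Deduplicate case versions by the FDA rule
#'
#' FAERS cases are resubmitted over time; all versions share a CASEID. For
#' each CASEID the version with the largest FDA_DT is retained, and among
#' versions tied on FDA_DT the one with the largest PRIMARYID — i.e. the
#' survivor maximises `(fda_date, primaryid)` lexicographically. Output is
#' ordered by ascending `caseid` and the operation is idempotent.
#'
#' @param cases data.frame with columns `caseid`, `fda_date`, `primaryid`
#'   (e.g. from [as_case_reports()]).
#' @return data.frame with exactly one row per distinct `caseid`.
#' @export
deduplicate_cases <- function(cases) {
  if (nrow(cases) == 0) return(cases)
  ord <- order(cases$caseid, cases$fda_date, cases$primaryid)
  x <- cases[ord, , drop = FALSE]
  keep <- !duplicated(x$caseid, fromLast = TRUE)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select reports where a target drug is the primary suspect
#'
#' A report qualifies when at least one DRUG row both names the drug
#' (case-insensitive substring match of any pattern against `drugname` or
#' `prod_ai`) and carries the primary-suspect role code `PS`. Rows naming
#' the drug in a concomitant or secondary role do not qualify.
#'
#' @param drug DRUG data.frame from [read_faers_table()].
#' @param name_patterns character vector of name fragments; must be
#'   non-empty.
#' @return character vector of qualifying `primaryid` values (unique).
#' @export
select_primary_suspect <- function(drug, name_patterns) {
  if (length(name_patterns) == 0 || all(!nzchar(name_patterns))) {
    stop("name_patterns must contain at least one non-empty pattern",
         call. = FALSE)
  }
  fields <- tolower(paste(drug$drugname %||% "",
                          drug$prod_ai %||% "", sep = "\r"))
  hit <- rep(FALSE, nrow(drug))
  for (p in tolower(name_patterns)) {
    if (nzchar(p)) hit <- hit | grepl(p, fields, fixed = TRUE)
  }
  role <- toupper(trimws(drug$role_cod %||% ""))
  unique(drug$primaryid[hit & role == "PS"])
}

#' Link therapy start dates to event dates and compute onset times
#'
#' Time to onset is the interval in whole days from the initiation of
#' therapy (THER start date) to the adverse-event occurrence date recorded
#' in DEMO. Reports with a partial or missing date on either side are
#' excluded and tallied, as are negative intervals; day-0 onsets are mapped
#' to `zero_day_value` (default half a day) so that the Weibull likelihood,
#' whose support is t > 0, is defined. When a report has several therapy
#' rows, the earliest complete start date is used (first exposure defines
#' time at risk).
#'
#' @param cases deduplicated case reports ([deduplicate_cases()]).
#' @param ther THER data.frame, pre-filtered to the drug of interest if the
#'   corpus records therapy lines for several drugs per report.
#' @param zero_day_value value substituted for zero-day onsets; set to 0 to
#'   keep them (and exclude them yourself before Weibull fitting).
#' @return list with `onsets` (data.frame `primaryid`, `onset_days`, `sex`)
#'   and `exclusions` (named integer vector: `missing_event_date`,
#'   `missing_start_date`, `negative`), whose total plus `nrow(onsets)`
#'   equals `nrow(cases)`.
#' @export
link_onset <- function(cases, ther, zero_day_value = 0.5) {
  st <- parse_faers_date(ther$start_dt)
  ok <- st$status == "complete"
  starts <- data.frame(primaryid = as.numeric(ther$primaryid[ok]),
                       start = st$date[ok])
  first <- if (nrow(starts)) {
    stats::aggregate(start ~ primaryid, data = starts, FUN = min)
  } else {
    data.frame(primaryid = numeric(0), start = as.Date(character(0)))
  }

  ev_status <- cases$event_dt_status
  ev_date <- cases$event_date
  if (is.null(ev_status)) {
    p <- parse_faers_date(cases$event_dt_raw %||% cases$event_dt)
    ev_status <- p$status
    ev_date <- p$date
  }
  start <- first$start[match(cases$primaryid, first$primaryid)]

  miss_event <- ev_status != "complete"
  miss_start <- !miss_event & is.na(start)
  onset <- as.numeric(ev_date - start)
  negative <- !miss_event & !miss_start & onset < 0
  keep <- !miss_event & !miss_start & !negative
  onset_days <- onset[keep]
  onset_days[onset_days == 0] <- zero_day_value

  sex <- if (!is.null(cases$sex)) cases$sex[keep] else rep("unknown", sum(keep))
  list(
    onsets = data.frame(primaryid = cases$primaryid[keep],
                        onset_days = onset_days, sex = sex,
                        stringsAsFactors = FALSE),
    exclusions = c(missing_event_date = sum(miss_event),
                   missing_start_date = sum(miss_start),
                   negative = sum(negative))
  )
}
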