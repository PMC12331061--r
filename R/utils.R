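#' Round half away from zero
#'
#' Decimal rounding with the "half-up" convention used in clinical tables
#' (0.125 -> 0.13 at 2 digits), as opposed to the IEEE round-half-even rule
#' of [base::round()]. Used for all reported percentages so that printed
#' frequency tables are reproducible digit-for-digit.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(12.615, 0.125, -0.125), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by one ulp before truncation so values like 4.55 that decimal
  # arithmetic stores just below the half-way point still round up
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

#' Parse FAERS 8-digit dates
#'
#' FAERS date fields are plain text: `YYYYMMDD` when complete, `YYYYMM` or
#' `YYYY` when the reporter supplied a partial date, empty when missing.
#' Partial dates are never imputed; they are flagged so that downstream
#' onset-time analyses can exclude and count them.
#'
#' @param x character (or numeric) vector of raw date fields.
#' @return a data.frame with columns `raw`, `date` (a [Date], `NA` unless the
#'   field held a valid complete date) and `status`
#'   (`"complete"`, `"partial"`, `"missing"`).
#' @export
parse_faers_date <- function(x) {
  raw <- trimws(as.character(x))
  raw[is.na(raw)] <- ""
  nc <- nchar(raw)
  status <- rep("missing", length(raw))
  status[nc %in% c(4L, 6L) & grepl("^[0-9]+$", raw)] <- "partial"
  is_full <- nc == 8L & grepl("^[0-9]{8}$", raw)
  date <- rep(as.Date(NA), length(raw))
  if (any(is_full)) {
    parsed <- as.Date(raw[is_full], format = "%Y%m%d")
    date[is_full] <- parsed
    status[is_full] <- ifelse(is.na(parsed), "partial", "complete")
  }
  # anything non-empty that is neither full nor partial-numeric is treated
  # as a malformed partial: retained as raw text, excluded from arithmetic
  status[nc > 0 & status == "missing"] <- ifelse(
    is_full[nc > 0 & status == "missing"], "complete", "partial")
  data.frame(raw = raw, date = date, status = status,
             stringsAsFactors = FALSE)
}

# format a Date back to FAERS YYYYMMDD text
format_faers_date <- function(d) format(d, "%Y%m%d")

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_prob <- function(x, field, open = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stop_field(field, "must be numeric, non-missing")
  if (open) {
    if (any(x <= 0 | x >= 1)) stop_field(field, "must lie strictly in (0, 1)")
  } else {
    if (any(x < 0 | x > 1)) stop_field(field, "must lie in [0, 1]")
  }
  invisible(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop_field(field, "must be a positive number")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
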