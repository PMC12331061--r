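#' Built-in country-to-continent lookup
#'
#' Minimal ISO-2 lookup covering the countries emitted by the synthetic
#' generator plus common FAERS reporters; extend or replace for real
#' extracts.
#' @return named character vector, country code -> continent.
#' @export
default_continent_map <- function() {
  c(US = "North America", CA = "North America", MX = "North America",
    JP = "Asia", CN = "Asia", KR = "Asia", IN = "Asia",
    FR = "Europe", DE = "Europe", GB = "Europe", PL = "Europe",
    IT = "Europe", ES = "Europe",
    CO = "South America", BR = "South America", AR = "South America",
    AU = "Oceania", NZ = "Oceania")
}

freq_rows <- function(group, labels, counts, denom) {
  data.frame(group = group, label = labels, count = as.integer(counts),
             percent = round_half_up(100 * counts / denom, 2),
             stringsAsFactors = FALSE)
}

#' Clinical-characteristics summary of a deduplicated cohort
#'
#' Produces the standard "Table 1" of a spontaneous-report cohort: sex, age
#' group and quantitative age, year of report, reporter occupation,
#' occurrence and reporting geography, seriousness, and outcome
#' frequencies. All percentages use the deduplicated report count as the
#' denominator, so missing demographic information surfaces as explicit
#' "Not specified" rows rather than silently shrinking denominators; with
#' sex and age largely unreported in FAERS, the missingness itself is part
#' of the summary. Outcome rows are counted per (report, outcome) pair — a
#' report may contribute to several rows or to none, so the outcome column
#' need not sum to 100%. Quantitative age uses linear-interpolation
#' quartiles ([stats::quantile()] type 7) over non-missing ages;
#' percentages are rounded half-up to two decimals.
#'
#' @param cases deduplicated case reports ([as_case_reports()] +
#'   [deduplicate_cases()]).
#' @param outcomes optional OUTC data.frame (`primaryid`, `outc_cod`);
#'   duplicate (report, outcome) pairs are collapsed.
#' @param top_countries number of individually listed countries; the rest
#'   are pooled as "Other".
#' @param continent_map named vector country -> continent
#'   ([default_continent_map()]); set `NULL` to skip continent rows.
#' @return object of class `faers_descriptives`: list with `freq` (columns
#'   `group`, `label`, `count`, `percent`), `age_stats` (list `n`,
#'   `missing`, `mean`, `sd`, `median`, `q1`, `q3`, `min`, `max`) and
#'   `n_reports`.
#' @export
summarize_cases <- function(cases, outcomes = NULL, top_countries = 5,
                            continent_map = default_continent_map()) {
  n <- nrow(cases)
  if (is.null(n) || n == 0) stop("empty cohort: no case reports", call. = FALSE)
  freq <- list()

  sex_lab <- c(female = "Female", male = "Male", unknown = "Not specified")
  sx <- sex_lab[ifelse(cases$sex %in% names(sex_lab), cases$sex, "unknown")]
  tab <- table(factor(sx, levels = sex_lab))
  freq$sex <- freq_rows("Gender", names(tab), as.integer(tab), n)

  age <- cases$age_years
  grp <- cut(age, c(-Inf, 17, 44, 64, Inf),
             labels = c("<18", "18-44", "45-64", ">=65"))
  grp <- as.character(grp)
  grp[is.na(grp)] <- "Not specified"
  tab <- table(factor(grp, levels = c("<18", "18-44", "45-64", ">=65",
                                      "Not specified")))
  freq$age <- freq_rows("Age", names(tab), as.integer(tab), n)

  ok <- !is.na(age)
  age_stats <- list(
    n = sum(ok), missing = sum(!ok),
    mean = if (any(ok)) mean(age[ok]) else NA_real_,
    sd = if (sum(ok) > 1) stats::sd(age[ok]) else NA_real_,
    median = if (any(ok)) stats::median(age[ok]) else NA_real_,
    q1 = if (any(ok)) stats::quantile(age[ok], 0.25, names = FALSE) else NA_real_,
    q3 = if (any(ok)) stats::quantile(age[ok], 0.75, names = FALSE) else NA_real_,
    min = if (any(ok)) min(age[ok]) else NA_real_,
    max = if (any(ok)) max(age[ok]) else NA_real_
  )

  if (!is.null(cases$fda_date)) {
    yr <- floor(cases$fda_date / 10000)
    tab <- table(yr)
    freq$year <- freq_rows("Year of report", names(tab), as.integer(tab), n)
  }

  rep_lab <- c(consumer = "Consumer", pharmacist = "Pharmacist",
               physician = "Physician", other = "Other",
               unknown = "Not specified")
  rp <- rep_lab[ifelse(cases$reporter %in% names(rep_lab),
                       cases$reporter, "unknown")]
  tab <- table(factor(rp, levels = rep_lab))
  tab <- tab[tab > 0 | names(tab) != "Not specified"]
  freq$reporter <- freq_rows("Reporter", names(tab), as.integer(tab), n)

  country_block <- function(x, what) {
    x <- ifelse(is.na(x) | x == "", "Not specified", x)
    rows <- list()
    if (!is.null(continent_map)) {
      cont <- continent_map[x]
      cont[is.na(cont) & x != "Not specified"] <- "Other"
      cont[x == "Not specified"] <- "Not specified"
      tab <- sort(table(cont), decreasing = TRUE)
      rows$continent <- freq_rows(paste("Continent of", what), names(tab),
                                  as.integer(tab), n)
    }
    tab <- sort(table(x[x != "Not specified"]), decreasing = TRUE)
    keep <- utils::head(seq_along(tab), top_countries)
    cn <- as.integer(tab[keep]); lb <- names(tab)[keep]
    if (length(tab) > top_countries) {
      cn <- c(cn, sum(tab[-keep])); lb <- c(lb, "Other")
    }
    if (any(x == "Not specified")) {
      cn <- c(cn, sum(x == "Not specified")); lb <- c(lb, "Not specified")
    }
    rows$country <- freq_rows(paste("Country of", what), lb, cn, n)
    rows
  }
  if (!is.null(cases$occurrence_country)) {
    freq <- c(freq, country_block(cases$occurrence_country, "occurrence"))
  }
  if (!is.null(cases$reporting_country)) {
    freq <- c(freq, country_block(cases$reporting_country, "reporting"))
  }

  if (!is.null(cases$serious) && !all(is.na(cases$serious))) {
    lab <- ifelse(is.na(cases$serious), "Not specified",
                  ifelse(cases$serious, "Serious", "Non-serious"))
    tab <- table(factor(lab, levels = c("Serious", "Non-serious",
                                        "Not specified")))
    tab <- tab[tab > 0 | names(tab) != "Not specified"]
    freq$severity <- freq_rows("Severity", names(tab), as.integer(tab), n)
  }

  if (!is.null(outcomes) && nrow(outcomes) > 0) {
    oc <- unique(data.frame(primaryid = as.numeric(outcomes$primaryid),
                            outc_cod = toupper(trimws(outcomes$outc_cod)),
                            stringsAsFactors = FALSE))
    oc <- oc[oc$primaryid %in% cases$primaryid, ]
    out_lab <- c(LT = "Life-threatening", HO = "Hospitalization",
                 DS = "Disability", DE = "Death", OT = "Other")
    lab <- out_lab[oc$outc_cod]
    lab[is.na(lab)] <- "Other"
    tab <- table(factor(lab, levels = unname(out_lab)))
    freq$outcome <- freq_rows("Outcome", names(tab), as.integer(tab), n)
  }

  structure(list(freq = do.call(rbind, c(freq, make.row.names = FALSE)),
                 age_stats = age_stats, n_reports = n),
            class = "faers_descriptives")
}

#' @export
print.faers_descriptives <- function(x, ...) {
  cat(sprintf("Cohort summary (%d deduplicated reports)\n", x$n_reports))
  f <- x$freq
  for (g in unique(f$group)) {
    cat(g, "\n")
    rows <- f[f$group == g, ]
    for (i in seq_len(nrow(rows))) {
      cat(sprintf("  %-28s %6d (%.2f)\n", rows$label[i], rows$count[i],
                  rows$percent[i]))
    }
  }
  a <- x$age_stats
  cat("Age (years, quantitative)\n")
  cat(sprintf("  N (missing)                  %d (%d)\n", a$n, a$missing))
  if (a$n > 0) {
    cat(sprintf("  Mean (SD)                    %.2f (%.2f)\n", a$mean, a$sd))
    cat(sprintf("  Median (Q1, Q3)              %.2f (%.2f, %.2f)\n",
                a$median, a$q1, a$q3))
    cat(sprintf("  Min, Max                     %.2f, %.2f\n", a$min, a$max))
  }
  invisible(x)
}
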