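#' Build PT-level 2x2 contingency tables
#'
#' For each preferred term the classical pharmacovigilance 2x2 table is
#' formed contrasting the index drug against all other drugs in the corpus.
#' The counting unit is the unique (report, PT) pair: a report contributes
#' at most once to a given PT but may contribute to many PTs, so the column
#' totals are event counts, not case counts. For PT p:
#' `a` = index-drug reports mentioning p, `b` = remaining index-drug
#' (report, PT) pairs, `c`/`d` the analogues over all other reports, and
#' `expected = (a+b)(a+c)/N` with `N = a+b+c+d` (identical across PTs).
#'
#' @param events data.frame with columns `primaryid` and `pt`, restricted to
#'   deduplicated reports; repeated identical pairs are collapsed.
#' @param index_ids vector of `primaryid` values of index-drug reports.
#' @return data.frame with columns `label`, `a`, `b`, `c`, `d`, `expected`,
#'   one row per PT, ordered by descending `a` then label.
#' @export
build_pt_tables <- function(events, index_ids) {
  if (is.null(events) || nrow(events) == 0) {
    stop("empty event set: no (report, PT) pairs to tabulate", call. = FALSE)
  }
  ev <- unique(data.frame(primaryid = as.character(events$primaryid),
                          pt = as.character(events$pt),
                          stringsAsFactors = FALSE))
  idx <- ev$primaryid %in% as.character(index_ids)
  t_index <- sum(idx)
  t_other <- sum(!idx)
  pts <- sort(unique(ev$pt))
  a <- as.integer(table(factor(ev$pt[idx], levels = pts)))
  cc <- as.integer(table(factor(ev$pt[!idx], levels = pts)))
  b <- t_index - a
  d <- t_other - cc
  n <- t_index + t_other
  out <- data.frame(label = pts, a = a, b = b, c = cc, d = d,
                    expected = (a + b) * (a + cc) / n,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$a, out$label), ]
  rownames(out) <- NULL
  out
}

#' Aggregate PT-level cells to the system-organ-class level
#'
#' SOC counts are sums of the member PTs' (report, PT) pair counts, without
#' re-deduplication at SOC level: a report mentioning two PTs of one SOC
#' contributes 2 to that SOC's event count. PTs absent from the map are
#' collected under the label `"unmapped"` and reported via a warning.
#' `proportion` is the SOC's share of all index-drug events,
#' `100 * a / sum(a)`, rounded half-up to 2 decimals.
#'
#' @param pt_cells output of [build_pt_tables()].
#' @param pt_to_soc data.frame with columns `pt` and `soc`.
#' @return data.frame with columns `label`, `a`, `b`, `c`, `d`, `expected`,
#'   `proportion`, one row per SOC, ordered by descending `a`.
#' @export
aggregate_soc <- function(pt_cells, pt_to_soc) {
  stopifnot(all(c("pt", "soc") %in% names(pt_to_soc)))
  soc <- pt_to_soc$soc[match(pt_cells$label, pt_to_soc$pt)]
  if (anyNA(soc)) {
    warning(sprintf("%d PT(s) not in the PT->SOC map; grouped under 'unmapped'",
                    sum(is.na(soc))), call. = FALSE)
    soc[is.na(soc)] <- "unmapped"
  }
  a <- rowsum(pt_cells$a, soc)
  cc <- rowsum(pt_cells$c, soc)
  t_index <- pt_cells$a[1] + pt_cells$b[1]
  t_other <- pt_cells$c[1] + pt_cells$d[1]
  n <- t_index + t_other
  out <- data.frame(label = rownames(a),
                    a = as.integer(a), b = t_index - as.integer(a),
                    c = as.integer(cc), d = t_other - as.integer(cc),
                    stringsAsFactors = FALSE)
  out$expected <- (out$a + out$b) * (out$a + out$c) / n
  out$proportion <- round_half_up(100 * out$a / sum(out$a), 2)
  out <- out[order(-out$a, out$label), ]
  rownames(out) <- NULL
  out
}

#' Build observed/expected cells for every drug-event pair of a corpus
#'
#' The empirical-Bayes MGPS prior is fitted over all drug-event
#' combinations of the database, not just the index drug's rows. For each
#' (drug, PT) pair with at least one report, `a` is the number of reports
#' of that drug mentioning that PT and `expected` the count implied by
#' independence of drug and event margins, `n_drug * n_pt / N` over
#' (report, PT) pairs.
#'
#' @param report_drugs data.frame with columns `primaryid`, `drug`: the
#'   primary-suspect drug of each deduplicated report (one row per report).
#' @param events data.frame with columns `primaryid`, `pt`.
#' @return data.frame with columns `drug`, `pt`, `a`, `expected`.
#' @export
build_drug_event_cells <- function(report_drugs, events) {
  ev <- unique(data.frame(primaryid = as.character(events$primaryid),
                          pt = as.character(events$pt),
                          stringsAsFactors = FALSE))
  rd <- data.frame(primaryid = as.character(report_drugs$primaryid),
                   drug = as.character(report_drugs$drug),
                   stringsAsFactors = FALSE)
  rd <- rd[!duplicated(rd$primaryid), ]
  ev$drug <- rd$drug[match(ev$primaryid, rd$primaryid)]
  ev <- ev[!is.na(ev$drug), ]
  if (nrow(ev) == 0) stop("no events could be linked to a drug", call. = FALSE)
  dt <- data.table::as.data.table(ev)
  cells <- dt[, list(a = .N), by = c("drug", "pt")]
  n_drug <- dt[, list(n_drug = .N), by = "drug"]
  n_pt <- dt[, list(n_pt = .N), by = "pt"]
  cells <- merge(cells, n_drug, by = "drug")
  cells <- merge(cells, n_pt, by = "pt")
  cells[, "expected" := cells$n_drug * cells$n_pt / nrow(ev)]
  out <- as.data.frame(cells[, c("drug", "pt", "a", "expected")])
  out <- out[order(out$drug, out$pt), ]
  rownames(out) <- NULL
  out
}
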