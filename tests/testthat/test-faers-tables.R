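test_that("reading preserves rows, blanks become missing, partial dates are flagged", {
  demo <- data.frame(primaryid = c("1", "2", "3"), caseid = c("10", "20", "30"),
                     fda_dt = c("20240101", "20240102", "20240103"),
                     event_dt = c("20240101", "202403", ""),
                     age = c("45", "", "60"), age_cod = c("YR", "", "YR"),
                     sex = c("F", "", "M"), stringsAsFactors = FALSE)
  p <- write_dollar_file(demo)
  x <- read_faers_table(p, "DEMO")
  expect_equal(nrow(x), 3)
  cr <- as_case_reports(x)
  expect_equal(sum(cr$sex == "unknown"), 1)
  expect_equal(sum(is.na(cr$age_years)), 1)
  expect_equal(cr$event_dt_status, c("complete", "partial", "missing"))
})

test_that("schema violations and empty files are reported explicitly", {
  bad <- data.frame(primaryid = "1", caseid = "10", stringsAsFactors = FALSE)
  expect_error(read_faers_table(write_dollar_file(bad), "DEMO"), "fda_dt")
  empty <- tempfile(fileext = ".txt")
  file.create(empty)
  expect_error(read_faers_table(empty, "REAC"), "empty")
})

test_that("a generated DEMO table round-trips through write and read", {
  d <- generate_faers_dataset(small_config(seed = 5, n_reports = 200))
  dir <- tempfile()
  write_faers_dataset(d, dir, quarter = "24Q3")
  x <- read_faers_table(file.path(dir, "DEMO24Q3.txt"), "DEMO")
  orig <- d$tables$demo
  for (cl in names(orig)) orig[[cl]] <- as.character(orig[[cl]])
  expect_equal(as.data.frame(x), orig, ignore_attr = TRUE)
})

test_that("deduplication keeps the version maximising (FDA_DT, PRIMARYID)", {
  # larger FDA_DT wins
  g1 <- rbind(case_row(100, 20240101, 1001), case_row(100, 20240301, 1002))
  expect_equal(deduplicate_cases(g1)$primaryid, 1002)
  # FDA_DT tie: larger PRIMARYID wins
  g2 <- rbind(case_row(100, 20240301, 1002), case_row(100, 20240301, 1003))
  expect_equal(deduplicate_cases(g2)$primaryid, 1003)
  # unique caseids: output equals input (ordered by caseid)
  g3 <- rbind(case_row(3, 20240101, 31), case_row(1, 20240101, 11),
              case_row(2, 20240101, 21))
  expect_equal(deduplicate_cases(g3)$primaryid, c(11, 21, 31))
  expect_equal(nrow(deduplicate_cases(g1[0, ])), 0)
})

test_that("deduplication is idempotent and matches the generator ledger", {
  for (s in 1:2) {
    d <- generate_faers_dataset(small_config(seed = s, duplicate_fraction = 0.4))
    cases <- as_case_reports(d$tables$demo)
    once <- deduplicate_cases(cases)
    expect_identical(deduplicate_cases(once), once)
    expect_equal(nrow(once), length(unique(cases$caseid)))
    surv <- sort(d$ledger$primaryid[d$ledger$is_final])
    expect_equal(sort(as.character(once$primaryid)), surv)
  }
})

test_that("primary-suspect selection requires both name match and PS role", {
  drug <- data.frame(
    primaryid = c("1", "2", "3"),
    role_cod = c("PS", "C", "PS"),
    drugname = c("OSILODROSTAT", "OSILODROSTAT", "OTHER"),
    stringsAsFactors = FALSE)
  expect_equal(select_primary_suspect(drug, "osilodrostat"), "1")
  expect_equal(select_primary_suspect(drug, "nomatch"), character(0))
  expect_error(select_primary_suspect(drug, character(0)), "pattern")

  d <- generate_faers_dataset(small_config(seed = 6))
  ids <- select_primary_suspect(d$tables$drug, "osilodrostat")
  expect_setequal(ids, d$ledger$primaryid[d$ledger$is_index])
})

test_that("onset linkage does calendar arithmetic and tallies all exclusions", {
  cases <- data.frame(
    primaryid = 1:5,
    event_dt_raw = c("20240301", "20240101", "20240110", "202401", "20240601"),
    sex = c("female", "male", "female", "male", "female"),
    stringsAsFactors = FALSE)
  pe <- parse_faers_date(cases$event_dt_raw)
  cases$event_date <- pe$date; cases$event_dt_status <- pe$status
  ther <- data.frame(primaryid = as.character(1:5),
                     start_dt = c("20240109", "20240201", "20240110",
                                  "20240101", ""),
                     stringsAsFactors = FALSE)
  lk <- link_onset(cases, ther)
  # report 1: 2024-01-09 -> 2024-03-01 is 52 days
  expect_equal(lk$onsets$onset_days[lk$onsets$primaryid == 1], 52)
  # report 3: same-day onset mapped to half a day
  expect_equal(lk$onsets$onset_days[lk$onsets$primaryid == 3], 0.5)
  # report 2 negative, report 4 partial event date, report 5 missing start
  expect_equal(unname(lk$exclusions["negative"]), 1)
  expect_equal(unname(lk$exclusions["missing_event_date"]), 1)
  expect_equal(unname(lk$exclusions["missing_start_date"]), 1)
  expect_equal(nrow(lk$onsets) + sum(lk$exclusions), nrow(cases))
})

test_that("earliest complete therapy start defines time at risk", {
  cases <- data.frame(primaryid = 1, event_dt_raw = "20240301",
                      sex = "female", stringsAsFactors = FALSE)
  pe <- parse_faers_date(cases$event_dt_raw)
  cases$event_date <- pe$date; cases$event_dt_status <- pe$status
  ther <- data.frame(primaryid = c("1", "1", "1"),
                     start_dt = c("20240201", "20240109", "2023"),
                     stringsAsFactors = FALSE)
  expect_equal(link_onset(cases, ther)$onsets$onset_days, 52)
})

test_that("recovered onsets equal the ledger for complete-date index cases", {
  d <- generate_faers_dataset(small_config(seed = 7, n_reports = 800))
  cases <- deduplicate_cases(as_case_reports(d$tables$demo))
  idx <- as.numeric(select_primary_suspect(d$tables$drug, "osilodrostat"))
  cases <- cases[cases$primaryid %in% idx, ]
  ther <- d$tables$ther
  lk <- link_onset(cases, ther[as.numeric(ther$primaryid) %in% idx, ])
  led <- d$ledger[d$ledger$is_final & d$ledger$is_index, ]
  led$expected_days <- ifelse(led$onset_days_dates == 0, 0.5,
                              led$onset_days_dates)
  m <- merge(lk$onsets,
             data.frame(primaryid = as.numeric(led$primaryid),
                        expected = led$expected_days),
             by = "primaryid")
  expect_equal(nrow(m), nrow(lk$onsets))
  expect_equal(m$onset_days, m$expected)
})
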