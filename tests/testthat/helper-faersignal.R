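# shared fixtures, all built in code

# a small, fast generator configuration for structural tests
small_config <- function(seed = 1, n_reports = 400, ...) {
  synthetic_config(n_reports = n_reports, seed = seed, ...)
}

# write a '$'-delimited table file from a data.frame, returning its path
write_dollar_file <- function(df, path = tempfile(fileext = ".txt")) {
  data.table::fwrite(df, path, sep = "$", quote = FALSE, eol = "\n", na = "")
  path
}

# hand-built case-report rows for dedup tests
case_row <- function(caseid, fda, pid) {
  data.frame(primaryid = pid, caseid = caseid, fda_date = fda,
             stringsAsFactors = FALSE)
}

# toy (report, PT) corpus used by the contingency tests:
# index reports R1:{P,Q}, R2:{P}; other reports R3:{P}, R4:{Q,S}
toy_events <- function() {
  data.frame(
    primaryid = c("R1", "R1", "R2", "R3", "R4", "R4"),
    pt = c("P", "Q", "P", "P", "Q", "S"),
    stringsAsFactors = FALSE
  )
}

# grid of 2x2 cells spanning small and large counts, used by estimator
# property tests
cell_grid <- function() {
  expand.grid(a = c(1, 3, 10, 50),
              b = c(20, 200),
              c = c(5, 80),
              d = 10000)
}
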