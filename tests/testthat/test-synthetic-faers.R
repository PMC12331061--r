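test_that("configuration validation rejects out-of-range fields by name", {
  expect_error(synthetic_config(duplicate_fraction = 1.5), "duplicate_fraction")
  expect_error(synthetic_config(sex_missing_rate = -0.1), "sex_missing_rate")
  expect_error(synthetic_config(n_reports = 0), "n_reports")
  expect_error(synthetic_config(tto_shape_by_sex = c(female = 0.7, male = -1)),
               "tto_shape_by_sex")
  expect_error(synthetic_config(planted_signals = c(not_a_pt = 5)),
               "planted_signals")
  # lambda * background rate must stay a probability
  expect_error(synthetic_config(planted_signals = c(pt_001 = 50)),
               "planted_signals")
})

test_that("identical seed and config give identical tables and identical files", {
  cfg <- small_config(seed = 11)
  d1 <- generate_faers_dataset(cfg)
  d2 <- generate_faers_dataset(cfg)
  expect_identical(d1$tables, d2$tables)
  expect_identical(d1$ledger, d2$ledger)

  t1 <- file.path(tempfile(), "a"); t2 <- file.path(tempfile(), "b")
  write_faers_dataset(d1, t1)
  write_faers_dataset(d2, t2)
  for (f in list.files(t1)) {
    expect_identical(readBin(file.path(t1, f), "raw", file.size(file.path(t1, f))),
                     readBin(file.path(t2, f), "raw", file.size(file.path(t2, f))))
  }
})

test_that("duplicate versions appear only when requested and are well-ordered", {
  d0 <- generate_faers_dataset(small_config(seed = 2, duplicate_fraction = 0))
  expect_equal(nrow(d0$tables$demo), length(unique(d0$tables$demo$caseid)))
  expect_equal(nrow(d0$tables$demo), 400)

  d1 <- generate_faers_dataset(small_config(seed = 2, duplicate_fraction = 0.3))
  demo <- d1$tables$demo
  expect_gt(nrow(demo), length(unique(demo$caseid)))
  # within a case, FDA_DT and PRIMARYID increase with the version
  by_case <- split(demo, demo$caseid)
  multi <- Filter(function(x) nrow(x) > 1, by_case)
  expect_gt(length(multi), 0)
  for (g in multi[1:10]) {
    g <- g[order(g$caseversion), ]
    expect_true(all(diff(as.numeric(g$fda_dt)) > 0) ||
                  all(diff(as.Date(g$fda_dt, "%Y%m%d") > 0)))
    expect_true(all(diff(as.numeric(g$primaryid)) > 0))
  }
  # duplicate versions differ only in primaryid, caseversion and fda_dt
  inv <- setdiff(names(demo), c("primaryid", "caseversion", "fda_dt"))
  for (g in multi[1:10]) {
    expect_equal(nrow(unique(g[, inv])), 1)
  }
})

test_that("demographic missingness tracks the configured rates", {
  d <- generate_faers_dataset(small_config(seed = 3, n_reports = 5000,
                                           duplicate_fraction = 0))
  demo <- d$tables$demo
  expect_lt(abs(mean(demo$sex == "") - 0.83), 0.02)
  expect_lt(abs(mean(demo$age == "") - 0.85), 0.02)
})

test_that("ledger onset times are nonnegative and follow the configured Weibull law", {
  for (s in 1:3) {
    cfg <- synthetic_config(n_reports = 10000, duplicate_fraction = 0,
                            tto_scale_by_sex = c(female = 187.21, male = 187.21),
                            tto_shape_by_sex = c(female = 0.73, male = 0.73),
                            seed = s)
    led <- generate_faers_dataset(cfg)$ledger
    expect_true(all(led$true_onset_days >= 0))
    ks <- stats::ks.test(led$true_onset_days, "pweibull",
                         shape = 0.73, scale = 187.21)
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("event multiplicity and planted relative reporting rates match the design", {
  cfg <- synthetic_config(n_reports = 5000, duplicate_fraction = 0,
                          index_fraction = 0.3,
                          planted_signals = c(pt_040 = 8), seed = 4)
  d <- generate_faers_dataset(cfg)
  reac <- d$tables$reac
  pairs_per_case <- table(reac$caseid)
  # independent Bernoulli rates sum to 3.5 expected events per case, and the
  # at-least-one-event rule plus the planted PT push it only slightly higher
  expect_lt(abs(mean(pairs_per_case) - 3.5), 0.25)
  # one REAC row per (case, PT)
  expect_equal(nrow(reac), nrow(unique(reac[, c("caseid", "pt")])))

  led <- d$ledger[d$ledger$is_final, ]
  has_sig <- led$caseid %in% reac$caseid[reac$pt == "pt_040"]
  p_bg <- cfg$background_event_rates[["pt_040"]]
  p_idx <- mean(has_sig[led$is_index])
  p_oth <- mean(has_sig[!led$is_index])
  expect_lt(abs(p_idx - 8 * p_bg), 0.03)
  expect_lt(abs(p_oth - p_bg), 0.01)
})
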