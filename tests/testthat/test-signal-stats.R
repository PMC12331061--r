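test_that("ROR and Woolf interval reproduce hand-evaluated values", {
  r <- ror_estimate(20, 80, 10, 90)
  expect_equal(r$ror, 2.25)
  expect_equal(r$ror_lo, 0.99428, tolerance = 1e-4)
  expect_equal(r$ror_hi, 5.09162, tolerance = 1e-4)
  # independence: ROR 1, interval straddles 1
  r0 <- ror_estimate(10, 10, 10, 10)
  expect_equal(r0$ror, 1)
  expect_lt(r0$ror_lo, 1); expect_gt(r0$ror_hi, 1)
})

test_that("zero cells get the Haldane-Anscombe correction, or NA when disabled", {
  r <- ror_estimate(0, 10, 5, 100)
  expect_equal(r$ror, 0.5 * 100.5 / (10.5 * 5.5))
  expect_true(all(is.finite(unlist(r))))
  r_na <- ror_estimate(0, 10, 5, 100, zero_correction = FALSE)
  expect_true(all(is.na(unlist(r_na))))
  p_na <- prr_estimate(0, 10, 5, 100, zero_correction = FALSE)
  expect_true(is.na(p_na$prr))
  expect_true(is.finite(p_na$chi2))  # chi-square stays defined on raw counts
})

test_that("PRR and Yates chi-square reproduce hand-evaluated values", {
  p <- prr_estimate(20, 80, 10, 90)
  expect_equal(p$prr, 2)
  expect_equal(p$chi2, 200 * (1000 - 100)^2 / (100 * 100 * 30 * 170))
  expect_equal(p$chi2, 3.17647, tolerance = 1e-4)
  # the classical criterion fails here despite PRR >= 2
  expect_false(p$prr >= 2 && p$chi2 > 4)
  expect_equal(prr_estimate(10, 10, 10, 10)$prr, 1)
  # Yates clamp: tiny deviation from independence gives exactly 0
  expect_equal(prr_estimate(6, 5, 5, 5)$chi2, 0)
  # uncorrected variant exceeds the corrected one
  expect_gt(prr_estimate(20, 80, 10, 90, yates = FALSE)$chi2, p$chi2)
})

test_that("Noren IC matches its closed form and vanishes at independence", {
  # a = 50, margins 100 and 200, N = 10000 -> E = 2
  ic <- bcpnn_ic(50, 50, 150, 9750, variant = "noren")
  expect_equal(ic$ic, log2(50.5 / 2.5))
  expect_equal(ic$ic, 4.33628, tolerance = 1e-4)
  expect_equal(ic$ic025, 3.86634, tolerance = 1e-4)
  # a = E exactly with a large: IC near 0
  ic0 <- bcpnn_ic(100, 900, 900, 8100, variant = "noren")
  expect_lt(abs(ic0$ic), 0.01)
})

test_that("Bate IC posterior moments agree with Monte-Carlo sampling", {
  # moderate Monte-Carlo check here; the full 12-cell grid at 1e6 draws is
  # exercised by the acceptance suite
  a <- 50; b <- 50; cc <- 150; d <- 9750; n <- a + b + cc + d
  got <- bcpnn_ic(a, b, cc, d, variant = "bate")
  set.seed(99); m <- 2e5
  gam <- (n + 2)^2 / ((a + b + 1) * (a + cc + 1))
  pxy <- rbeta(m, a + 1, n - a + gam - 1)
  px <- rbeta(m, a + b + 1, n - (a + b) + 1)
  py <- rbeta(m, a + cc + 1, n - (a + cc) + 1)
  ic_draws <- log2(pxy / (px * py))
  mcse <- sd(ic_draws) / sqrt(m)
  expect_lt(abs(got$ic - mean(ic_draws)), 4 * mcse)
  expect_equal(got$ic025, got$ic - 2 * sqrt(var(ic_draws)), tolerance = 0.01)
})

test_that("ror >= prr whenever ror > 1, on a grid and on a synthetic corpus", {
  g <- cell_grid()
  r <- ror_estimate(g$a, g$b, g$c, g$d)$ror
  p <- prr_estimate(g$a, g$b, g$c, g$d)$prr
  up <- r > 1
  expect_true(all(r[up] >= p[up]))
})

test_that("each statistic is nondecreasing in a with the other cells fixed", {
  a <- c(1, 2, 5, 10, 20, 50, 100)
  b <- 500; cc <- 50; d <- 10000
  expect_true(all(diff(ror_estimate(a, b, cc, d)$ror) > 0))
  expect_true(all(diff(prr_estimate(a, b, cc, d)$prr) > 0))
  expect_true(all(diff(bcpnn_ic(a, b, cc, d, "noren")$ic) > 0))
  pr <- default_mgps_prior()
  e <- (a + b) * (a + cc) / (a + b + cc + d)
  expect_true(all(diff(ebgm_scores(a, e, pr)$ebgm) > 0))
})

test_that("MGPS marginal likelihood improves over its initialisation and the fit
           recovers a pure-noise corpus", {
  set.seed(21)
  e <- exp(rnorm(5000, 0, 1)) * 2
  cells <- data.frame(a = rpois(5000, e), expected = e)
  fit <- fit_mgps_prior(cells)
  expect_true(fit$converged)
  init <- default_mgps_prior()
  ll_init <- sum(log(
    init$p_mix * dnbinom(cells$a, size = init$alpha1,
                         prob = init$beta1 / (init$beta1 + e)) +
    (1 - init$p_mix) * dnbinom(cells$a, size = init$alpha2,
                               prob = init$beta2 / (init$beta2 + e))))
  expect_gte(fit$loglik, ll_init)
  prior_mean <- fit$p_mix * fit$alpha1 / fit$beta1 +
    (1 - fit$p_mix) * fit$alpha2 / fit$beta2
  expect_gt(prior_mean, 0.8); expect_lt(prior_mean, 1.2)
})

test_that("duplicating every cell leaves the MGPS optimum unchanged", {
  set.seed(22)
  e <- exp(rnorm(400, 0, 0.8))
  cells <- data.frame(a = rpois(400, e * c(rep(1, 380), rep(8, 20))), expected = e)
  f1 <- suppressWarnings(fit_mgps_prior(cells))
  f2 <- suppressWarnings(fit_mgps_prior(rbind(cells, cells)))
  m1 <- f1$p_mix * f1$alpha1 / f1$beta1 + (1 - f1$p_mix) * f1$alpha2 / f1$beta2
  m2 <- f2$p_mix * f2$alpha1 / f2$beta1 + (1 - f2$p_mix) * f2$alpha2 / f2$beta2
  expect_equal(m1, m2, tolerance = 1e-3)
  expect_equal(2 * f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("EBGM matches first-principles quadrature and shows correct shrinkage", {
  pr <- default_mgps_prior()
  # quadrature oracle built from the unnormalised posterior density
  oracle <- function(a, e) {
    dens <- function(l) (pr$p_mix * dgamma(l, pr$alpha1, rate = pr$beta1) +
                         (1 - pr$p_mix) * dgamma(l, pr$alpha2, rate = pr$beta2)) *
                        l^a * exp(-l * e)
    z <- integrate(dens, 0, Inf, rel.tol = 1e-12)$value
    gm <- exp(integrate(function(l) log(l) * dens(l) / z, 0, Inf,
                        rel.tol = 1e-12)$value)
    q05 <- uniroot(function(q) integrate(dens, 0, q, rel.tol = 1e-12)$value / z - 0.05,
                   c(1e-9, 200), tol = 1e-12)$root
    c(gm, q05)
  }
  got <- ebgm_scores(5, 1, pr)
  exp_vals <- oracle(5, 1)
  expect_equal(got$ebgm, exp_vals[1], tolerance = 1e-6)
  expect_equal(got$ebgm05, exp_vals[2], tolerance = 1e-6)

  # shrinkage: for a = E = 1 the estimate sits between the prior geometric
  # mean and the raw ratio a/E
  prior_gm <- exp(pr$p_mix * (digamma(pr$alpha1) - log(pr$beta1)) +
                  (1 - pr$p_mix) * (digamma(pr$alpha2) - log(pr$beta2)))
  g1 <- ebgm_scores(1, 1, pr)
  expect_gt(g1$ebgm, prior_gm); expect_lt(g1$ebgm, 1)
  # shrinkage vanishes as counts grow with a/E fixed
  g_big <- ebgm_scores(10000, 1000, pr)
  expect_equal(g_big$ebgm, 10, tolerance = 0.01)
  # ordering invariants
  g <- cell_grid()
  e <- (g$a + g$b) * (g$a + g$c) / (g$a + g$b + g$c + g$d)
  sc <- ebgm_scores(g$a, e, pr)
  expect_true(all(sc$ebgm05 < sc$ebgm))
  expect_true(all(sc$ebgm05 > 0))
})

test_that("IC and log2(EBGM) agree for large counts at fixed a/E", {
  # a = 10000 with margins 1e5 in a corpus of 1e7 pairs: E = 1000, a/E = 10;
  # shrinkage is negligible on both routes so IC ~ log2(EBGM) ~ log2(10)
  a <- 10000; b <- 90000; cc <- 90000; d <- 1e7 - a - b - cc
  ic <- bcpnn_ic(a, b, cc, d, variant = "noren")$ic
  eb <- ebgm_scores(a, 1000, default_mgps_prior())$ebgm
  expect_lt(abs(ic - log2(eb)), 0.01)
  expect_equal(ic, log2(10), tolerance = 0.01)
})

test_that("the combined rule requires every criterion and the minimum count", {
  est <- data.frame(a = c(63, 50, 2, 10),
                    prr = c(98.45, 1.9, 50, 3), chi2 = c(6036.78, 500, 100, 10),
                    ror_lo = c(77.98, 10, 10, 1.2),
                    ic025 = c(4.92, 2, 2, 0.5),
                    ebgm05 = c(76.17, 30, 30, 2.5))
  out <- combined_signal(est)
  expect_equal(out$is_signal, c(TRUE, FALSE, FALSE, TRUE))
  expect_false(out$eligible[3])          # a = 2 gated out before evaluation
  expect_false(out$crit_prr[2])          # PRR < 2 is the only failure
  expect_true(all(out[2, c("crit_ror", "crit_ic", "crit_ebgm")] == TRUE))
})

test_that("estimate bundles keep their internal ordering invariants", {
  d <- generate_faers_dataset(small_config(seed = 9, n_reports = 2000,
                                           planted_signals = c(pt_030 = 6)))
  cases <- deduplicate_cases(as_case_reports(d$tables$demo))
  idx <- intersect(as.numeric(select_primary_suspect(d$tables$drug, "osilodrostat")),
                   cases$primaryid)
  ev <- data.frame(primaryid = as.numeric(d$tables$reac$primaryid),
                   pt = d$tables$reac$pt)
  ev <- ev[ev$primaryid %in% cases$primaryid, ]
  cells <- build_pt_tables(ev, idx)
  est <- suppressWarnings(signal_estimates(cells))
  expect_true(all(est$ror_lo <= est$ror & est$ror <= est$ror_hi, na.rm = TRUE))
  expect_true(all(est$prr_lo <= est$prr & est$prr <= est$prr_hi, na.rm = TRUE))
  expect_true(all(est$ic025_bate <= est$ic_bate))
  expect_true(all(est$ic025_noren <= est$ic_noren))
  expect_true(all(est$ebgm05 <= est$ebgm))
  up <- !is.na(est$ror) & est$ror > 1
  expect_true(all(est$ror[up] >= est$prr[up]))
})
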