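#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = ad / (bc)`; the interval is
#' `exp(log ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell of
#' a table is zero the Haldane-Anscombe correction adds 0.5 to all four
#' cells of that table before estimation; with `zero_correction = FALSE`
#' such tables yield `NA` (undefined estimate), never an error.
#'
#' @param a,b,c,d vectors of 2x2 counts (recycled to a common length).
#' @param zero_correction apply +0.5 to all cells of tables with a zero.
#' @param conf_level confidence level.
#' @return data.frame with columns `ror`, `ror_lo`, `ror_hi`.
#' @export
ror_estimate <- function(a, b, c, d, zero_correction = TRUE, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cells <- cbind(as.numeric(a), as.numeric(b), as.numeric(c), as.numeric(d))
  has_zero <- rowSums(cells == 0) > 0
  if (zero_correction) {
    cells[has_zero, ] <- cells[has_zero, , drop = FALSE] + 0.5
  } else {
    cells[has_zero, ] <- NA
  }
  a <- cells[, 1]; b <- cells[, 2]; c <- cells[, 3]; d <- cells[, 4]
  ror <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  data.frame(ror = ror,
             ror_lo = exp(log(ror) - z * se),
             ror_hi = exp(log(ror) + z * se))
}

#' Proportional reporting ratio, confidence interval and Yates chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` (comparator: all other drugs), with
#' interval `exp(log PRR +/- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' The chi-square statistic is computed on the uncorrected counts with the
#' Yates continuity correction,
#' `N (|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`, clamped at 0 when
#' `|ad - bc| < N/2`; set `yates = FALSE` for the uncorrected statistic.
#' Zero-cell handling for the ratio as in [ror_estimate()].
#'
#' @inheritParams ror_estimate
#' @param yates use the Yates continuity correction in the chi-square.
#' @return data.frame with columns `prr`, `prr_lo`, `prr_hi`, `chi2`.
#' @export
prr_estimate <- function(a, b, c, d, zero_correction = TRUE, yates = TRUE,
                         conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - n / 2, 0)
  chi2 <- n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))

  cells <- cbind(a, b, c, d)
  has_zero <- rowSums(cells == 0) > 0
  if (zero_correction) {
    cells[has_zero, ] <- cells[has_zero, , drop = FALSE] + 0.5
  } else {
    cells[has_zero, ] <- NA
  }
  aa <- cells[, 1]; bb <- cells[, 2]; cc <- cells[, 3]; dd <- cells[, 4]
  prr <- (aa / (aa + bb)) / (cc / (cc + dd))
  se <- sqrt(1 / aa - 1 / (aa + bb) + 1 / cc - 1 / (cc + dd))
  data.frame(prr = prr,
             prr_lo = exp(log(prr) - z * se),
             prr_hi = exp(log(prr) + z * se),
             chi2 = chi2)
}

#' BCPNN information component (Bate and Noren variants)
#'
#' The information component IC is the shrunk log2 observed-to-expected
#' reporting ratio of a drug-event pair.
#'
#' The Bate variant places independent Beta posteriors (prior constants
#' alpha1 = beta1 = gamma11 = 1, alpha = beta = 2) on the joint and
#' marginal reporting probabilities; IC mean and variance are the exact
#' posterior moments of `log2(p_xy / (p_x p_y))`, evaluated in closed form
#' with digamma/trigamma functions, and `IC025 = E(IC) - 2 sqrt(V(IC))`.
#'
#' The Noren variant is the credibility-interval approximation
#' `IC = log2((a + 0.5) / (E + 0.5))` with
#' `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2)`, where
#' `E = (a+b)(a+c)/N` is the independence-expected count.
#'
#' @inheritParams ror_estimate
#' @param variant `"noren"` (default) or `"bate"`.
#' @return data.frame with columns `ic` and `ic025` (bits).
#' @export
bcpnn_ic <- function(a, b, c, d, variant = c("noren", "bate")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (any(n <= 0)) stop("total count N must be positive", call. = FALSE)
  expected <- (a + b) * (a + c) / n
  if (variant == "noren") {
    ic <- log2((a + 0.5) / (expected + 0.5))
    ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
    return(data.frame(ic = ic, ic025 = ic025))
  }
  # Bate model: p_xy ~ Beta(a + g11, N - a + gam - g11), and independently
  # p_x ~ Beta(a+b+1, N-(a+b)+1), p_y ~ Beta(a+c+1, N-(a+c)+1);
  # gam is chosen so that E(p_xy) = E(p_x) E(p_y) under independence
  g11 <- 1; al1 <- 1; be1 <- 1; al <- 2; be <- 2
  cx <- a + b; cy <- a + c
  gam <- g11 * (n + al) * (n + be) / ((cx + al1) * (cy + be1))
  ln2 <- log(2)
  e_ic <- (digamma(a + g11) - digamma(n + gam) -
           digamma(cx + al1) + digamma(n + al) -
           digamma(cy + be1) + digamma(n + be)) / ln2
  v_ic <- (trigamma(a + g11) - trigamma(n + gam) +
           trigamma(cx + al1) - trigamma(n + al) +
           trigamma(cy + be1) - trigamma(n + be)) / ln2^2
  data.frame(ic = e_ic, ic025 = e_ic - 2 * sqrt(v_ic))
}

# marginal density of a under lambda ~ Gamma(shape, rate), a | lambda E
# ~ Poisson: negative binomial with size = shape, prob = rate / (rate + E)
mgps_marginal <- function(a, expected, shape, rate, log = FALSE) {
  stats::dnbinom(a, size = shape, prob = rate / (rate + expected), log = log)
}

mgps_negloglik <- function(theta, a, expected) {
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  p <- stats::plogis(theta[5])
  f1 <- mgps_marginal(a, expected, a1, b1, log = TRUE)
  f2 <- mgps_marginal(a, expected, a2, b2, log = TRUE)
  m <- pmax(f1, f2)
  ll <- m + log(p * exp(f1 - m) + (1 - p) * exp(f2 - m))
  -sum(ll)
}

#' Fit the MGPS two-component gamma mixture prior
#'
#' The multi-item gamma Poisson shrinker models each cell count as
#' `a | lambda ~ Poisson(lambda * E)` with the relative reporting rate
#' `lambda` drawn from the mixture
#' `p Gamma(alpha1, beta1) + (1-p) Gamma(alpha2, beta2)` (shape/rate).
#' Marginally each count is a mixture of two negative binomials; the five
#' hyperparameters are estimated by maximising the summed marginal
#' log-likelihood over all drug-event cells of the corpus, starting from
#' the classical initialisation (0.2, 0.1, 2, 4, 1/3) with parameters kept
#' in range by log/logit transforms.
#'
#' @param cells data.frame with columns `a` (observed count) and `expected`
#'   (independence-expected count), normally from
#'   [build_drug_event_cells()]; at least 100 cells are recommended for a
#'   stable fit.
#' @return object of class `mgps_prior`: list with `alpha1`, `beta1`,
#'   `alpha2`, `beta2`, `p_mix`, `loglik`, `converged`, `n_cells`.
#' @export
fit_mgps_prior <- function(cells) {
  a <- cells$a
  expected <- cells$expected
  if (length(a) < 2 || any(expected <= 0)) {
    stop("need at least two cells with positive expected counts", call. = FALSE)
  }
  if (length(a) < 100) {
    warning("fewer than 100 cells; MGPS hyperparameter estimates may be unstable",
            call. = FALSE)
  }
  init <- c(log(0.2), log(0.1), log(2), log(4), stats::qlogis(1 / 3))
  # box bounds keep both components identified: without them a component
  # whose mixture weight hits the boundary can drift to arbitrary values
  run <- function(start) {
    stats::nlminb(start, mgps_negloglik, a = a, expected = expected,
                  lower = c(rep(-12, 4), -7), upper = c(rep(12, 4), 7),
                  control = list(iter.max = 500, eval.max = 1000))
  }
  opt <- run(init)
  if (opt$convergence != 0) {
    # a restart from the current point clears spurious "false convergence"
    # stops on the flat ridge left by a near-degenerate component
    opt2 <- run(opt$par)
    if (opt2$objective <= opt$objective) opt <- opt2
  }
  converged <- opt$convergence == 0 && is.finite(opt$objective)
  if (!converged) {
    warning("MGPS prior optimisation did not converge; estimates returned as-is",
            call. = FALSE)
  }
  structure(list(
    alpha1 = exp(opt$par[1]), beta1 = exp(opt$par[2]),
    alpha2 = exp(opt$par[3]), beta2 = exp(opt$par[4]),
    p_mix = stats::plogis(opt$par[5]),
    loglik = -opt$objective, converged = converged,
    n_cells = length(a)
  ), class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("MGPS gamma-mixture prior (shape/rate)\n")
  cat(sprintf("  component 1: Gamma(%.4g, %.4g)   weight %.3f\n",
              x$alpha1, x$beta1, x$p_mix))
  cat(sprintf("  component 2: Gamma(%.4g, %.4g)   weight %.3f\n",
              x$alpha2, x$beta2, 1 - x$p_mix))
  cat(sprintf("  log-likelihood %.2f over %d cells; converged: %s\n",
              x$loglik, x$n_cells, x$converged))
  invisible(x)
}

#' Default MGPS prior (classical initialisation values)
#'
#' Useful for worked examples and for scoring single cells without a
#' corpus-wide fit.
#' @return an `mgps_prior` object with hyperparameters
#'   (0.2, 0.1, 2, 4, 1/3).
#' @export
default_mgps_prior <- function() {
  structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                 p_mix = 1 / 3, loglik = NA_real_, converged = NA,
                 n_cells = 0L), class = "mgps_prior")
}

#' Empirical Bayes geometric mean and its lower 5th percentile
#'
#' Under the MGPS prior the posterior of the relative reporting rate given
#' `a` is the mixture `Q Gamma(alpha1 + a, beta1 + E) +
#' (1-Q) Gamma(alpha2 + a, beta2 + E)` with `Q` proportional to the
#' component marginal likelihoods. `EBGM = exp(E[log lambda | a])` is
#' evaluated in closed form with digamma functions; `EBGM05` is the 5th
#' percentile of the posterior mixture, found by root-finding on its CDF.
#'
#' @param a observed counts.
#' @param expected independence-expected counts.
#' @param prior an `mgps_prior` from [fit_mgps_prior()] or
#'   [default_mgps_prior()].
#' @param quantile lower tail probability for the percentile (default 0.05).
#' @return data.frame with columns `ebgm`, `ebgm05`.
#' @export
ebgm_scores <- function(a, expected, prior, quantile = 0.05) {
  stopifnot(inherits(prior, "mgps_prior"))
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + expected
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + expected
  f1 <- mgps_marginal(a, expected, prior$alpha1, prior$beta1, log = TRUE)
  f2 <- mgps_marginal(a, expected, prior$alpha2, prior$beta2, log = TRUE)
  lw1 <- log(prior$p_mix) + f1
  lw2 <- log(1 - prior$p_mix) + f2
  q_mix <- 1 / (1 + exp(lw2 - lw1))
  ebgm <- exp(q_mix * (digamma(s1) - log(r1)) +
              (1 - q_mix) * (digamma(s2) - log(r2)))
  ebgm05 <- vapply(seq_along(a), function(i) {
    cdf <- function(x) {
      q_mix[i] * stats::pgamma(x, s1[i], rate = r1[i]) +
        (1 - q_mix[i]) * stats::pgamma(x, s2[i], rate = r2[i]) - quantile
    }
    lo <- min(stats::qgamma(quantile / 2, s1[i], rate = r1[i]),
              stats::qgamma(quantile / 2, s2[i], rate = r2[i]))
    hi <- max(stats::qgamma(1 - (1 - quantile) / 1e3, s1[i], rate = r1[i]),
              stats::qgamma(1 - (1 - quantile) / 1e3, s2[i], rate = r2[i]))
    stats::uniroot(cdf, lower = max(lo, 1e-12), upper = hi,
                   tol = 1e-10, extendInt = "upX")$root
  }, numeric(1))
  data.frame(ebgm = ebgm, ebgm05 = ebgm05)
}

#' Apply the combined four-method signal criterion
#'
#' A drug-event pair is flagged as a potential signal only when every
#' method's conventional threshold is met simultaneously:
#' `PRR >= 2` with `chi2 > 4`; lower 95% CI bound of ROR `> 1`;
#' `IC025 > 0`; and `EBGM05 > 2`. Pairs with fewer than `min_cases`
#' reports (default 3) are excluded before evaluation.
#'
#' @param estimates data.frame containing columns `a`, `prr`, `chi2`,
#'   `ror_lo`, `ebgm05` and the IC025 column selected by `ic_variant`
#'   (`ic025` or `ic025_bate`/`ic025_noren`).
#' @param min_cases minimum observed count for eligibility.
#' @param ic_variant which IC025 column drives the BCPNN criterion when
#'   both variants are present.
#' @return the input with logical columns `eligible`, `crit_prr`,
#'   `crit_ror`, `crit_ic`, `crit_ebgm` and `is_signal` appended.
#' @export
combined_signal <- function(estimates, min_cases = 3,
                            ic_variant = c("noren", "bate")) {
  ic_variant <- match.arg(ic_variant)
  ic_col <- if (paste0("ic025_", ic_variant) %in% names(estimates)) {
    paste0("ic025_", ic_variant)
  } else if ("ic025" %in% names(estimates)) "ic025" else {
    stop("no IC025 column found in estimates", call. = FALSE)
  }
  out <- estimates
  out$eligible <- estimates$a >= min_cases
  out$crit_prr <- out$eligible & !is.na(estimates$prr) &
    estimates$prr >= 2 & estimates$chi2 > 4
  out$crit_ror <- out$eligible & !is.na(estimates$ror_lo) & estimates$ror_lo > 1
  out$crit_ic <- out$eligible & estimates[[ic_col]] > 0
  out$crit_ebgm <- out$eligible & estimates$ebgm05 > 2
  out$is_signal <- out$crit_prr & out$crit_ror & out$crit_ic & out$crit_ebgm
  out
}

#' Compute all four disproportionality statistics for a set of cells
#'
#' Convenience wrapper running [ror_estimate()], [prr_estimate()],
#' [bcpnn_ic()] (both variants), [ebgm_scores()] and [combined_signal()]
#' over a table of 2x2 cells.
#'
#' @param cells data.frame from [build_pt_tables()] or [aggregate_soc()]
#'   (columns `label`, `a`, `b`, `c`, `d`).
#' @param prior an `mgps_prior`; fit it on the full drug-event cell set of
#'   the corpus ([build_drug_event_cells()] + [fit_mgps_prior()]). When
#'   `NULL` it is fitted on `cells` itself, which is only appropriate for
#'   exploration.
#' @param min_cases,ic_variant,yates,zero_correction see the underlying
#'   functions.
#' @return data.frame: `cells` with all statistics, the per-method
#'   criterion flags and `is_signal` appended.
#' @export
signal_estimates <- function(cells, prior = NULL, min_cases = 3,
                             ic_variant = c("noren", "bate"),
                             yates = TRUE, zero_correction = TRUE) {
  ic_variant <- match.arg(ic_variant)
  if (is.null(prior)) {
    prior <- fit_mgps_prior(data.frame(a = cells$a, expected = cells$expected))
  }
  ror <- ror_estimate(cells$a, cells$b, cells$c, cells$d,
                      zero_correction = zero_correction)
  prr <- prr_estimate(cells$a, cells$b, cells$c, cells$d,
                      zero_correction = zero_correction, yates = yates)
  bate <- bcpnn_ic(cells$a, cells$b, cells$c, cells$d, variant = "bate")
  noren <- bcpnn_ic(cells$a, cells$b, cells$c, cells$d, variant = "noren")
  expected <- if ("expected" %in% names(cells)) cells$expected else {
    (cells$a + cells$b) * (cells$a + cells$c) / (cells$a + cells$b + cells$c + cells$d)
  }
  eb <- ebgm_scores(cells$a, expected, prior)
  est <- cbind(cells, ror, prr,
               ic_bate = bate$ic, ic025_bate = bate$ic025,
               ic_noren = noren$ic, ic025_noren = noren$ic025,
               eb)
  combined_signal(est, min_cases = min_cases, ic_variant = ic_variant)
}
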