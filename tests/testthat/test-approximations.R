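test_that("the two weak-selection evaluation paths agree", {
  for (m in c(1, 4, 8, 14)) {
    gp <- baseline_gp(m = m)
    ap <- baseline_ap(omega = 0.5, delta = 0.03)
    expect_equal(weak_selection_abundance(gp, ap, path = "threshold")$value,
                 weak_selection_abundance(gp, ap, path = "generic")$value,
                 tolerance = 1e-12)
  }
  # omega = 0 gives exactly one half
  expect_equal(weak_selection_abundance(baseline_gp(),
                                        baseline_ap(omega = 0))$value, 0.5)
})

test_that("weak-selection worked examples reproduce to printed precision", {
  ap <- baseline_ap(omega = 0.5, delta = 0.03)
  expect_equal(round(weak_selection_abundance(baseline_gp(m = 1),
                                              ap)$value, 4), 0.4863)
  expect_equal(round(weak_selection_abundance(baseline_gp(m = 14),
                                              ap)$value, 1), 0.5)
})

test_that("the m = 1 closed form matches its simplification", {
  gp <- baseline_gp(m = 1)
  ap <- baseline_ap(omega = 0.5, delta = 0.03)
  d <- gp$d; r <- gp$r; tau <- gp$tau; cc <- gp$c
  pref <- ap$omega * (1 - ap$delta) / (1 + ap$delta)
  # un-approximated bracket: 2^{d-1}(r - tau + d tau) - d (2^{d-1} - 1)
  full <- 0.5 + pref / 2^(d + 2) * cc / d *
    (2^(d - 1) * (r - tau + d * tau) - d * (2^(d - 1) - 1))
  expect_equal(weak_selection_abundance(gp, ap)$value, full,
               tolerance = 1e-14)
  # the simplified form drops a d/2^{d+2} term; the change is below 1e-5
  approx <- 0.5 + pref / 8 * cc / d * (r - tau + d * tau - d)
  expect_lt(abs(full - approx), 1e-5)
})

test_that("weak-selection slope matches the exact abundance derivative", {
  eps <- 1e-3
  for (m in c(4, 8, 10)) {
    gp <- baseline_gp(m = m)
    fd <- (average_abundance_exact(gp, baseline_ap(omega = eps))$value -
             0.5) / eps
    slope <- weak_selection_abundance(gp, baseline_ap(omega = 1))$value - 0.5
    expect_equal(fd, slope, tolerance = 0.05)
  }
})

test_that("strong-selection ratio has the stated limits", {
  gp <- baseline_gp()
  i <- 0:(gp$N - 1)
  prof <- thresholdPGG:::payoff_profiles(gp)
  # delta = 0: the mutation factor is 1
  ap <- baseline_ap(omega = 3, delta = 0)
  expect_equal(strong_h_factor(i, gp, ap),
               (gp$N - i) / (i + 1) *
                 exp(-ap$omega * (prof$piB - prof$piA_next)),
               tolerance = 1e-12)
  # degenerate payoffs (pi_A(i+1) = pi_B(i) for all i): binomial(N, 1/2)
  gp1 <- game_params(N = 50, d = 5, m = 1, r = 2, c = 1, tau = 0)
  tab <- payoff_table(gp1)
  tab$a <- rep(1, gp1$d); tab$b <- rep(1, gp1$d)
  ap <- baseline_ap(omega = 6, delta = 0.03)
  lh <- thresholdPGG:::log_h_strong(gp1, ap,
                                    thresholdPGG:::payoff_profiles(gp1, tab))
  th <- stationary_distribution(gp1, ap, log_h_values = lh)
  expect_equal(th$probs, dbinom(0:gp1$N, gp1$N, 0.5), tolerance = 1e-12)
})

test_that("strong approximation error shrinks with omega on the three regimes", {
  for (nm in names(regime_sets)) {
    gp <- regime_sets[[nm]]$gp()
    err <- function(o) {
      ap <- baseline_ap(omega = o)
      abs(average_abundance_exact(gp, ap)$value -
            strong_selection_abundance(gp, ap)$value)
    }
    e0 <- err(0.5)
    es <- vapply(regime_sets[[nm]]$omegas, err, numeric(1))
    expect_true(all(es < e0), label = paste(nm, "below omega=0.5 error"))
    expect_true(all(diff(es) <= 0), label = paste(nm, "monotone decrease"))
  }
})

test_that("piecewise estimator switches between the two formulas", {
  gp <- baseline_gp()
  ap_lo <- baseline_ap(omega = 0.5); ap_hi <- baseline_ap(omega = 6)
  expect_equal(piecewise_abundance(gp, ap_lo)$value,
               weak_selection_abundance(gp, ap_lo)$value)
  expect_equal(piecewise_abundance(gp, ap_hi)$value,
               strong_selection_abundance(gp, ap_hi)$value)
  expect_identical(piecewise_abundance(gp, ap_hi)$method, "piecewise")
  # switch point is user-settable
  ap_mid <- baseline_ap(omega = 1.5)
  expect_equal(piecewise_abundance(gp, ap_mid, omega_switch = 1)$value,
               strong_selection_abundance(gp, ap_mid)$value)
  expect_equal(piecewise_abundance(gp, ap_mid, omega_switch = 2)$value,
               weak_selection_abundance(gp, ap_mid)$value)
})

test_that("validity report flags the regimes sensibly", {
  # small omega: weak regime
  rep_lo <- approximation_validity(baseline_gp(), baseline_ap(omega = 0.3))
  expect_identical(rep_lo$regime, "weak_ok")
  # small r, large m, delta = 0.03: payoffs never clear the aspiration
  # level, the known failure regime of the strong approximation
  rep_bad <- approximation_validity(baseline_gp(m = 12, r = 3),
                                    baseline_ap(omega = 4))
  expect_identical(rep_bad$regime, "neither")
  expect_lt(rep_bad$min_scaled_gap, 0)
  # strong_ok requires a positive minimum scaled gap; since a lone
  # defector always earns 0, that needs an aspiration level below 0
  gp_rich <- game_params(N = 30, d = 2, m = 1, r = 6, c = 2, tau = 0)
  rep_ok <- approximation_validity(gp_rich,
                                   baseline_ap(omega = 8, alpha = -0.5))
  expect_identical(rep_ok$regime, "strong_ok")
  expect_gt(rep_ok$min_scaled_gap, 0)
  expect_true(is.finite(rep_ok$omega_floor))
  # strong result carries the diagnostics
  res <- strong_selection_abundance(baseline_gp(), baseline_ap(omega = 4))
  expect_s3_class(res$diagnostics, "validity_report")
})

test_that("critical multiplication factor reproduces the printed values", {
  expect_equal(round(critical_r(15, 12, 0.25), 2), 0.21)
  expect_equal(round(critical_r(15, 8, 0.25), 2), 2.02)
  expect_equal(round(critical_r(15, 2, 0.25), 2), 11.48)
  expect_equal(round(critical_r(15, 5, 0.25), 2), 8.48)
  expect_error(critical_r(15, 15, 0.25), "m <= d-1")
})

test_that("sign of exact abundance minus 1/2 matches the critical condition", {
  ap <- baseline_ap(omega = 0.1)
  for (pm in list(c(3, 12), c(8, 8), c(10, 2), c(5, 5))) {
    gp <- baseline_gp(m = pm[2], r = pm[1])
    exact_margin <- average_abundance_exact(gp, ap)$value - 0.5
    crit_margin <- pm[1] - critical_r(gp$d, gp$m, gp$tau)
    expect_identical(sign(exact_margin), sign(crit_margin),
                     label = paste("r =", pm[1], "m =", pm[2]))
    fav <- is_A_favoured(gp, ap, method = "weak")
    expect_identical(fav$favoured, crit_margin > 0)
    expect_equal(fav$margin, crit_margin)
    fav_exact <- is_A_favoured(gp, ap, method = "exact")
    expect_identical(fav_exact$favoured, exact_margin > 0)
  }
})

test_that("optimal threshold equals the brute-force weak-selection maximiser", {
  expect_identical(optimal_threshold(15, 8, 0.25), 9L)
  ap <- baseline_ap(omega = 0.5)
  xs <- vapply(1:14, function(m)
    weak_selection_abundance(baseline_gp(m = m), ap)$value, numeric(1))
  expect_identical(which.max(xs), 9L)
  # brute-force agreement across a range of r
  for (r in c(4, 6, 10)) {
    xs <- vapply(1:14, function(m)
      weak_selection_abundance(baseline_gp(m = m, r = r), ap)$value,
      numeric(1))
    expect_identical(as.integer(which.max(xs)), optimal_threshold(15, r, 0.25))
  }
  # negative radicand is rejected (only reachable outside the usual
  # parameter ranges: over r > 0, tau in [0, 1] the radicand stays positive)
  expect_error(optimal_threshold(15, -4, 0), "radicand")
})
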