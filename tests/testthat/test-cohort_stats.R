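test_that("Kruskal-Wallis H matches the rank formula and its edge cases", {
  # two identical groups: H = 0, p = 1
  same <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)

  # separated groups, no ties: H = 3.857 by hand (rank sums 6 and 15)
  g2 <- list(lo = c(1, 2, 3), hi = c(4, 5, 6))
  kw <- kruskal_wallis(g2)
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$H, oracle_kw_h(g2), tolerance = 1e-12)

  # tie-heavy small groups match the tie-corrected formula
  g3 <- list(a = c(1, 1, 2, 5), b = c(2, 2, 3), c = c(3, 5, 5, 5))
  expect_equal(kruskal_wallis(g3)$H, oracle_kw_h(g3), tolerance = 1e-12)

  expect_error(kruskal_wallis(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("Kruskal-Wallis H is invariant to strictly monotone transforms", {
  set.seed(91)
  g <- list(a = rnorm(8), b = rnorm(6, 1), c = rnorm(7, 2))
  h0 <- kruskal_wallis(g)$H
  expect_equal(kruskal_wallis(lapply(g, exp))$H, h0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(lapply(g, function(v) 3 * v - 100))$H, h0,
               tolerance = 1e-12)
})

test_that("Dunn post-hoc z matches the pooled-rank formula", {
  # identical groups: all z = 0, adjusted p = 1
  same <- dunn_posthoc(list(a = c(2, 2, 2), b = c(2, 2, 2),
                            c = c(2, 2, 2)))
  expect_equal(same$z, rep(0, 3))
  expect_equal(same$p_adjusted, rep(1, 3))

  # three small hand-built groups (with a tie) against the direct formula
  g <- list(a = c(1, 3, 5), b = c(2, 4, 6, 8), c = c(5, 7, 9))
  d <- dunn_posthoc(g, adjust = "none")
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"],
               oracle_dunn_z(g, 1, 2), tolerance = 1e-12)
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"],
               oracle_dunn_z(g, 1, 3), tolerance = 1e-12)
  expect_equal(d$z[d$group1 == "b" & d$group2 == "c"],
               oracle_dunn_z(g, 2, 3), tolerance = 1e-12)
  expect_equal(nrow(d), choose(3, 2))  # every unordered pair exactly once

  # Bonferroni is min(1, m * p) by definition
  d_bonf <- dunn_posthoc(g, adjust = "bonferroni")
  expect_equal(d_bonf$p_adjusted, pmin(1, 3 * d$p_value), tolerance = 1e-12)
})

test_that("b-on-w regression matches the normal-equations oracle", {
  w <- c(0.2, 0.35, 0.4, 0.55, 0.6, 0.8)
  # collinear points recover the line exactly
  fit0 <- regress_b_on_w(w, 0.1 + 0.5 * w)
  expect_equal(fit0$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit0$r_squared, 1, tolerance = 1e-12)

  set.seed(17)
  b <- 0.1 + 0.5 * w + rnorm(6, 0, 0.05)
  fit <- regress_b_on_w(w, b)
  o <- oracle_ols(w, b)
  expect_equal(fit$slope, o$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-10)
  expect_equal(fit$p_value, o$p_value, tolerance = 1e-10)

  # pairs with missing b are dropped, not propagated
  fit_na <- regress_b_on_w(c(w, 0.9), c(b, NA))
  expect_equal(fit_na$n_points, 6L)
})

test_that("coupled cohorts show a positive b-on-w slope; null cohorts stay null", {
  slope_of <- function(seed, ...) {
    coh <- generate_cohort(generator_params(...), seed = seed)
    w <- sapply(coh$series, function(x) compute_str(x, "whole")$fit$exponent)
    b <- sapply(coh$series, function(x) compute_lft(x)$b)
    regress_b_on_w(w, b)
  }
  coupled <- lapply(400 + 1:15, function(s) slope_of(s))
  expect_gt(median(sapply(coupled, `[[`, "slope")), 0)
  expect_gte(mean(sapply(coupled, `[[`, "slope") > 0), 0.8)
  # a true null removes every PEx effect: no immigration burst, no %FEV1
  # trend, no coupling (pure observation noise; note that the burst must go
  # too, because denser sampling around treatment alone raises both the
  # local time compression in the b fit and the realized w); a significantly
  # positive slope is then a type-I error and must stay rare
  null <- lapply(600 + 1:15, function(s) {
    slope_of(s, coupling = 0, fev1_decline = 0, fev1_recovery = 0,
             burst_multiplier = 1)
  })
  sig_pos <- sapply(null, function(f) f$slope > 0 && f$p_value < 0.05)
  expect_lte(mean(sig_pos), 0.2)
})

test_that("cohort summary reports n-1 sample statistics and flags absences", {
  str_fits <- data.frame(
    patient_id = rep(c("P1", "P2", "P3"), each = 3),
    subset = rep(c("whole", "chronic", "intermittent"), 3),
    w = c(0.3, 0.1, NA, 0.4, 0.2, NA, 0.5, 0.3, NA))
  smry <- summarize_cohort(str_fits)
  w_whole <- smry[smry$statistic == "w_whole", ]
  expect_equal(w_whole$mean, 0.4)
  expect_equal(w_whole$sd, 0.1)
  expect_equal(c(w_whole$min, w_whole$max), c(0.3, 0.5))
  # the intermittent subset has no fitted values -> flagged absent
  expect_true(smry[smry$statistic == "w_intermittent", ]$absent)
})
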