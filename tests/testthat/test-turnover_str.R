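test_that("moving-window accumulation matches the closed-form limits", {
  # static community: 5 identical samples of 7 taxa
  static <- matrix(TRUE, nrow = 7, ncol = 5)
  expect_equal(accumulate_moving_window(static)$mean_richness, rep(7, 5))

  # complete replacement: 2 unique taxa per sample, no recurrence
  repl <- matrix(FALSE, nrow = 12, ncol = 6)
  for (j in 1:6) repl[(2 * j - 1):(2 * j), j] <- TRUE
  curve <- accumulate_moving_window(repl)
  expect_equal(curve$mean_richness, c(2, 4, 6, 8, 10, 12))
  expect_equal(curve$n_windows, 6:1)

  fit <- fit_power(curve$window_lengths, curve$mean_richness)
  expect_equal(fit$c, 2, tolerance = 1e-12)
  expect_equal(fit$exponent, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_error(accumulate_moving_window(matrix(logical(0), 0, 0)), "empty")
  expect_error(accumulate_moving_window(matrix(FALSE, 3, 4)), "no taxon")
})

test_that("moving-window accumulation equals exhaustive window enumeration", {
  set.seed(101)
  for (rep in 1:30) {
    nt <- sample(2:20, 1)
    ns <- sample(3:8, 1)
    pres <- matrix(runif(nt * ns) < 0.3, nrow = nt)
    if (!any(pres)) pres[1, 1] <- TRUE
    got <- accumulate_moving_window(pres)$mean_richness
    expect_identical(got, oracle_moving_window(pres))
  }
})

test_that("mean cumulative richness is non-decreasing in window length", {
  set.seed(202)
  for (rep in 1:25) {
    pres <- matrix(runif(15 * 10) < runif(1, 0.1, 0.9), nrow = 15)
    if (!any(pres)) pres[3, 3] <- TRUE
    expect_true(all(diff(accumulate_moving_window(pres)$mean_richness) >=
                      -1e-12))
  }
})

test_that("power fit is exact on a noiseless power law and handles degeneracy", {
  x <- 1:6
  fit <- fit_power(x, 3 * x^0.5)
  expect_equal(fit$c, 3, tolerance = 1e-10)
  expect_equal(fit$exponent, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$df_den, 4L)

  const <- fit_power(1:5, rep(7, 5))
  expect_true(const$degenerate)
  expect_equal(const$exponent, 0)
  expect_equal(const$c, 7)
  expect_equal(const$r_squared, 1)
  expect_true(is.na(const$p_value))

  expect_error(fit_power(1:2, 1:2), "at least 3")
  expect_error(fit_power(c(0, 1, 2), c(1, 2, 3)), "strictly positive")
  expect_error(fit_power(1:3, c(1, -2, 3)), "strictly positive")
})

test_that("power-fit slope estimator is unbiased under lognormal noise", {
  set.seed(303)
  x <- 1:50
  slopes <- replicate(200, {
    y <- 1.5 * x^0.4 * exp(rnorm(50, 0, 0.05))
    fit_power(x, y)$exponent
  })
  expect_lt(abs(mean(slopes) - 0.4), 0.01)
})

test_that("power fit agrees with the normal-equations oracle", {
  set.seed(404)
  x <- sort(runif(12, 1, 40))
  y <- 2.2 * x^0.7 * exp(rnorm(12, 0, 0.2))
  fit <- fit_power(x, y)
  o <- oracle_ols(log(x), log(y))
  expect_equal(fit$exponent, o$slope, tolerance = 1e-10)
  expect_equal(fit$c, exp(o$intercept), tolerance = 1e-10)
  expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-10)
  expect_equal(fit$f_statistic, o$f_statistic, tolerance = 1e-8)
  expect_equal(fit$p_value, o$p_value, tolerance = 1e-10)
})

test_that("duplicating every taxon row doubles c and leaves w unchanged", {
  set.seed(505)
  pres <- matrix(runif(10 * 8) < 0.4, nrow = 10)
  pres[1, ] <- TRUE
  c1 <- accumulate_moving_window(pres)
  c2 <- accumulate_moving_window(rbind(pres, pres))
  expect_equal(c2$mean_richness, 2 * c1$mean_richness)
  f1 <- fit_power(c1$window_lengths, c1$mean_richness)
  f2 <- fit_power(c2$window_lengths, c2$mean_richness)
  expect_equal(f2$exponent, f1$exponent, tolerance = 1e-12)
  expect_equal(f2$c, 2 * f1$c, tolerance = 1e-10)
})

test_that("compute_str reproduces a hand-enumerated fixture end to end", {
  # 4 taxa x 8 samples, worked by the union oracle + normal equations
  pres <- rbind(c(1, 1, 1, 1, 1, 1, 1, 1),
                c(1, 0, 1, 0, 1, 0, 1, 0),
                c(0, 0, 1, 1, 0, 0, 1, 1),
                c(0, 1, 0, 0, 0, 1, 0, 0)) == 1
  rownames(pres) <- paste0("t", 1:4)
  s <- make_series(pres * 0.25)
  res <- compute_str(s, "whole")
  expected_S <- oracle_moving_window(pres)
  expect_equal(res$curve$mean_richness, expected_S)
  o <- oracle_ols(log(1:8), log(expected_S))
  expect_equal(res$fit$exponent, o$slope, tolerance = 1e-10)
  expect_equal(res$fit$c, exp(o$intercept), tolerance = 1e-10)
})

test_that("static chronic core gives w = 0 and subsets order correctly", {
  # static community: all taxa in every sample -> zero turnover everywhere
  ab <- matrix(1, nrow = 7, ncol = 6,
               dimnames = list(paste0("t", 1:7), NULL))
  s <- make_series(ab)
  prof <- compute_persistence(s)
  r_whole <- compute_str(s, "whole", prof)
  r_chronic <- compute_str(s, "chronic", prof)
  expect_equal(r_whole$fit$exponent, 0)
  expect_equal(r_chronic$fit$exponent, 0)
  # no intermittent taxa: explicit empty-subset result, not a crash
  r_int <- compute_str(s, "intermittent", prof)
  expect_equal(r_int$status, "empty_subset")
  expect_true(is.na(str_fit_table(list(r_int))$w))
})

test_that("immigration-driven intermittents turn over faster than the chronic core", {
  set.seed(77)
  ok <- 0L
  for (rep in 1:10) {
    g <- generate_patient(generator_params(), seed = 7000 + rep, pex = TRUE)
    prof <- compute_persistence(g$series)
    w_c <- compute_str(g$series, "chronic", prof)$fit$exponent
    w_i <- compute_str(g$series, "intermittent", prof)$fit$exponent
    if (w_i > w_c) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("elapsed-days axis starts at one mean interval and spans the series", {
  s <- make_series(matrix(1, 3, 5), days = c(0, 10, 20, 40, 60))
  curve <- accumulate_moving_window(presence_matrix(s))
  tt <- str_time_axis(curve, s$sample_dates, "days")
  expect_equal(tt[1], 15)            # mean inter-sample interval
  expect_equal(tt[5], 60 + 15)       # full span + one interval
  expect_true(all(diff(tt) > 0))
})
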