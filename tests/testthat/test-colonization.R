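test_that("persistence follows the modified Leeds criterion with exclusive cutoff", {
  # one taxon in 6/10 samples (chronic), one in 5/10 (intermittent at the
  # boundary), one never detected (excluded), one always present
  ab <- rbind(tax6 = c(rep(1, 6), rep(0, 4)),
              tax5 = c(rep(0, 5), rep(1, 5)),
              tax0 = rep(0, 10),
              core = rep(5, 10))
  prof <- compute_persistence(make_series(ab))
  expect_setequal(prof$taxon_id, c("tax6", "tax5", "core"))
  expect_equal(prof$persistence[prof$taxon_id == "tax6"], 0.6)
  expect_equal(prof$label[prof$taxon_id == "tax6"], "chronic")
  expect_equal(prof$persistence[prof$taxon_id == "tax5"], 0.5)
  expect_equal(prof$label[prof$taxon_id == "tax5"], "intermittent")
  expect_equal(prof$label[prof$taxon_id == "core"], "chronic")
  # persistence = n_detected / n_samples for every profile
  expect_equal(prof$persistence, prof$n_detected / prof$n_samples)
  # mean abundance when present is a valid proportion
  expect_true(all(prof$mean_abundance > 0 & prof$mean_abundance <= 1))
})

test_that("label counts partition detected taxa and are monotone in the cutoff", {
  set.seed(21)
  ab <- matrix(rbinom(300, 1, 0.4) * runif(300, 0.1, 1), nrow = 30)
  ab[1, ] <- 1  # guarantee non-zero columns
  rownames(ab) <- paste0("t", 1:30)
  s <- make_series(ab)
  prof <- compute_persistence(s)
  cnt <- count_by_label(prof)
  expect_equal(unname(sum(cnt)), nrow(prof))

  cutoffs <- c(0.2, 0.4, 0.5, 0.6, 0.8)
  n_chronic <- sapply(cutoffs, function(cc) {
    p <- compute_persistence(s, cohort_config(chronic_persistence_cutoff = cc))
    unname(count_by_label(p)["n_chronic"])
  })
  expect_true(all(diff(n_chronic) <= 0))
})

test_that("removing absence samples strictly increases a taxon's persistence", {
  ab <- rbind(target = c(1, 0, 1, 0, 1, 0),
              core = rep(1, 6))
  s_full <- make_series(ab)
  p_full <- compute_persistence(s_full)
  # drop two samples in which the target is absent
  s_sub <- make_series(ab[, c(1, 3, 5, 6)], days = c(0, 28, 56, 70))
  p_sub <- compute_persistence(s_sub)
  expect_gt(p_sub$persistence[p_sub$taxon_id == "target"],
            p_full$persistence[p_full$taxon_id == "target"])
})

test_that("PAR fit recovers an exact log-linear relationship", {
  prof <- data.frame(taxon_id = c("a", "b", "c"),
                     n_detected = c(2, 6, 10), n_samples = 10,
                     persistence = c(0.2, 0.6, 1.0),
                     mean_abundance = c(1e-3, 1e-2, 1e-1),
                     label = c("intermittent", "chronic", "chronic"),
                     stringsAsFactors = FALSE)
  fit <- fit_par(prof)
  expect_equal(fit$slope, 2.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("PAR slope is recovered within its 95% CI under noise", {
  set.seed(33)
  n <- 20
  persistence <- runif(n, 0.05, 1)
  log10_ab <- -4 + 3.0 * persistence + rnorm(n, 0, 0.1)
  prof <- data.frame(taxon_id = paste0("t", 1:n), n_detected = 1,
                     n_samples = 20, persistence = persistence,
                     mean_abundance = 10^log10_ab,
                     label = "intermittent", stringsAsFactors = FALSE)
  fit <- fit_par(prof)
  ci <- fit$slope + c(-1, 1) * qt(0.975, fit$df_den) * fit$slope_se
  expect_gt(3.0, ci[1])
  expect_lt(3.0, ci[2])
})

test_that("PAR preconditions are enforced", {
  prof2 <- data.frame(taxon_id = c("a", "b"), n_detected = c(1, 2),
                      n_samples = 4, persistence = c(0.25, 0.5),
                      mean_abundance = c(0.1, 0.2),
                      label = "intermittent", stringsAsFactors = FALSE)
  expect_error(fit_par(prof2), "at least 3")
  prof3 <- rbind(prof2, data.frame(taxon_id = "c", n_detected = 1,
                                   n_samples = 4, persistence = 0.25,
                                   mean_abundance = 0.3,
                                   label = "intermittent"))
  prof3$persistence <- 0.5
  expect_error(fit_par(prof3), "zero variance")
})

test_that("chronic-regime taxa are labelled chronic at the binomial rate", {
  # presence prob 0.9 over 22 samples: P(persistence > 0.5) = P(X >= 12)
  p_theory <- 1 - pbinom(11, 22, 0.9)
  expect_gt(p_theory, 0.99)  # the regime guarantees near-certain labelling
  set.seed(55)
  n_rep <- 60
  hits <- 0L
  for (r in seq_len(n_rep)) {
    pres <- rbinom(22, 1, 0.9)
    ab <- rbind(chronic = pres * 1, anchor = rep(1, 22))
    prof <- compute_persistence(make_series(ab))
    if ("chronic" %in% prof$taxon_id &&
        prof$label[prof$taxon_id == "chronic"] == "chronic") hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)  # empirical rate consistent with >= 0.99
})
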