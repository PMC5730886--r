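test_that("normalisation anchors traces and conserves species", {
  k <- log(2) / 3
  tc <- simulate_phospho_timecourse(k, t_step = 2, n_steps = 10,
                                    n_resonances = 4)
  norm <- normalize_timecourse(tc)
  first <- norm[norm$species == "disappearing" & norm$time_min == 0, ]
  expect_true(all(first$norm_height == 1))
  # per residue, (1 - disappearing) and appearing agree point-wise on
  # noiseless input up to the appearing-anchor plateau factor
  wide <- tidyr::pivot_wider(norm[, c("residue", "species", "time_min",
                                      "fraction")],
                             names_from = "species",
                             values_from = "fraction")
  plateau <- 1 - exp(-k * max(tc$time_min))
  expect_equal(wide$appearing * plateau, wide$disappearing,
               tolerance = 1e-12)
})

test_that("zero anchors exclude a residue with a warning", {
  tc <- simulate_phospho_timecourse(0.2, t_step = 2, n_steps = 6,
                                    n_resonances = 3)
  tc$height[tc$residue == 2 & tc$species == "disappearing" &
              tc$time_min == 0] <- 0
  expect_warning(norm <- normalize_timecourse(tc), "zero anchor")
  expect_false(2 %in% norm$residue)
})

test_that("aggregation averages across resonances with population
           spread", {
  tc <- simulate_phospho_timecourse(0.3, t_step = 2, n_steps = 8,
                                    n_resonances = 9)
  curve <- aggregate_progress(normalize_timecourse(tc))
  # noiseless: all resonances identical after normalisation
  expect_true(all(curve$sd < 1e-12))
  expect_equal(attr(curve, "n_resonances"), 9)

  two <- tibble::tibble(residue = rep(1:2, each = 1), species = "appearing",
                        time_min = 5, fraction = c(0.4, 0.6))
  agg <- aggregate_progress(two, min_resonances = 2)
  expect_equal(agg$fraction, 0.5)
  expect_equal(agg$sd, 0.1)

  expect_error(aggregate_progress(normalize_timecourse(
    simulate_phospho_timecourse(0.3, n_resonances = 3)),
    min_resonances = 9), "need >= 9")
})

test_that("increment time stamps default to the midpoint convention", {
  expect_equal(increment_times(3, 4), c(2, 6, 10))
  expect_equal(increment_times(3, 4, stamp = "start"), c(0, 4, 8))
})

test_that("first-order fit reproduces the half-time identity", {
  k <- log(2) / 2
  curve <- tibble::tibble(time_min = seq(0, 12, by = 1),
                          fraction = 1 - exp(-k * seq(0, 12, by = 1)))
  fit <- fit_rate(curve)
  expect_equal(fit$t50, 2, tolerance = 1e-9)
  # model-free interpolation agrees with the model fit on clean input
  expect_equal(fit$t50_interp, fit$t50, tolerance = 0.02)

  # end-to-end through normalisation: the appearing-species anchor is
  # the last spectrum, so the course must run to effective completion
  tc <- simulate_phospho_timecourse(k, t_step = 1, n_steps = 40,
                                    n_resonances = 9)
  fit2 <- fit_rate(aggregate_progress(normalize_timecourse(tc)))
  expect_equal(fit2$t50, 2, tolerance = 1e-3)
})

test_that("a noisy nine-resonance course recovers the half-time within
           10 percent", {
  k <- log(2) / 2
  tc <- simulate_phospho_timecourse(k, t_step = 4, n_steps = 16,
                                    n_resonances = 9,
                                    noise = noise_model("gaussian", 0.05,
                                                        seed = 1))
  norm <- normalize_timecourse(tc)
  expect_true(all(norm$norm_height > -0.2 & norm$norm_height < 1.2))
  fit <- fit_rate(aggregate_progress(norm))
  expect_equal(fit$t50, 2, tolerance = 0.1)
})

test_that("fold-acceleration is a half-time ratio with inverse
           symmetry", {
  fast <- structure(list(t50 = 2), class = "rate_fit")
  slow <- structure(list(t50 = 90), class = "rate_fit")
  slower <- structure(list(t50 = 275), class = "rate_fit")
  expect_equal(fold_acceleration(fast, fast), 1)
  expect_equal(fold_acceleration(fast, slow), 45)
  expect_equal(fold_acceleration(fast, slower), 137.5)
  expect_equal(fold_acceleration(fast, slow) *
                 fold_acceleration(slow, fast), 1)
})
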