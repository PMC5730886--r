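paper_taus <- c(5.2, 10.4, 20.8, 41.6, 83.2, 166.4)

test_that("noiseless exchange rates are recovered to optimizer
           tolerance", {
  series <- simulate_cleanex_series(c(`8` = 5), r1_amide = 2,
                                    r1_water = 0.6,
                                    mixing_times_ms = paper_taus)
  fit <- fit_exchange_rate(series, r1_water = 0.6)
  expect_equal(fit$k, 5, tolerance = 1e-6)
  expect_equal(fit$r1_amide, 2, tolerance = 1e-4)
  expect_equal(fit$flag, "ok")
})

test_that("rate estimates ignore the global intensity scale", {
  series <- simulate_cleanex_series(3, reference = 1e6,
                                    mixing_times_ms = paper_taus)
  scaled <- series
  scaled$intensity <- scaled$intensity * 42
  scaled$reference <- scaled$reference * 42
  expect_equal(fit_exchange_rate(scaled)$k, fit_exchange_rate(series)$k,
               tolerance = 1e-10)
})

test_that("degenerate series are flagged rather than fitted", {
  zero <- tibble::tibble(residue = 1, mixing_time_ms = paper_taus,
                         intensity = 0, reference = 1e6)
  fit <- fit_exchange_rate(zero)
  expect_equal(fit$k, 0)
  expect_equal(fit$flag, "zero_signal")
  expect_error(fit_exchange_rate(zero[1:2, ]), "mixing times")
})

test_that("initial-rate mode approximates k from the early slope", {
  series <- simulate_cleanex_series(4, r1_amide = 2, r1_water = 0.6,
                                    mixing_times_ms = paper_taus)
  fit <- fit_exchange_rate(series, mode = "initial_rate")
  expect_equal(fit$k, 4, tolerance = 0.15)
})

test_that("the buildup curve rises then decays, peaking earlier for
           faster decay", {
  tau <- seq(0.001, 1, by = 0.001)
  slow <- cleanex_buildup(tau, 5, 2, 0.6)
  fast <- cleanex_buildup(tau, 30, 12, 0.6)
  peak_pos <- function(y) tau[which.max(y)]
  d <- diff(slow)
  expect_true(all(d[tau[-1] < peak_pos(slow)] > 0))
  expect_true(all(d[tau[-1] > peak_pos(slow) + 0.01] < 0))
  expect_lt(peak_pos(fast), peak_pos(slow))
})

test_that("protection analysis flags bound-state protection", {
  apo <- fit_exchange_rate(simulate_cleanex_series(c(10, 4, 1),
                                                   mixing_times_ms = paper_taus))
  # identical tables: no protection anywhere
  same <- protection_analysis(apo, apo)
  expect_true(all(same$delta_k == 0))
  expect_true(all(same$protection == "none"))

  # tenfold slower exchange when bound: protected at the default rule
  bound <- apo; bound$k <- apo$k / 10
  prot <- protection_analysis(apo, bound)
  expect_true(all(prot$protection == "protected"))

  # five-residue exposed-loop fixture: high apo rates, silent bound
  loop_apo <- fit_exchange_rate(
    simulate_cleanex_series(setNames(c(12, 9, 15, 8, 11), 62:66),
                            mixing_times_ms = paper_taus))
  loop_bound <- tibble::tibble(residue = 62:66, k = 0, k_se = 0,
                               r1_amide = NA_real_, flag = "zero_signal")
  loop <- protection_analysis(loop_apo, loop_bound)
  expect_true(all(loop$protection == "fully_protected"))
})

test_that("hetNOE is the on/off ratio with propagated uncertainty", {
  on <- make_random_peaklist(8, seed = 6)
  off <- on
  noe <- compute_hetnoe(on, off)
  expect_true(all(noe$value == 1))
  expect_true(all(noe$sigma == 0))

  # negative on-resonance intensity passes through (flexible tail)
  on2 <- on; on2$height <- -0.2 * off$height
  expect_true(all(compute_hetnoe(on2, off)$value == -0.2))

  # scaling i_on by c scales the value by exactly c
  on3 <- on; on3$height <- on$height * 0.77
  expect_equal(compute_hetnoe(on3, off)$value, rep(0.77, 8))

  # first-order error propagation
  noe4 <- compute_hetnoe(on3, off, noise_on = 1e4, noise_off = 2e4)
  expected <- abs(noe4$value) *
    sqrt((1e4 / noe4$i_on)^2 + (2e4 / noe4$i_off)^2)
  expect_equal(noe4$sigma, expected)

  off5 <- off; off5$height[3] <- 0
  expect_warning(res5 <- compute_hetnoe(on, off5), "zero off-resonance")
  expect_equal(nrow(res5), 7)
})
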