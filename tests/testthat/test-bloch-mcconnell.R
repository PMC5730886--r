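test_that("the generator has the expected closed-form structure", {
  # no minor state, no irradiation: block-diagonal with -r1 on Mz
  p0 <- make_exchange_params(p_minor = 0, k_ex = 1, r1 = 1.25)
  L <- evolution_matrix(p0, 1, b1_hz = 0, offset_ppm = 150)
  expect_equal(L[1:3, 4:6], diag(1, 3))       # k_minor_to_major = k_ex
  expect_equal(L[4:6, 1:3], matrix(0, 3, 3))  # k_major_to_minor = 0
  expect_equal(L[3, 3], -1.25)
  expect_equal(L[3, 1:2], c(0, 0))

  # detailed balance holds exactly by construction
  p <- make_exchange_params(p_minor = 0.3, k_ex = 80)
  L <- evolution_matrix(p, 1, 25, 118)
  k_fwd <- L[4, 1]
  k_rev <- L[1, 4]
  expect_equal(k_fwd / k_rev, 0.3 / 0.7)
})

test_that("eigenvalues of random valid generators never grow", {
  withr::with_seed(11, {
    for (i in 1:100) {
      pp <- draw_valid_params()
      L <- evolution_matrix(pp, 1, runif(1, 5, 50), runif(1, 102, 134))
      expect_lte(max(Re(eigen(L, only.values = TRUE)$values)), 1e-10)
    }
  })
})

test_that("propagation reproduces analytic limits", {
  p0 <- make_exchange_params(p_minor = 0, k_ex = 1, r1 = 1.25)
  L <- evolution_matrix(p0, 1, 0, 150)
  m0 <- c(0, 0, 1, 0, 0, 0)
  expect_identical(propagate(m0, L, 0), m0)
  expect_equal(propagate(m0, L, 0.4)[3], exp(-0.5), tolerance = 1e-12)

  # strong on-resonance irradiation saturates Mz once the transverse
  # decay has damped the nutation (w1 >> r2 >> 1/t_ex)
  p <- make_exchange_params(p_minor = 0, k_ex = 1, r1 = 4, r2a = 40)
  mz <- vapply(c(200, 2000), function(b1) {
    propagate(m0, evolution_matrix(p, 1, b1, 120), 0.4)[3]
  }, numeric(1))
  expect_true(all(abs(mz) < 1e-3))
})

test_that("matrix-exponential propagation matches the RK4 oracle", {
  withr::with_seed(23, {
    for (i in 1:20) {
      pp <- draw_valid_params()
      L <- evolution_matrix(pp, 1, runif(1, 5, 50),
                            pp$residues$shift_major_n + runif(1, -3, 3))
      m0 <- c(0, 0, 1 - pp$p_minor, 0, 0, pp$p_minor)
      expect_equal(propagate(m0, L, 0.4), rk4_propagate(m0, L, 0.4),
                   tolerance = 1e-8)
    }
  })
})

test_that("the C++ profile equals the R-level propagation point-wise", {
  pp <- make_exchange_params(mhz = 950)
  scheme <- cest_scheme(b1_fields_hz = c(12.5, 50),
                        offsets_ppm = seq(114, 126, length.out = 31))
  prof <- cest_profile(pp, scheme, 1)
  m0 <- c(0, 0, 1 - pp$p_minor, 0, 0, pp$p_minor)
  manual <- purrr::pmap_dbl(prof[, c("b1_hz", "offset_ppm")],
    function(b1_hz, offset_ppm) {
      L <- evolution_matrix(pp, 1, b1_hz, offset_ppm)
      propagate(m0, L, scheme$t_ex)[3] / (1 - pp$p_minor)
    })
  expect_equal(prof$i_over_i0, manual, tolerance = 1e-10)
})

test_that("profiles have the correct baseline and stay physical", {
  pp <- make_exchange_params(p_minor = 0.0068, k_ex = 63, r1 = 1.2)
  scheme <- cest_scheme(b1_fields_hz = 12.5,
                        offsets_ppm = seq(60, 180, length.out = 121))
  prof <- cest_profile(pp, scheme, 1)
  far <- abs(prof$offset_ppm - 120) > 40
  expect_equal(prof$i_over_i0[far],
               rep(exp(-1.2 * 0.4), sum(far)), tolerance = 1e-3)
  expect_true(all(prof$i_over_i0 >= -0.01 & prof$i_over_i0 <= 1.01))
})

test_that("dip detection finds the right number and location of dips", {
  scheme <- cest_scheme(b1_fields_hz = 25)
  # single state: exactly one dip
  p0 <- make_exchange_params(p_minor = 0, k_ex = 1)
  one <- cest_profile(p0, scheme, 1)
  d1 <- detect_dips(one, noise = 1e-3)
  expect_equal(nrow(d1), 1)
  step <- diff(scheme$offsets_ppm[1:2])
  expect_lt(abs(d1$offset_ppm - 120), 2 * step)

  # two-state wt-like: two dips separated by ~|dw|; the apparent minor
  # position is pulled slightly by the sloping tail of the major dip,
  # so allow two grid steps
  pp <- make_exchange_params(p_minor = 0.0068, k_ex = 63, dw = 2,
                             mhz = 950)
  two <- cest_profile(pp, scheme, 1)
  dips <- detect_dips(two, noise = 1e-3)
  expect_equal(nrow(dips), 2)
  step <- diff(scheme$offsets_ppm[1:2])
  expect_lt(abs(abs(diff(dips$offset_ppm)) - 2), 2 * step)

  # flat profile: nothing
  flat <- tibble::tibble(offset_ppm = seq(102, 134, 0.5), i_over_i0 = 1)
  expect_equal(nrow(detect_dips(flat)), 0)
})

test_that("van't Hoff extrapolation behaves like a two-point line", {
  # round-trip returns the inputs
  a <- c(318.15, 0.045); b <- c(298.15, 0.013)
  expect_equal(extrapolate_occupancy(a, b, 318.15), 0.045)
  expect_equal(extrapolate_occupancy(a, b, 298.15), 0.013)

  # same K at both temperatures: flat line
  expect_equal(extrapolate_occupancy(c(300, 0.05), c(330, 0.05), 280),
               0.05)

  # positive transition enthalpy: occupancy rises with temperature
  ts <- seq(280, 340, by = 10)
  ps <- vapply(ts, function(tt) extrapolate_occupancy(a, b, tt),
               numeric(1))
  expect_true(all(diff(ps) > 0))

  # scaling the hot/cold slope onto the wt 45C point keeps the cold
  # occupancy below 0.68%
  lk <- function(p) log(p / (1 - p))
  slope <- (lk(0.045) - lk(0.013)) / (1 / 318.15 - 1 / 298.15)
  wt25 <- {
    lk45 <- lk(0.0068)
    k <- exp(lk45 + slope * (1 / 298.15 - 1 / 318.15))
    k / (1 + k)
  }
  expect_lt(wt25, 0.0068)

  expect_error(extrapolate_occupancy(c(300, 0.1), c(300, 0.2), 310),
               "temperatures must differ")
})
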