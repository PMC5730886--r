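test_that("generators are reproducible under a fixed seed", {
  nz <- noise_model("gaussian", 0.01, seed = 4)
  p <- make_exchange_params(mhz = 950)
  sch <- cest_scheme(b1_fields_hz = 25,
                     offsets_ppm = seq(110, 130, length.out = 41))
  expect_identical(simulate_cest_dataset(p, sch, nz)$i_over_i0,
                   simulate_cest_dataset(p, sch, nz)$i_over_i0)
  expect_identical(simulate_cleanex_series(c(5, 2), noise = nz),
                   simulate_cleanex_series(c(5, 2), noise = nz))
  expect_identical(simulate_phospho_timecourse(0.3, noise = nz),
                   simulate_phospho_timecourse(0.3, noise = nz))
  expect_identical(simulate_dsc_endotherm(83, noise = nz),
                   simulate_dsc_endotherm(83, noise = nz))
  # and the global RNG stream is left untouched
  withr::with_seed(99, {
    before <- runif(1)
    set.seed(99); invisible(simulate_cleanex_series(5, noise = nz))
    expect_identical(runif(1), before)
  })
})

test_that("a single-state system shows exactly one saturation dip", {
  p0 <- make_exchange_params(p_minor = 0, k_ex = 1, mhz = 950)
  sch <- cest_scheme(b1_fields_hz = 25)
  ds <- simulate_cest_dataset(p0, sch)
  dips <- detect_dips(ds[ds$b1_hz == 25, ], noise = 1e-3)
  expect_equal(nrow(dips), 1)
  step <- diff(sch$offsets_ppm[1:2])
  expect_lt(abs(dips$offset_ppm - 120), 2 * step)
})

test_that("CLEANEX generator matches its closed form", {
  # zero exchange: exactly zero intensity before noise
  s0 <- simulate_cleanex_series(0)
  expect_true(all(s0$intensity == 0))
  expect_error(simulate_cleanex_series(-1), "rates")

  # doubling k doubles the initial slope of the buildup
  tau <- 1e-6
  s1 <- cleanex_buildup(tau, 5, 2, 0.6) / tau
  s2 <- cleanex_buildup(tau, 10, 2, 0.6) / tau
  expect_equal(s2 / s1, 2, tolerance = 1e-4)
  expect_equal(s1, 5, tolerance = 1e-4)
})

test_that("phosphorylation time course obeys first-order identities", {
  k <- log(2) / 2
  tc <- simulate_phospho_timecourse(k, t_step = 1, n_steps = 8,
                                    n_resonances = 1,
                                    noise = noise_model("none"))
  dis <- tc[tc$species == "disappearing", ]
  app <- tc[tc$species == "appearing", ]
  # 50% conversion at exactly t = 2 min; traces follow the exponential
  expect_equal(dis$height[dis$time_min == 2] / dis$height[1], 0.5)
  expect_equal(dis$height / dis$height[1], exp(-k * dis$time_min))
  late <- app$time_min > 0
  expect_equal(app$height[late] / (1 - exp(-k * app$time_min[late])),
               rep(app$height[2] / (1 - exp(-k * app$time_min[2])),
                   sum(late)))

  # zero rate: flat disappearing trace at its initial value
  flat <- simulate_phospho_timecourse(0, t_step = 4, n_steps = 5,
                                      n_resonances = 2)
  d <- flat[flat$species == "disappearing", ]
  expect_true(all(tapply(d$height, d$residue,
                         function(h) length(unique(h))) == 1))
})

test_that("DSC generator conserves enthalpy and peaks at T_m", {
  grid <- seq(40, 110, by = 0.05)
  endo <- simulate_dsc_endotherm(83, dh_cal = 300, dh_vh = 300,
                                 t_grid_c = grid)
  expect_equal(endo$temp_c[which.max(endo$cp)], 83, tolerance = 0.051)
  integral <- sum(diff(endo$temp_c) *
                    (head(endo$cp, -1) + tail(endo$cp, -1)) / 2)
  expect_equal(integral, 300, tolerance = 0.01 * 300)
  expect_warning(simulate_dsc_endotherm(83, t_grid_c = seq(80, 90, 0.1)),
                 "span")
})
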