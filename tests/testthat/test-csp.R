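test_that("weighted CSP applies the 1/5 nitrogen weighting", {
  expect_equal(weighted_csp(0, 0), 0)
  expect_equal(weighted_csp(0, 1), 0.2)
  expect_equal(weighted_csp(0.3, 0), 0.3)
  expect_equal(weighted_csp(0.3, 1.5), sqrt(0.09 + 0.09))
})

test_that("weighted CSP is a norm", {
  withr::with_seed(2, {
    dh <- rnorm(50); dn <- rnorm(50)
    v <- weighted_csp(dh, dn)
    expect_true(all(v >= 0))
    expect_identical(v == 0, dh == 0 & dn == 0)
    expect_equal(weighted_csp(-dh, dn), v)
    expect_equal(weighted_csp(dh, -dn), v)
  })
})

test_that("csp_map computes per-residue differences and flags gaps", {
  a <- make_random_peaklist(10, seed = 3)
  expect_true(all(csp_map(a, a)$weighted_csp == 0))

  # two-residue fixture with hand-computed CSPs
  b <- a
  b$shift_h[1] <- b$shift_h[1] + 0.1
  b$shift_n[2] <- b$shift_n[2] - 1.0
  m <- csp_map(a, b)
  expect_equal(m$weighted_csp[1], 0.1)
  expect_equal(m$weighted_csp[2], 0.2)
  expect_equal(m$weighted_csp[3:10], rep(0, 8))

  # a residue missing from the bound list is flagged, not dropped
  m2 <- csp_map(a, b[-1, ])
  expect_equal(m2$status[m2$residue_number == 1], "only_a")
  expect_true(is.na(m2$weighted_csp[m2$residue_number == 1]))

  expect_error(csp_map(a, make_random_peaklist(3, seed = 1) |>
                         dplyr::mutate(residue_number = 100:102)),
               "no assigned residues")
})

test_that("largest CSPs land on the residues with the largest shift
           differences", {
  res <- draw_cest_residues(8, seed = 9)
  base <- peak_list(data.frame(
    residue_number = res$residue, residue_code = "L",
    shift_n = res$shift_major_n, shift_h = 8, height = 1e6))
  shifted <- base
  shifted$shift_n <- res$shift_major_n + res$delta_shift_n
  m <- csp_map(base, shifted)
  expect_equal(order(m$weighted_csp), order(abs(res$delta_shift_n)))
})

test_that("broadening classes follow the mean/stdv rule", {
  free <- make_random_peaklist(10, seed = 4)
  ratios <- c(rep(1, 8), 0.4, 0.3)
  bound <- free
  bound$height <- free$height * ratios
  fp <- broadening_footprint(free, bound)
  # arithmetic oracle evaluated directly
  m <- mean(ratios); s <- sqrt(mean((ratios - m)^2))
  expected <- ifelse(ratios < m - s, "strong",
                     ifelse(ratios < m - 0.5 * s, "moderate", "none"))
  expect_equal(fp$class, expected)
  expect_equal(attr(fp, "mean"), m)
  expect_equal(attr(fp, "stdv"), s)

  # degenerate spread: all ratios equal, all classes none
  fp0 <- broadening_footprint(free, free)
  expect_true(all(fp0$class == "none"))

  # affine invariance: rescaling bound heights leaves classes unchanged
  bound2 <- bound; bound2$height <- bound$height * 17
  expect_equal(broadening_footprint(free, bound2)$class, fp$class)

  # a residue vanished in the bound spectrum is strong evidence
  fp3 <- broadening_footprint(free, bound[-10, ])
  expect_equal(fp3$class[fp3$residue_number == 10], "strong")
  expect_equal(fp3$intensity_ratio[fp3$residue_number == 10], 0)
})

test_that("minor_fraction is the normalised intensity share", {
  expect_equal(minor_fraction(12, 88), 0.12)
  expect_equal(minor_fraction(0, 5), 0)
  expect_equal(minor_fraction(3, 3), 0.5)
  expect_equal(minor_fraction(12, 88) + minor_fraction(88, 12), 1)
  expect_error(minor_fraction(0, 0), "zero")
  expect_error(minor_fraction(-1, 2), ">= 0")
})
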