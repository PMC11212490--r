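test_that("length extrapolation matches the linear length model", {
  # identity at the reference length, for a spread of values
  for (x in c(-30, -5, 0, 2.5))
    expect_identical(length_extrapolate(x, 24), x)
  expect_identical(length_extrapolate(0, 7), 0)
  # hand evaluation: factor (a_l*24 + b_l)/(a_l*12 + b_l) = 2.3612
  expect_equal(length_extrapolate(-5, 12), -11.806, tolerance = 1e-3 / 11.8)
  expect_error(length_extrapolate(-5, 6), "length")
  expect_error(length_extrapolate(-5, 25), "length")
  expect_error(length_extrapolate(NaN, 12), "finite")
})

test_that("the extrapolation factor amplifies short peptides monotonically", {
  factors <- vapply(7:24, function(L) length_extrapolate(-1, L) / -1,
                    numeric(1))
  expect_true(all(diff(factors) < 0))  # shrinks toward 1 as L grows
  expect_equal(factors[length(factors)], 1)
  expect_gt(factors[1], 5.4)           # about 5.46 at L = 7
  expect_lt(factors[1], 5.5)
  expect_true(all(abs(vapply(7:24, function(L)
    length_extrapolate(-3, L), numeric(1))) >= 3))
})

test_that("charge adjustment shifts by 0.93 kJ/mol per unit charge", {
  expect_identical(charge_adjust(-5, 0), -5)
  expect_equal(charge_adjust(-5, 2), -6.86)
  expect_equal(charge_adjust(-5, -1), -4.07)
  expect_message(charge_adjust(-5, 5), "caution")
  expect_message(charge_adjust(-5, -2), "caution")
  expect_error(charge_adjust(-5, 1.5), "integer")
})

test_that("vesicle strain follows 1/R^2 + 2/R and vanishes for flat membranes", {
  expect_identical(vesicle_strain(Inf), 0)
  expect_equal(vesicle_strain(50), 0.0404)
  expect_equal(vesicle_strain(1), 3)
  r <- c(5, 10, 20, 50, 100, 500)
  expect_true(all(diff(vesicle_strain(r)) < 0))
  expect_error(vesicle_strain(0), "positive")
  expect_error(vesicle_strain(-3), "positive")
})

test_that("binding free energy is the affine map plus strain-scaled curvature", {
  expect_equal(binding_free_energy(0, Inf), 12.27)
  expect_equal(binding_free_energy(-10, 50), -28.48, tolerance = 0.01 / 28)
  expect_equal(binding_free_energy(-6.4, 50), -13.81, tolerance = 0.01 / 13)
  # affine in ddf_eff: slope alpha on flat, alpha + strain/eps_ref at R = 50
  slope_flat <- binding_free_energy(1, Inf) - binding_free_energy(0, Inf)
  slope_50 <- binding_free_energy(1, 50) - binding_free_energy(0, 50)
  expect_equal(slope_flat, 3.83)
  expect_equal(slope_50, 3.83 + 0.0404 / 0.165)
  x <- seq(-20, 5, by = 2.5)
  expect_equal(binding_free_energy(x, 50),
               slope_50 * x + 12.27, tolerance = 1e-12)
})

test_that("binding probability is a bounded decreasing sigmoid with the exact midpoint", {
  cst <- pmi_constants()
  mid <- -cst$thermal_energy * log(cst$ns_over_nm)
  expect_equal(binding_probability(mid), 0.5)
  expect_lt(binding_probability(60), 1e-13)
  expect_equal(binding_probability(-28.48), 0.95, tolerance = 0.005 / 0.95)
  grid <- seq(-80, 80, by = 1)
  p <- binding_probability(grid)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) < 0))
  # extreme arguments saturate without overflow or NaN
  expect_identical(binding_probability(1e6) < 1e-300, TRUE)
  expect_equal(binding_probability(-1e6), 1)
})

test_that("classification partitions the free-energy axis with inclusive sensor bounds", {
  expect_identical(as.character(classify_ddf(-5)), "non-binder")
  expect_identical(as.character(classify_ddf(-6.4)), "sensor")
  expect_identical(as.character(classify_ddf(-10.0)), "sensor")
  expect_identical(as.character(classify_ddf(-12)), "binder")
  grid <- seq(-20, 5, by = 0.05)
  lab <- classify_ddf(grid)
  expect_false(anyNA(lab))
  expect_identical(sum(table(lab)), length(grid))
  expect_true(all(grid[lab == "non-binder"] > -6.4))
  expect_true(all(grid[lab == "binder"] < -10))
})

test_that("the Pm-vs-radius curve composes the free-energy and probability maps", {
  cv <- pm_radius_curve(0, 50)
  expect_equal(cv$pm, binding_probability(binding_free_energy(0, 50)))
  expect_equal(cv$pm, 1.36e-6, tolerance = 0.01)
  cv2 <- pm_radius_curve(-10, 50)
  expect_equal(cv2$pm, 0.95, tolerance = 0.005 / 0.95)
  cv3 <- pm_radius_curve(-10, c(20, 50, 200))
  expect_true(all(diff(cv3$pm) < 0))
  # non-increasing in R for any sensing (negative) free energy
  for (x in c(-2, -8, -15))
    expect_true(all(diff(pm_radius_curve(x, c(10, 30, 100, 400))$pm) <= 0))
})

test_that("root-finding the probability crossings recovers the printed thresholds", {
  b <- derive_class_boundaries()
  expect_equal(round(unname(b), 1), c(-6.4, -10.0))
  expect_error(derive_class_boundaries(0.5, 0.5), "p_low")
  # closed form: Pm = p  <=>  dFsm = RT*log((1/p - 1)/ (Ns/Nm)); back-solve Eq. 3
  cst <- pmi_constants()
  b5 <- derive_class_boundaries(p_low = 0.5, p_high = 0.95)
  dfsm_half <- cst$thermal_energy * log((1 / 0.5 - 1) / cst$ns_over_nm)
  slope <- cst$alpha + vesicle_strain(50) / cst$eps_ref
  expect_equal(unname(b5["at_p_low"]), (dfsm_half - cst$beta) / slope,
               tolerance = 1e-6)
})

test_that("constants are validated and readable from key=value files", {
  expect_error(pmi_constants(a_l = 1), "negative")
  expect_error(pmi_constants(eps_ref = 0), "positive")
  expect_error(pmi_constants(sensor_lo = -5, sensor_hi = -6), "thresholds")
  expect_error(pmi_constants(ref_length = 20), "24")
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# custom run", "alpha = 4.0", "beta = 10"), f)
  cst <- read_constants_file(f)
  expect_equal(cst$alpha, 4.0)
  expect_equal(cst$beta, 10)
  expect_equal(cst$c_z, -0.93)  # untouched default
  writeLines("gamma = 1", f)
  expect_error(read_constants_file(f), "unknown constant")
})
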