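test_that("r_squared matches its definition and affine invariance", {
  expect_identical(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), c(2, 2, 2)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  withr::local_seed(5)
  obs <- rnorm(50)
  pred <- obs + rnorm(50, sd = 0.3)
  expect_equal(r_squared(3 * obs - 7, 3 * pred - 7),
               r_squared(obs, pred), tolerance = 1e-12)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(r_squared(1, 1), "length")
})

test_that("fit_spec validates parameter roles", {
  sp <- fit_spec("phase1", fixed = list(sigma1 = 11, t2_plus = 300))
  expect_setequal(sp$free, c("V0", "n1", "t1_plus", "n2", "sigma2"))
  expect_error(fit_spec("phase1", fixed = list(RC2 = 1)), "unknown fixed")
  expect_error(fit_spec("phase1", fixed = list(n1 = 1), free = "n1"),
               "both free and fixed")
  expect_error(fit_spec("system", free = "foo"), "unknown free")
})

test_that("noiseless phase I series regenerates the published parameters", {
  for (case in list(
    list(gt = table1_pepsin(), t2 = 300, win = c(120, 600), dur = 600),
    list(gt = table1_water(), t2 = 540, win = c(360, 900), dur = 900))) {
    s <- phase1_series(case$gt, noise_cv = 0, duration = case$dur)
    f <- fit_phase1(s, fit_spec("phase1",
                                fixed = list(sigma1 = 11, t2_plus = case$t2),
                                window = case$win))
    expect_true(f$converged)
    truth <- c(n1 = case$gt$pulse1$n, t1_plus = case$gt$pulse1$center,
               n2 = case$gt$pulse2$n, sigma2 = case$gt$pulse2$sigma)
    expect_equal(f$estimates[names(truth)], truth, tolerance = 1e-3)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("phase I fit handles flat data and under-determined input", {
  flat <- kinetics_series(seq(0, 100, by = 0.5),
                          rep(43.72, 201), provenance = "synthetic")
  f <- fit_phase1(flat, fit_spec("phase1",
                                 fixed = list(sigma1 = 11, t2_plus = 90)))
  expect_lt(f$estimates[["n1"]], 1e-6)
  expect_lt(f$estimates[["n2"]], 1e-6)
  tiny <- kinetics_series(c(0, 1, 2), c(40, 39, 38),
                          provenance = "synthetic")
  expect_error(fit_phase1(tiny, fit_spec("phase1",
                                         fixed = list(sigma1 = 11,
                                                      t2_plus = 2))),
               "under-determined")
})

test_that("the automatic minimum finder locates the shrinkage hand-off", {
  gt <- table1_pepsin()
  # pure shrinkage followed by growth from t = 450: the smoothed minimum
  # sits at the hand-off
  sp <- scenario_spec("water_ph2", ground_truth = gt, noise_cv = 0,
                      duration = 700, growth_start = 450,
                      growth_rate = 0.002, reference_volume_fL = 217.45)
  s <- generate_kinetics(sp)
  expect_equal(detect_shrinkage_minimum(s), 450, tolerance = 1)
  # and it is used as default t2+ when none is fixed
  f <- fit_phase1(s, fit_spec("phase1", fixed = list(sigma1 = 11),
                              window = c(120, 450)))
  expect_identical(f$diagnostics$t2_source, "detected")
})

test_that("noisy phase I replicates recover parameters with small median error", {
  gt <- table1_pepsin()
  truth <- c(n1 = 0.0116, t1_plus = 187.5, n2 = 0.015, sigma2 = 35.15)
  errs <- vapply(1:20, function(seed) {
    s <- phase1_series(gt, noise_cv = 0.01, seed = seed, duration = 600)
    f <- fit_phase1(s, fit_spec("phase1",
                                fixed = list(sigma1 = 11, t2_plus = 300),
                                window = c(120, 600)))
    abs(f$estimates[names(truth)] / truth - 1)
  }, numeric(4))
  expect_true(all(apply(errs, 1, stats::median) < 0.05))
})

test_that("fixing a parameter at its generating value cannot beat the free fit", {
  gt <- table1_pepsin()
  s <- phase1_series(gt, noise_cv = 0.01, seed = 99, duration = 600)
  spec_free <- fit_spec("phase1", fixed = list(sigma1 = 11, t2_plus = 300),
                        window = c(120, 600))
  spec_nested <- fit_spec("phase1",
                          fixed = list(sigma1 = 11, t2_plus = 300,
                                       n1 = 0.0116),
                          window = c(120, 600))
  f_free <- fit_phase1(s, spec_free)
  f_nested <- fit_phase1(s, spec_nested)
  expect_lte(f_free$residual_ss, f_nested$residual_ss + 1e-10)
})

test_that("noiseless phase III series regenerates the published parameters", {
  s <- generate_kinetics(scenario_spec("preacidified_pepsin",
                                       noise_cv = 0))
  f <- fit_phase3(s, fit_spec("phase3"))
  expect_true(f$converged)
  truth <- c(V0 = 197.4, n3 = 0.0141, t3_plus = 193.5, V4 = 122.3,
             t4 = 141.7, V_inf = 55.5)
  expect_equal(f$estimates[names(truth)], truth, tolerance = 1e-3)
  # recovered decay rate rounds to the printed 7e-3 1/s
  expect_equal(signif(1 / f$estimates[["t4"]], 1), 7e-3)
  expect_true(is.finite(f$diagnostics$discontinuity_pL))
})

test_that("exponential branch of the segment fit degrades gracefully", {
  # constant tail -> amplitude to zero, plateau to the constant
  tt <- seq(0, 600, by = 0.5)
  const_area <- volume_to_area(convert_volume_units(80, "pL", "um3"))
  v_model <- ifelse(tt < 147, seq_along(tt) * 0 + 90, 80)
  areas <- volume_to_area(convert_volume_units(v_model, "pL", "um3"))
  s <- kinetics_series(tt, areas, provenance = "synthetic")
  f <- fit_phase3(s, fit_spec("phase3"))
  expect_lt(f$estimates[["V4"]], 1e-4)
  expect_equal(f$estimates[["V_inf"]], 80, tolerance = 1e-6)
  # a branch with too few points is rejected
  expect_error(fit_phase3(kinetics_series(c(200, 250, 300),
                                          rep(const_area, 3),
                                          provenance = "synthetic"),
                          fit_spec("phase3")),
               "under-determined")
})

test_that("differential evolution minimizes, respects bounds, and is seeded", {
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  r1 <- differential_evolution(rosen, c(-2, -2), c(2, 2), seed = 4,
                               maxiter = 400)
  expect_lt(r1$value, 1e-8)
  expect_equal(r1$par, c(1, 1), tolerance = 1e-3)
  r2 <- differential_evolution(rosen, c(-2, -2), c(2, 2), seed = 4,
                               maxiter = 400)
  expect_identical(r1$trace, r2$trace)   # bit-identical given the seed
  r3 <- differential_evolution(rosen, c(-2, -2), c(2, 2), seed = 5,
                               maxiter = 400)
  expect_false(identical(r1$trace, r3$trace))
  # constrained optimum lands on the boundary
  rb <- differential_evolution(function(x) sum(x^2), 1, 3, seed = 1,
                               maxiter = 200)
  expect_equal(rb$par, 1, tolerance = 1e-6)
})

test_that("the system fit runs forward with no free parameters and needs bounds", {
  s <- generate_kinetics(scenario_spec("sgf_pepsin", noise_cv = 0,
                                       duration = 900))
  f0 <- fit_system(s, fit_spec("system"))
  expect_identical(f0$converged, TRUE)
  expect_equal(f0$residual_ss, 0, tolerance = 1e-12)
  expect_equal(f0$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_system(s, fit_spec("system", free = "RC2", seed = 1)),
               "unbounded")
  expect_error(fit_system(s, fit_spec("system", free = "RC2",
                                      bounds = list(RC2 = c(1e-3, 0.02)))),
               "seed")
})

test_that("seeded system fits are reproducible and recover a free rate", {
  s <- generate_kinetics(scenario_spec("sgf_pepsin", noise_cv = 0,
                                       duration = 1200))
  sp <- fit_spec("system", free = "RC2",
                 bounds = list(RC2 = c(0.001, 0.02)), seed = 11,
                 control = list(np = 10, maxiter = 60, tol = 1e-12))
  f1 <- fit_system(s, sp)
  f2 <- fit_system(s, sp)
  expect_identical(f1$trace, f2$trace)
  expect_equal(f1$estimates[["RC2"]], 0.005, tolerance = 1e-3)
})
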