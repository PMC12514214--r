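# linear-decay-only configuration: I_V3 active from t = 0, all else off
decay_only_config <- function(V0 = 100, RC2 = 0.005, RC3 = 0.1533,
                              dt = 0.25, t_end = 2000) {
  system_config(V0 = V0,
                gauss1 = gaussian_pulse(0, 187.5, 11),
                gauss2 = gaussian_pulse(0, 300, 35.15),
                gauss3 = gaussian_pulse(0, 510, 37.16),
                RC1 = 0, RC2 = RC2, RC3 = RC3,
                t_pulse1_start = -3, t_pH28 = -2, Degt = -1,
                dt = dt, t_end = t_end)
}

test_that("flows are quiescent before the first pulse and at the fixed point", {
  cfg <- system_config()
  early <- system_flows(cfg, 50, cfg$V0)
  expect_true(all(abs(unlist(early)) < 1e-12 * cfg$V0))
  # Phase III fixed point V = RC3/RC2 has zero net flow
  fp <- system_flows(cfg, 1000, cfg$RC3 / cfg$RC2)
  expect_identical(fp$iv3, 0)
  expect_identical(fp$iv1 + fp$iv2, 0)
})

test_that("the solvent flow reverses direction exactly at t2+ = 300 s", {
  cfg <- system_config()
  V <- 200
  before <- system_flows(cfg, 300 - 1e-9, V)
  after <- system_flows(cfg, 300, V)
  expect_gt(before$iv1, 0)        # outflow still on
  expect_identical(before$iv2, 0)
  expect_identical(after$iv1, 0)  # outflow off at exactly 300
  expect_gt(after$iv2, 0)         # inflow on at exactly 300
  expect_error(system_flows(cfg, 300, -1), "V")
})

test_that("simulation with all kernels off keeps the volume constant", {
  cfg <- system_config(gauss1 = gaussian_pulse(0, 187.5, 11),
                       gauss2 = gaussian_pulse(0, 300, 35.15),
                       gauss3 = gaussian_pulse(0, 510, 37.16),
                       RC1 = 0, RC2 = 0, RC3 = 0, t_end = 1000)
  traj <- simulate_system(cfg)
  expect_true(all(traj$volume_fL == cfg$V0))
  expect_true(all(traj$area_um2 == volume_to_area(cfg$V0)))
})

test_that("Euler integration matches the analytic linear decay", {
  cfg <- decay_only_config()
  traj <- simulate_system(cfg)
  v_inf <- cfg$RC3 / cfg$RC2
  expect_equal(v_inf, 30.66)
  analytic <- v_inf + (cfg$V0 - v_inf) * exp(-cfg$RC2 * traj$time_s)
  rel_err <- max(abs(traj$volume_fL / analytic - 1))
  expect_lt(rel_err, 1e-3)
  # halving dt roughly halves the first-order Euler error
  traj2 <- simulate_system(decay_only_config(dt = 0.125))
  analytic2 <- v_inf + (cfg$V0 - v_inf) * exp(-cfg$RC2 * traj2$time_s)
  expect_lt(max(abs(traj2$volume_fL / analytic2 - 1)), rel_err / 1.8)
})

test_that("the tabulated configuration reaches the steady-state area", {
  cfg <- system_config()
  traj <- simulate_system(cfg)
  a_inf <- steady_state_area(cfg)
  expect_equal(tail(traj$area_um2, 1), a_inf, tolerance = 1e-3)
  # dt convergence: halving the step moves the final area by < 0.1%
  cfg2 <- system_config(dt = 0.125)
  traj2 <- simulate_system(cfg2)
  expect_equal(tail(traj2$area_um2, 1), tail(traj$area_um2, 1),
               tolerance = 1e-3)
})

test_that("the simulated kinetics has the three-phase structure", {
  cfg <- system_config()
  traj <- simulate_system(cfg)
  v <- traj$volume_fL
  tt <- traj$time_s
  t1 <- cfg$gauss1$center
  s1 <- cfg$gauss1$sigma
  # phase I: non-increasing from t1+ - 3 sigma1 up to the 300 s minimum
  ph1 <- tt >= t1 - 3 * s1 & tt < 300
  expect_true(all(diff(v[ph1]) <= 0))
  # pre-swelling minimum within one step of t = 300
  pre <- tt < 400
  expect_lte(abs(tt[pre][which.min(v[pre])] - 300), cfg$dt)
  # phase II: increasing over (300, 400)
  ph2 <- tt > 300 & tt < 400
  expect_true(all(diff(v[ph2]) > 0))
  # phase III: non-increasing after Degt
  ph3 <- tt >= cfg$Degt
  expect_true(all(diff(v[ph3]) <= 0))
})

test_that("per-step volume increments equal dt times the recorded net flow", {
  traj <- simulate_system(system_config(t_end = 800))
  n <- nrow(traj)
  net <- (-traj$iv1 + traj$iv2 - traj$iv3)[-n]
  expect_equal(diff(traj$volume_fL), 0.25 * net, tolerance = 1e-12)
  # areas are the pointwise spherical conversion of the volumes
  expect_equal(traj$area_um2, volume_to_area(traj$volume_fL),
               tolerance = 1e-14)
})

test_that("steady-state area follows the rate-coefficient ratio only", {
  # RC3/RC2 = unit-sphere volume -> area pi
  cfg <- system_config(RC2 = 0.01, RC3 = 0.01 * 4 / 3 * pi)
  expect_equal(steady_state_area(cfg), pi, tolerance = 1e-12)
  cfg1 <- system_config()
  expect_equal(steady_state_area(cfg1), 11.84, tolerance = 1e-3)
  cfg2 <- system_config(RC2 = 2 * cfg1$RC2, RC3 = 2 * cfg1$RC3)
  expect_equal(steady_state_area(cfg2), steady_state_area(cfg1),
               tolerance = 1e-12)
  expect_error(steady_state_area(system_config(RC2 = 0)),
               "no steady state")
})

test_that("the integrator guards positivity and flags divergence", {
  # violent decay overshoots below zero -> clipped at the floor, warned
  cfg <- decay_only_config(V0 = 10, RC2 = 10, RC3 = 0)
  expect_warning(traj <- simulate_system(cfg), "floor")
  expect_true(all(traj$volume_fL > 0))
  # superlinear absolute swelling kernel blows up in finite time -> error
  boom <- system_config(phase2_kernel = "absolute", RC1 = 1, nx = 3,
                        t_end = 600)
  expect_error(simulate_system(boom), "diverged")
})

test_that("system configuration round-trips through JSON", {
  cfg <- system_config(RC2 = 0.004, dt = 0.5, phase2_kernel = "absolute")
  f <- withr::local_tempfile(fileext = ".json")
  write_system_config(cfg, f)
  expect_equal(read_system_config(f), cfg)
  # the shipped fixture equals the default configuration
  fx <- read_system_config(system.file("extdata", "table3.json",
                                       package = "cmpkin"))
  expect_equal(fx, system_config())
  expect_error(system_config(dt = -1), "dt")
  expect_error(system_config(Degt = 200), "chronology")
})
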