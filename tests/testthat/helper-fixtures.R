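# shared fixture builders: the tabulated parameter sets and synthetic series

table1_pepsin <- function() {
  read_phase1_params(system.file("extdata", "table1_pepsin.json",
                                 package = "cmpkin"))
}

table1_water <- function() {
  read_phase1_params(system.file("extdata", "table1_water.json",
                                 package = "cmpkin"))
}

table2_params <- function() {
  read_phase3_params(system.file("extdata", "table2.json",
                                 package = "cmpkin"))
}

# pure Phase I synthetic area series (growth segment pushed out of range)
phase1_series <- function(ground_truth, noise_cv = 0, seed = 1L,
                          duration = 600) {
  generate_kinetics(scenario_spec(
    "water_ph2", ground_truth = ground_truth, noise_cv = noise_cv,
    seed = seed, duration = duration, growth_start = 1e9,
    reference_volume_fL = 217.45))
}

# random valid phase1 parameter draw for property tests
random_phase1 <- function() {
  t1 <- stats::runif(1, 100, 300)
  phase1_params(
    V0 = stats::runif(1, 0.5, 300),
    pulse1 = gaussian_pulse(stats::runif(1, 1e-4, 0.05), t1,
                            stats::runif(1, 5, 40)),
    pulse2 = gaussian_pulse(stats::runif(1, 1e-4, 0.05),
                            t1 + stats::runif(1, 50, 300),
                            stats::runif(1, 5, 60)))
}

# numeric quadrature of the total Gaussian outflow rate (independent oracle)
quad_outflow <- function(params, t0, t1) {
  stats::integrate(function(u) {
    gaussian_value(params$pulse1, u) + gaussian_value(params$pulse2, u)
  }, t0, t1, rel.tol = 1e-12, abs.tol = 1e-14)$value
}
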