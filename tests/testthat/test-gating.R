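# closed-form pieces of the membrane model

test_that("temperature scaling is base^((T-T0)/10) with unit value at T0", {
  expect_equal(temperature_scaling(298.15, 298.15, 1.3), 1)
  expect_equal(temperature_scaling(308.15, 298.15, 1.3), 1.3)
  expect_equal(temperature_scaling(288.15, 298.15, 3), 1 / 3)
  # strictly increasing in T
  ts <- temperature_scaling(seq(270, 320, 5), base = 1.3)
  expect_true(all(diff(ts) > 0))
  expect_error(temperature_scaling(-1, base = 1.3), "> 0")
  expect_error(temperature_scaling(300, base = 0), "> 0")
})

test_that("Boltzmann gates hit their half point and are monotone", {
  expect_equal(boltzmann_gate(-24.7, -24.7, 3.4, "activation"), 0.5)
  expect_equal(boltzmann_gate(-41.2, -41.2, 4.2, "inactivation"), 0.5)
  expect_equal(boltzmann_gate(-24.7 + 3.4 * log(3), -24.7, 3.4, "activation"),
               0.75)
  v <- seq(-100, 50, 5)
  act <- boltzmann_gate(v, -24.7, 3.4, "activation")
  inact <- boltzmann_gate(v, -41.2, 4.2, "inactivation")
  expect_true(all(diff(act) > 0) && all(diff(inact) < 0))
  expect_true(all(act > 0 & act < 1))
  expect_error(boltzmann_gate(0, 0, 0), "nonzero")
})

test_that("Hill gates hit their half point and respect domains", {
  expect_equal(hill_gate(1700, 1700, 3), 0.5)
  expect_equal(hill_gate(800, 800, 3), 0.5)
  expect_equal(hill_gate(8000, 800, 3), 1 / (1 + 1e-3))
  ca <- 10^seq(0, 5, 0.5)
  expect_true(all(diff(hill_gate(ca, 800, 3)) > 0))
  expect_error(hill_gate(-5, 800, 3), "> 0")
})

test_that("voltage-dependent time constants match closed forms", {
  p <- default_params
  expect_equal(voltage_dependent_tau(-46, "mBK", p), 0.1806 - 0.15021 / 2)
  # at the center of the cosh argument both tau profiles give the minimum
  # plus-offset value
  expect_equal(voltage_dependent_tau(-abs(p$Vh_Na), "hNa", p),
               (4.5 + 0.75) / 1000)
  expect_equal(voltage_dependent_tau(-abs(p$Vm_K), "mK", p),
               (5 + 0.75) / 1000)
  # sech profile: fast away from the center; literal cosh profile: slow
  p_lit <- neuron_parameters(tau_profile = "cosh")
  expect_lt(voltage_dependent_tau(0, "hNa", p), 0.002)
  expect_gt(voltage_dependent_tau(0, "hNa", p_lit), 0.05)
  expect_true(all(voltage_dependent_tau(seq(-100, 50, 1), "hNa", p) > 0))
  expect_error(voltage_dependent_tau(0, "nope", p))
})

test_that("tau centering conventions move the cosh argument as documented", {
  p_mag <- default_params
  p_cen <- neuron_parameters(tau_convention = "centered")
  p_lit <- neuron_parameters(tau_convention = "literal")
  # for hNa (Vh = -41.2) magnitude and centered agree; literal differs
  expect_equal(voltage_dependent_tau(-20, "hNa", p_mag),
               voltage_dependent_tau(-20, "hNa", p_cen))
  expect_false(isTRUE(all.equal(voltage_dependent_tau(-20, "hNa", p_mag),
                                voltage_dependent_tau(-20, "hNa", p_lit))))
})

test_that("Nernst calcium reversal matches the closed form", {
  expect_equal(nernst_calcium(2e6, 2e6, 298.15), 0)
  expect_equal(nernst_calcium(50, 2e6, 298.15),
               1000 * 8.31e-9 * 298.15 / (2 * 96485.35e-9) * log(4e4))
  expect_equal(round(nernst_calcium(50, 2e6, 298.15), 1), 136.1)
  expect_equal(round(nernst_calcium(50, 2e6, 283.15), 1), 129.2)
  # decreasing in Ca_i
  expect_true(all(diff(nernst_calcium(c(50, 500, 5000), 2e6, 298.15)) < 0))
  expect_error(nernst_calcium(0, 2e6, 298.15), "> 0")
})

test_that("the printed default parameter set ships in the config file", {
  cfg <- read_params_config(system.file("extdata", "default_params.cfg",
                                        package = "coldburst"))
  expect_equal(cfg$params$G_Na, 80)
  expect_equal(cfg$params$G_K, 140)
  expect_equal(cfg$params$G_Ca, 3.5)
  expect_equal(cfg$params$Cm, 0.01)
  expect_equal(cfg$trp$G_TRP_max, 1.2)
  expect_equal(cfg$trp$T_h, 290.15)
  expect_equal(cfg$trp$tau_hTRP, 10)
  # round trip through a temp file
  tmp <- tempfile(fileext = ".cfg")
  write_params_config(cfg$params, cfg$trp, tmp)
  back <- read_params_config(tmp)
  expect_equal(unclass(back$params), unclass(cfg$params))
  expect_equal(unclass(back$trp), unclass(cfg$trp))
})

test_that("parameter validation rejects unphysical values", {
  expect_error(neuron_parameters(G_Na = -1), ">= 0")
  expect_error(neuron_parameters(Cm = 0), "> 0")
  expect_error(neuron_parameters(Km_Na = 0), "nonzero")
  expect_error(neuron_parameters(Ca_min = 3e6), "Ca_e > Ca_min")
  expect_error(neuron_parameters(nonsense = 1), "unknown")
  expect_error(trp_parameters("dynamic", B = 1.5), "\\(0, 1\\]")
  expect_error(trp_parameters("dynamic", A = -1), "> 0")
  expect_error(trp_parameters("dynamic", N = 0.5), ">= 1")
})
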