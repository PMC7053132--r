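test_that("Hill dose-response anchors: no drug, MIC, saturation", {
  expect_equal(hill_growth_factor(0, 2, 2), 1)
  expect_equal(hill_growth_factor(0, 0.5, 7), 1)
  expect_equal(hill_growth_factor(1, 2, 2), 0)
  expect_equal(hill_growth_factor(1e6, 2, 2), -2, tolerance = 1e-6)
  expect_equal(hill_growth_factor(1.25, 2, 2),
               (1 - 1.5625) / (1 + 1.5625 / 2))
  # strictly decreasing in b
  b <- seq(0, 5, by = 0.1)
  expect_true(all(diff(hill_growth_factor(b, 2, 2)) < 0))
  expect_error(hill_growth_factor(-1, 2, 2), ">= 0")
  expect_error(hill_growth_factor(1, -2, 2), "kappa")
})

test_that("pyoverdine yield factor rises from 1 to sigma", {
  expect_equal(yield_factor(0, 2), 1)
  expect_equal(yield_factor(1e3, 2), 2, tolerance = 1e-9)
  expect_equal(yield_factor(log(2), 2), 1.5)
  p <- seq(0, 10, by = 0.5)
  expect_true(all(diff(yield_factor(p, 3)) > 0))
  expect_error(yield_factor(-1, 2), ">= 0")
  expect_error(yield_factor(1, 0.9), "sigma")
})

test_that("single neutral deme matches the exponential-growth closed form", {
  w <- base_world1()
  g <- grow_deme(10, w)
  expect_equal(g$final_sizes, 100010, tolerance = 1e-8)
  expect_equal(g$t_depl, log(10001), tolerance = 1e-6)
  expect_true(g$depleted)
  cf <- base_closed_form(10, w)
  expect_equal(cf$final_sizes, g$final_sizes, tolerance = 1e-8)
  # empty deme stays empty, under every interaction
  for (w0 in list(neutral_world2(), ab_world(), pyo_world()))
    expect_equal(grow_deme(c(0, 0), w0)$final_sizes, c(0, 0))
})

test_that("ODE integrator matches the closed-form oracle on an inoculum/trait grid", {
  for (da in c(-0.1, -0.01, 0)) {
    for (dp in c(0.1, 0.01, 0)) {
      w <- world_config(list(strain_params(da, dp), strain_params(-da, -dp)),
                        s0_phi = 1e5, t_mix = 24, d = 6e-4)
      for (n1 in c(1, 10, 1000)) for (n2 in c(1, 100)) {
        ode <- grow_deme(c(n1, n2), w)$final_sizes
        exact <- base_closed_form(c(n1, n2), w)$final_sizes
        expect_equal(ode, exact, tolerance = 1e-6)
      }
    }
  }
})

test_that("mass balance holds along base trajectories", {
  w <- world_config(list(strain_params(-0.05, 0.2), strain_params(0.05, -0.2)),
                    s0_phi = 1e5, t_mix = 24, d = 6e-4)
  g <- grow_deme(c(7, 3), w, trajectory = TRUE, n_times = 60)
  tr <- g$trajectory
  budget <- tr$N_1 / 1.2 + tr$N_2 / 0.8 + tr$S
  expect_equal(budget, rep(budget[1], length(budget)), tolerance = 1e-6)
})

test_that("final sizes grow with resource supply and inoculum", {
  finals <- vapply(c(1e3, 1e4, 1e5), function(s0)
    grow_deme(10, base_world1(s0_phi = s0))$final_sizes, numeric(1))
  expect_true(all(diff(finals) > 0))
  w <- base_world1(s0_phi = 1e4)
  # once depleted, extra founders only add themselves
  finals_n <- vapply(c(1, 10, 100), function(n)
    grow_deme(n, w)$final_sizes, numeric(1))
  expect_true(all(diff(finals_n) > 0))
})

test_that("antibiotics create an inoculum survival threshold (bistability)", {
  w <- world_config(strain_params(rho = 5e-3), s0_phi = 1e5, t_mix = 24,
                    d = 6e-4, interaction = antibiotic_params(1.25, 2, 2))
  # a single producing cell loses the degradation race and the deme dies
  expect_lt(grow_deme(1, w)$final_sizes, 1)
  finals <- vapply(1:40, function(n) grow_deme(n, w)$final_sizes, numeric(1))
  dead <- finals < 1
  full <- finals > 0.9 * 1e5
  expect_true(any(dead) && any(full))
  # all-or-nothing up to a narrow crossover: below the threshold dead,
  # above it fully grown; the few in-between inocula recover but too late
  # to finish depleting by the mixing time
  n_lo <- max(which(dead)); n_hi <- min(which(full))
  expect_true(all(dead[seq_len(n_lo)]))
  expect_true(all(full[n_hi:40]))
  expect_lte(n_hi - n_lo, 6)
  expect_true(all(diff(finals) > 0))
})

test_that("pyoverdine bounds: sigma = 1 is the base model, yield capped at sigma", {
  w1 <- world_config(strain_params(rho = 1e-3), s0_phi = 1e4, t_mix = 24,
                     d = 6e-4, interaction = pyoverdine_params(1))
  wb <- world_config(strain_params(rho = 1e-3), s0_phi = 1e4, t_mix = 24,
                     d = 6e-4)
  for (n in c(1, 17, 300))
    expect_equal(grow_deme(n, w1)$final_sizes, grow_deme(n, wb)$final_sizes,
                 tolerance = 1e-7)
  w2 <- world_config(strain_params(rho = 1e-3), s0_phi = 1e4, t_mix = 24,
                     d = 6e-4, interaction = pyoverdine_params(2))
  for (n in c(1, 60, 500)) {
    f <- grow_deme(n, w2)$final_sizes
    expect_lte(f, n + 2 * 1e4 * (1 + 1e-6))
  }
  # a producer inoculum at the dilution scale saturates the yield benefit
  w3 <- world_config(strain_params(rho = 1e-3), s0_phi = 1e5, t_mix = 24,
                     d = 6e-4, interaction = pyoverdine_params(2))
  expect_equal(grow_deme(60, w3)$final_sizes, 2e5, tolerance = 0.02)
})

test_that("trajectories freeze at depletion and expose the public good", {
  g <- grow_deme(10, base_world1(), trajectory = TRUE, n_times = 30)
  after <- g$trajectory[g$trajectory$t > g$t_depl, ]
  expect_true(all(abs(after$N_1 - max(g$final_sizes)) < 1e-6 * 1e5))
  gb <- grow_deme(c(5, 5), ab_world(), trajectory = TRUE, n_times = 20)
  expect_true("B" %in% names(gb$trajectory))
  expect_true(all(diff(gb$trajectory$B) <= 1e-12))
  gp <- grow_deme(c(5, 5), pyo_world(), trajectory = TRUE, n_times = 20)
  expect_true("P" %in% names(gp$trajectory))
  expect_true(all(diff(gp$trajectory$P) >= -1e-12))
})
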