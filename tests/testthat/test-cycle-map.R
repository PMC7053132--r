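test_that("Poisson expectation matches the closed-form seeded-deme average", {
  w <- base_world1()
  # every seeded deme (n >= 1) depletes and yields n + s0_phi; empty demes
  # contribute nothing: E[N] = nbar + s0_phi * (1 - exp(-nbar))
  for (nbar in c(60, 0.1, 3)) {
    e <- expected_final_sizes(mean_state(nbar), w)
    expect_equal(as.numeric(e), nbar + 1e5 * (1 - exp(-nbar)),
                 tolerance = 1e-3)
    expect_lt(attr(e, "neglected_mass"), 1e-11)
  }
  expect_equal(as.numeric(expected_final_sizes(mean_state(0), w)), 0)
})

test_that("the single-strain map converges to the dilution fixed point", {
  w <- base_world1()   # d * s0_phi = 60
  tr <- iterate_cycles(mean_state(10), w, 200)
  expect_true(attr(tr, "converged"))
  nstar <- nbar_total(attr(tr, "final_state"))
  # exact scalar fixed point nbar = d*(nbar + s0_phi*(1 - exp(-nbar)))
  exact <- uniroot(function(n) 6e-4 * (n + 1e5 * (1 - exp(-n))) - n,
                   c(1, 100), tol = 1e-12)$root
  expect_equal(nstar, exact, tolerance = 1e-6)
  # the dilution-line approximation d*s0_phi is accurate to < 0.1%
  expect_equal(nstar, 60, tolerance = 1e-3)
  # over-dilution leads to extinction
  w0 <- base_world1(d = 5e-6)   # d*(1 + s0_phi) < 1
  tr0 <- iterate_cycles(mean_state(10), w0, 400)
  expect_lt(nbar_total(attr(tr0, "final_state")), 1e-4)
})

test_that("composition is conserved for identical strains", {
  w <- neutral_world2()
  st <- mean_state(c(18, 42))
  for (i in 1:3) {
    st2 <- cycle_step(st, w)
    expect_equal(xbar(st2)[1], xbar(st)[1], tolerance = 1e-10)
    st <- st2
  }
  # and two identical strains end at equal sizes from symmetric seeds
  g <- grow_deme(c(5, 5), w)
  expect_equal(g$final_sizes[1], g$final_sizes[2])
})

test_that("halving the truncation mass tolerance barely moves the map", {
  w <- base_world1()
  st <- mean_state(25)
  for (tol in c(1e-6, 1e-8)) {
    a <- as.numeric(expected_final_sizes(st, w, truncation_policy(tol)))
    b <- as.numeric(expected_final_sizes(st, w, truncation_policy(tol / 2)))
    expect_lt(abs(a - b) / a, tol)
  }
  expect_error(truncation_policy(0.5), "mass_tolerance")
  expect_error(
    expected_final_sizes(mean_state(c(2e5, 2e5)), neutral_world2(),
                         truncation_policy(1e-12, max_lattice = 1e4)),
    "lattice")
})

test_that("total population equilibrates much faster than composition", {
  w <- two_strain_world(-0.01, 0.1, s0_phi = 1e5, t_mix = 24, d = 6e-4)
  tr <- iterate_cycles(mean_state(c(2, 8)), w, 10, tol = 0)
  # after 10 cycles the total sits on its quasi-equilibrium (the total-size
  # isocline at the current composition) to within 1%
  x_now <- tr$xbar_1[11]
  iso <- population_isocline(w, x_grid = x_now,
                             n_range = c(20, 150), n_scan = 25)
  expect_equal(tr$nbar_total[11], iso$nbar[1], tolerance = 0.01)
  # while composition still moves by more than 1e-3 per cycle
  expect_gt(abs(tr$xbar_1[11] - tr$xbar_1[10]), 1e-3)
})

test_that("Price identity is exact and vanishes under neutrality", {
  w <- neutral_world2()
  pt <- price_decomposition(mean_state(c(12, 12)), w)
  expect_equal(pt$within, c(0, 0), tolerance = 1e-12)
  expect_equal(pt$covariance, c(0, 0), tolerance = 1e-12)
  expect_equal(pt$delta_xbar, c(0, 0), tolerance = 1e-12)
  expect_error(price_decomposition(mean_state(c(0, 0)), w), "nbar = 0")

  # identity against the independently computed one-cycle composition change
  w2 <- two_strain_world(-0.03, 0.1, s0_phi = 1e4, t_mix = 24, d = 6e-3)
  st <- c(4, 9)
  pt2 <- price_decomposition(st, w2)
  nxt <- cycle_step(mean_state(st), w2)
  direct <- xbar(nxt) - st / sum(st)
  expect_equal(pt2$delta_xbar, direct, tolerance = 1e-10)
  expect_equal(pt2$delta_xbar, pt2$within + pt2$covariance, tolerance = 1e-10)
})

test_that("Price identity holds across randomized worlds of all interactions", {
  set.seed(7)
  kinds <- rep(c("base", "antibiotics", "pyoverdine"), c(20, 8, 8))
  for (kind in kinds) {
    w <- random_world(kind)
    st <- c(runif(1, 0.2, 4), runif(1, 0.2, 4))
    pt <- price_decomposition(st, w)
    expect_equal(pt$delta_xbar, pt$within + pt$covariance, tolerance = 1e-10)
    expect_equal(sum(pt$delta_xbar), 0, tolerance = 1e-10)
  }
})

test_that("iteration records trajectories and stops at fixed points", {
  w <- base_world1()
  tr <- iterate_cycles(mean_state(60.036), w, 50)
  expect_true(attr(tr, "converged"))
  expect_lt(nrow(tr), 25)
  expect_named(tr, c("cycle", "nbar_1", "nbar_total", "xbar_1"))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read.csv(f)
  expect_equal(back$nbar_total, tr$nbar_total)
  unlink(f)
})
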