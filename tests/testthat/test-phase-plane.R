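test_that("neutral strains give a vertical population isocline at the dilution point", {
  w <- neutral_world2()
  iso <- population_isocline(w, x_grid = c(0.2, 0.5, 0.8))
  expect_equal(nrow(iso), 3)
  nstar <- uniroot(function(n) 6e-4 * (n + 1e5 * (1 - exp(-n))) - n,
                   c(1, 100), tol = 1e-12)$root
  expect_equal(iso$nbar, rep(nstar, 3), tolerance = 1e-5)
  # composition isocline is degenerate: everywhere stationary
  expect_message(comp <- composition_isocline(w), "stationary")
  expect_true(attr(comp, "degenerate"))
})

test_that("every isocline point satisfies its stationarity residual", {
  w <- two_strain_world(-0.01, 0.1, s0_phi = 1e5, t_mix = 24, d = 6e-4)
  pop <- population_isocline(w, x_grid = c(0.25, 0.75))
  tr <- truncation_policy()
  for (r in seq_len(nrow(pop))) {
    nxt <- demecycles:::.map_nx(pop$nbar[r], pop$xbar_1[r], w, tr)
    expect_lt(abs(nxt[1] - pop$nbar[r]) / pop$nbar[r], 1e-5)
  }
  comp <- composition_isocline(w, x_grid = c(0.3, 0.7), n_range = c(0.05, 200))
  for (r in seq_len(nrow(comp))) {
    nxt <- demecycles:::.map_nx(comp$nbar[r], comp$xbar_1[r], w, tr)
    expect_lt(abs(nxt[2] - comp$xbar_1[r]), 1e-5)
  }
})

test_that("trade-off tilts the dilution line by the yield deviation", {
  w <- two_strain_world(-0.01, 0.2, s0_phi = 1e5, t_mix = 24, d = 6e-4)
  iso <- population_isocline(w, x_grid = c(0.05, 0.95))
  # all-efficient vs all-wasteful composition differ by ~ (1+dp)/(1-dp)
  expect_equal(iso$nbar[2] / iso$nbar[1], 1.2 / 0.8, tolerance = 0.05)
})

test_that("doubling the dilution factor moves only the population isocline", {
  mk <- function(d) two_strain_world(-0.01, 0.1, s0_phi = 1e5, t_mix = 24, d = d)
  p1 <- population_isocline(mk(6e-4), x_grid = 0.5)
  p2 <- population_isocline(mk(1.2e-3), x_grid = 0.5)
  expect_equal(p2$nbar / p1$nbar, 2, tolerance = 0.05)
  c1 <- composition_isocline(mk(6e-4), x_grid = 0.5, n_range = c(0.05, 300))
  c2 <- composition_isocline(mk(1.2e-3), x_grid = 0.5, n_range = c(0.05, 300))
  expect_lt(abs(c2$nbar - c1$nbar) / c1$nbar, 0.1)
})

test_that("extinction stability reflects the map slope d*(1 + s0_phi)", {
  # viable dilution: extinction unstable with multiplier ~ d*(1+s0_phi)
  fps <- find_fixed_points(neutral_world2())
  ext <- Filter(function(f) f$type == "extinction", fps)[[1]]
  expect_equal(max(Mod(ext$eigenvalues)), 6e-4 * (1 + 1e5), tolerance = 1e-3)
  expect_true(ext$classification %in% c("unstable_node", "saddle"))
  # the dilution fixed point on the diagonal is found and neutral-marginal
  # along composition (one eigenvalue on the unit circle)
  inner <- Filter(function(f) f$type == "interior", fps)
  if (length(inner)) {
    mods <- Mod(inner[[1]]$eigenvalues)
    expect_true(any(abs(mods - 1) < 1e-4))
    expect_true(any(mods < 0.1))
  }
})

test_that("antibiotic worlds have stable extinction and an all-producer state", {
  w <- ab_world(-0.005)
  fps <- find_fixed_points(w)
  ext <- Filter(function(f) f$type == "extinction", fps)[[1]]
  expect_true(all(Mod(ext$eigenvalues) < 1))   # small inocula die
  bnd <- Filter(function(f) f$type == "boundary_fixation" &&
                  f$position["xbar_1"] == 1, fps)
  expect_gte(length(bnd), 1)
  # the resource-limited all-producer state sits near the dilution line
  nb <- vapply(bnd, function(f) f$position[["nbar"]], numeric(1))
  expect_true(any(abs(nb - 60) < 2))
})

test_that("classification is consistent with iterated perturbations", {
  w <- ab_world(-0.003)   # stable interior coexistence
  tr <- truncation_policy()
  sol <- demecycles:::.newton_fixed_point(c(16, 38), w, tr, 1e-10, n_cap = 300)
  expect_false(is.null(sol))
  fp <- classify_fixed_point(sol, w)
  expect_equal(fp$classification, "stable_spiral")
  v <- sol * c(1.05, 0.97)
  for (i in 1:80) v <- demecycles:::.map_eval(v, w, tr)
  expect_lt(max(abs(v - sol) / sol), 0.01)
  # residual of the fixed point itself
  expect_lt(max(abs(demecycles:::.map_eval(sol, w, tr) - sol)), 1e-7 * sum(sol))
})

test_that("limit cycle detection rejects convergent and escaping orbits", {
  w <- ab_world(-0.003)
  tr <- truncation_policy()
  sol <- demecycles:::.newton_fixed_point(c(16, 38), w, tr, 1e-10, n_cap = 300)
  lc <- detect_limit_cycle(w, sol * c(1.05, 0.97), max_cycles = 600)
  expect_equal(lc$type, "none")
  expect_equal(lc$terminal, "fixed_point")
  # a start in the extinction basin reports terminal extinction
  lc2 <- detect_limit_cycle(w, c(nbar = 3, xbar_1 = 0.3), max_cycles = 200)
  expect_equal(lc2$type, "none")
  expect_equal(lc2$terminal, "extinction")
})

test_that("isocline intersections seed the interior fixed-point search", {
  w <- pyo_world(-1e-3)
  pop <- population_isocline(w, x_grid = c(0.05, 0.07, 0.09),
                             n_range = c(30, 250))
  comp <- composition_isocline(w, x_grid = c(0.05, 0.07, 0.09),
                               n_range = c(30, 250))
  fps <- find_fixed_points(w, seed_grid = matrix(numeric(0), 0, 2),
                           isoclines = list(pop, comp))
  inner <- Filter(function(f) f$type == "interior", fps)
  expect_gte(length(inner), 1)
  fp <- inner[[1]]
  expect_true(fp$classification %in% c("stable_node", "stable_spiral"))
  # the interior point lies on both isoclines (stationarity of both views)
  tr <- truncation_policy()
  nxt <- demecycles:::.map_nx(fp$position[["nbar"]], fp$position[["xbar_1"]], w, tr)
  expect_lt(abs(nxt[1] - fp$position[["nbar"]]) / fp$position[["nbar"]], 1e-6)
  expect_lt(abs(nxt[2] - fp$position[["xbar_1"]]), 1e-6)
})
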