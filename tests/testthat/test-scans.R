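test_that("neutral and trivial outcomes are labelled sensibly", {
  expect_equal(classify_outcome(neutral_world2())$label, "undetermined")
  # pure cost, no yield benefit: the slow strain is excluded
  w <- two_strain_world(-0.05, 0, s0_phi = 1e5, t_mix = 24, d = 1.2e-5)
  expect_equal(classify_outcome(w, method = "invasion")$label,
               "fixation_strain2")
  # over-dilution: everything dies
  w0 <- two_strain_world(-0.05, 0.1, s0_phi = 1e5, t_mix = 24, d = 5e-6)
  expect_equal(classify_outcome(w0, method = "invasion")$label, "extinction")
})

test_that("pyoverdine production sustains producer coexistence", {
  oc <- classify_outcome(pyo_world(), method = "invasion")
  expect_equal(oc$label, "coexistence")
  expect_true(all(oc$evidence$invasion$lambda_invasion > 1))
  # monomorphic residents sit on the sigma-scaled and plain dilution lines
  expect_equal(oc$evidence$invasion$resident_nbar,
               c(120, 60), tolerance = 0.01)
})

test_that("high-cost antibiotic producers leave only extinction or producer fixation", {
  w <- ab_world(-0.05)
  oc <- classify_outcome(w, method = "trajectory", horizon = 200)
  expect_true(all(oc$basins %in%
                    c("extinction", "fixation_strain1", "undetermined")))
  expect_true(any(oc$basins == "extinction"))
})

test_that("invasion and trajectory classifications agree on clear-cut cells", {
  w_coex <- two_strain_world(-0.15, 0.1, s0_phi = 1e5, t_mix = 24, d = 1.2e-5)
  expect_equal(classify_outcome(w_coex, method = "invasion")$label,
               "coexistence")
  tr <- iterate_cycles(mean_state(c(0.6, 0.6)), w_coex, 2500, tol = 0)
  xf <- tr$xbar_1[nrow(tr)]
  expect_gt(xf, 1e-3); expect_lt(xf, 1 - 1e-3)

  w_fix <- two_strain_world(-0.15, 0.02, s0_phi = 1e5, t_mix = 24, d = 1.2e-5)
  expect_equal(classify_outcome(w_fix, method = "invasion")$label,
               "fixation_strain2")
  tr2 <- iterate_cycles(mean_state(c(0.6, 0.6)), w_fix, 2500, tol = 0)
  expect_lt(tr2$xbar_1[nrow(tr2)], 0.02)
})

test_that("scans are deterministic and shaped by their grids", {
  tmpl <- two_strain_world(0, 0, s0_phi = 1e5, t_mix = 24, d = 1.2e-5)
  da <- -c(0.3, 0.15, 0.01)
  dp <- seq(0, 0.16, by = 0.04)
  s1 <- coexistence_scan(tmpl, da, dp)
  s2 <- coexistence_scan(tmpl, da, dp)
  expect_identical(s1$outcome, s2$outcome)
  expect_equal(dim(s1$outcome), c(3, 5))
  # pure-cost column never coexists
  expect_false(any(s1$outcome[, 1] == "coexistence"))
  # the large-trade-off rows carry a coexistence band
  expect_true(any(s1$outcome[1, ] == "coexistence"))
  expect_true(any(s1$outcome[2, ] == "coexistence"))
})

test_that("Simpson's paradox search reports the three Price quantities", {
  w <- ab_world(-0.01)
  res <- find_simpsons_paradox(w, nbar_grid = c(20, 35), x1_grid = c(0.4, 0.6))
  expect_equal(nrow(res), 4)
  expect_true(all(c("delta_xbar", "within", "covariance", "simpson") %in%
                    names(res)))
  expect_equal(res$delta_xbar, res$within + res$covariance, tolerance = 1e-10)
})

test_that("the command-line interface runs and validates configs", {
  skip_if(Sys.which("Rscript") == "", "Rscript not on PATH")
  cli <- system.file("cli", "demecycles.R", package = "demecycles")
  skip_if(cli == "", "CLI script not installed")
  dir <- tempfile(); dir.create(dir)
  cfg <- file.path(dir, "world.json")
  jsonlite::write_json(list(s0_phi = 1e3, d = 0.06, t_mix = 24,
                            strains = list(list(delta_alpha = 0))),
                       cfg, auto_unbox = TRUE)
  out <- file.path(dir, "out")
  # make sure the spawned interpreter sees the library this test runs from
  lib_env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  status <- system2("Rscript", c(cli, "cycle", "--config", cfg,
                                 "--cycles", "80", "--nbar", "5",
                                 "--out", out),
                    env = lib_env, stdout = TRUE, stderr = TRUE)
  expect_equal(attr(status, "status"), NULL)
  traj <- read.csv(file.path(out, "cycles.csv"))
  # fixed point of nbar -> d*(nbar + s0_phi) at d = 0.06: 60/(1 - d)
  expect_equal(traj$nbar_total[nrow(traj)], 60 / 0.94, tolerance = 1e-3)

  # a config missing s0_phi exits non-zero and names the key
  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(list(d = 0.06, strains = list(list())), bad,
                       auto_unbox = TRUE)
  res <- suppressWarnings(
    system2("Rscript", c(cli, "cycle", "--config", bad, "--out", out),
            env = lib_env, stdout = TRUE, stderr = TRUE))
  expect_equal(attr(res, "status"), 1L)
  expect_true(any(grepl("s0_phi", res)))
  unlink(dir, recursive = TRUE)
})
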