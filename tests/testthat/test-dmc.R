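# Scaled-down DMC checks; the analytic-ZPE acceptance runs live in
# test-acceptance.R at the full scaled-down protocol sizes.

test_that("a constant potential drives the reference energy to that constant", {
  pot <- pipfit:::.toy("const", function(X) rep(-0.25, ncol(X)),
                       function(x) 0 * x, 1L, 1, 0, v_min = -0.25)
  set.seed(1)
  X <- matrix(0, 1, 500)
  e_ref <- 0
  for (s in 1:200) {
    st <- dmc_step(X, pot, e_ref, dt = 5, masses = 1, n_target = 500, alpha = 0)
    X <- st$X; e_ref <- st$e_ref
  }
  expect_equal(e_ref, -0.25, tolerance = 1e-12)
})

test_that("a free particle has zero ZPE within noise", {
  pot <- pipfit:::.toy("free", function(X) numeric(ncol(X)),
                       function(x) 0 * x, 1L, 1, 0, v_min = 0)
  r <- run_dmc(pot, n_walkers = 300, n_steps = 2000, n_equil = 500,
               dt = 5, n_traj = 3, seed = 2)
  expect_lt(abs(r$zpe_cm1), max(3 * r$stderr_cm1, 1))
})

test_that("a quick harmonic run brackets the analytic ZPE and is seed-reproducible", {
  pot <- harmonic_potential(k = 0.01^2, m = 1, n_dof = 1)
  r1 <- run_dmc(pot, n_walkers = 800, n_steps = 6000, n_equil = 1500,
                dt = 5, n_traj = 3, seed = 11)
  exact <- hartree_to_cm1(pot$params$zpe)
  expect_lt(abs(r1$zpe_cm1 - exact), max(3 * r1$stderr_cm1, 0.01 * exact))
  # bit-for-bit reproducibility
  r2 <- run_dmc(pot, n_walkers = 800, n_steps = 6000, n_equil = 1500,
                dt = 5, n_traj = 3, seed = 11)
  expect_identical(r1$traces, r2$traces)
  # population stays within a sane band under the feedback rule
  expect_gt(min(r1$population["min", ]), 0.5 * 800)
  expect_lt(max(r1$population["max", ]), 2 * 800)
})

test_that("a separable two-mode potential adds its mode ZPEs", {
  pot <- harmonic_potential(k = c(0.008, 0.018)^2, m = 1, n_dof = 2)
  r <- run_dmc(pot, n_walkers = 1000, n_steps = 8000, n_equil = 2000,
               dt = 5, n_traj = 3, seed = 4)
  exact <- hartree_to_cm1(0.5 * (0.008 + 0.018))
  expect_lt(abs(r$zpe_cm1 - exact), max(3 * r$stderr_cm1, 0.01 * exact))
})

test_that("population collapse raises an explicit error", {
  pot <- pipfit:::.toy("wall", function(X) rep(10, ncol(X)),
                       function(x) 0 * x, 1L, 1, 0, v_min = 0)
  set.seed(3)
  X <- matrix(0, 1, 50)
  expect_error(dmc_step(X, pot, e_ref = 0, dt = 5, masses = 1, n_target = 50),
               "collapsed")
})

test_that("hole scanning flags walkers below the declared minimum", {
  # pocket 1000 cm^-1 deep, 6 bohr from the harmonic well
  pocket <- cm1_to_hartree(1000)
  pot <- pipfit:::.toy("holed",
                       function(X) 0.5 * 1e-4 * X[1, ]^2 -
                         pocket * exp(-((X[1, ] - 6)^2) / 0.5),
                       function(x) 1e-4 * x, 1L, 1, 0, v_min = 0)
  r <- run_dmc(pot, n_walkers = 400, n_steps = 1500, n_equil = 500,
               dt = 10, n_traj = 1, seed = 6, hole_tol_cm1 = 10)
  rep_ <- hole_scan(r)
  expect_gt(nrow(rep_), 0)
  expect_true(all(rep_$energy_below_min_cm1 > 10))

  # tolerance larger than the pocket depth: nothing flagged
  r2 <- run_dmc(pot, n_walkers = 400, n_steps = 1500, n_equil = 500,
                dt = 10, n_traj = 1, seed = 6, hole_tol_cm1 = 2000)
  expect_equal(nrow(hole_scan(r2)), 0L)

  # a potential bounded below by its minimum never reports holes
  hp <- harmonic_potential(k = 1e-4, m = 1, n_dof = 1)
  r3 <- run_dmc(hp, n_walkers = 300, n_steps = 1000, n_equil = 300,
                dt = 5, n_traj = 1, seed = 7)
  expect_equal(nrow(hole_scan(r3)), 0L)
})
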