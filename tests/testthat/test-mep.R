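# The full Morse-diatomic recovery run lives in test-acceptance.R; these
# are the semantic checks.

test_that("zero initial kinetic energy at the minimum stays at the minimum", {
  pot <- morse_sum_potential("A2", De = 0.01, a_morse = 1.0, r_e = 1.2)
  start <- matrix(c(0, 0, 0, 1.2, 0, 0), 3)
  p <- anneal_mep(pot, start, pair = c(1, 2), initial_ke_cm1 = 1e-9,
                  loss_fraction = 1e-3, max_steps = 5000,
                  ke_tol_cm1 = 1e-2, gtol = 1e-5)
  expect_equal(p$r_min, 1.2, tolerance = 1e-3)
  expect_lt(max(abs(p$profile$coord - 1.2)), 0.02)
})

test_that("the brake caps the kinetic energy once triggered", {
  # steep well: dropping in from the wall gains far more than 100 cm^-1
  pot <- morse_sum_potential("A2", De = 0.02, a_morse = 1.5, r_e = 1.4)
  start <- matrix(c(0, 0, 0, 3.5, 0, 0), 3)
  p_on <- anneal_mep(pot, start, pair = c(1, 2), initial_ke_cm1 = 12,
                     loss_fraction = 1e-3, brake_cm1 = 100,
                     brake_factor = 0.5, max_steps = 6e4,
                     ke_tol_cm1 = 0.1, gtol = 1e-4)
  p_off <- anneal_mep(pot, start, pair = c(1, 2), initial_ke_cm1 = 12,
                      loss_fraction = 1e-3, brake_cm1 = 1e9,
                      brake_factor = 0.5, max_steps = 3e5,
                      ke_tol_cm1 = 0.1, gtol = 1e-4)
  expect_equal(p_on$terminated, "converged")
  expect_equal(p_off$terminated, "converged")
  expect_equal(p_on$r_min, 1.4, tolerance = 5e-3)
  expect_equal(p_off$r_min, 1.4, tolerance = 5e-3)
  # braking shortens the annealing: less energy to dissipate at rate loss*KE
  expect_lt(p_on$steps, p_off$steps)
})

test_that("paths merge on overlap and disagree on nothing when identical", {
  pot <- morse_sum_potential("A2", De = 0.01, a_morse = 1.0, r_e = 1.2)
  start <- matrix(c(0, 0, 0, 4, 0, 0), 3)
  p <- anneal_mep(pot, start, pair = c(1, 2), initial_ke_cm1 = 12,
                  loss_fraction = 1e-3, max_steps = 1e5,
                  ke_tol_cm1 = 1e-2, gtol = 1e-5)
  m <- merge_paths(list(p, p))
  expect_equal(attr(m, "overlap_disagreement_cm1"), 0)
  expect_equal(m$r_min, p$r_min)
  expect_true(all(diff(m$profile$coord) > 0))
})

test_that("inner-wall and outer paths merge into the analytic Morse curve", {
  De <- 0.01; a_m <- 1.0; re <- 1.2
  pot <- morse_sum_potential("A2", De = De, a_morse = a_m, r_e = re)
  outer <- anneal_mep(pot, matrix(c(0, 0, 0, 6, 0, 0), 3), pair = c(1, 2),
                      initial_ke_cm1 = 12, loss_fraction = 5e-4,
                      max_steps = 2e5, ke_tol_cm1 = 1e-2, gtol = 1e-5)
  inner <- anneal_mep(pot, matrix(c(0, 0, 0, 0.8, 0, 0), 3), pair = c(1, 2),
                      initial_ke_cm1 = 12, loss_fraction = 5e-4,
                      max_steps = 2e5, ke_tol_cm1 = 1e-2, gtol = 1e-5)
  m <- merge_paths(list(inner, outer))
  # relaxed 1D curve must match the analytic Morse profile
  exact <- function(r) De * ((1 - exp(-a_m * (r - re)))^2 - 1)
  err <- abs(m$profile$energy_h - exact(m$profile$coord))
  expect_lt(max(err) / De, 0.005)
})

test_that("disjoint paths refuse to merge", {
  pot <- morse_sum_potential("A2", De = 0.01, a_morse = 1.0, r_e = 1.2)
  mk <- function(lo, hi) {
    prof <- data.frame(coord = seq(lo, hi, by = 0.05),
                       energy_h = 0, energy_cm1 = 0)
    structure(list(profile = prof, r_min = lo, e_min = 0, steps = 1L,
                   terminated = "converged", final = NULL,
                   bin_width = 0.05, pair = c(1L, 2L)), class = "mep_path")
  }
  expect_error(merge_paths(list(mk(1, 2), mk(5, 6))), "overlap")
})

test_that("dissociation energy requires a plateau", {
  pot <- morse_sum_potential("A2", De = 0.01, a_morse = 1.0, r_e = 1.2)
  # truncated path: stops at 3 bohr where the curve still climbs
  p <- anneal_mep(pot, matrix(c(0, 0, 0, 3, 0, 0), 3), pair = c(1, 2),
                  initial_ke_cm1 = 12, loss_fraction = 1e-3,
                  max_steps = 1e5, ke_tol_cm1 = 1e-2, gtol = 1e-5)
  expect_error(dissociation_energy(p), "plateau")

  # flat potential: De = 0
  flat <- data.frame(coord = seq(1, 10, by = 0.05), energy_h = -0.3)
  flat$energy_cm1 <- 0
  pf <- structure(list(profile = flat, r_min = 1, e_min = -0.3, steps = 1L,
                       terminated = "converged", final = NULL,
                       bin_width = 0.05, pair = c(1L, 2L)),
                  class = "mep_path")
  expect_equal(dissociation_energy(pf), 0)
})
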