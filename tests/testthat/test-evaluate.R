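test_that("energy evaluation is linear in the coefficients", {
  set.seed(1)
  b <- pip_basis("A2B", 3)
  g <- random_geometry("A2B")
  zero <- pes_model(b, numeric(b$size))
  expect_equal(pes_energy(zero, g), 0)

  coefs <- rnorm(b$size)
  m1 <- pes_model(b, coefs)
  m2 <- pes_model(b, 2 * coefs)
  expect_equal(pes_energy(m2, g), 2 * pes_energy(m1, g), tolerance = 1e-12)
})

test_that("energy is invariant under like-atom exchange", {
  set.seed(5)
  m <- a5b2_model(order = 2)
  g <- random_geometry("A5B2")
  e0 <- pes_energy(m, g)
  # swap the two B atoms (positions 6 and 7)
  sw <- c(1:5, 7, 6)
  gs <- geometry(g$elements, g$coords[, sw], g$masses)
  expect_lt(abs(pes_energy(m, gs) - e0) / abs(e0), 1e-12)
})

test_that("reverse, forward and finite-difference gradients agree", {
  set.seed(6)
  m <- a5b2_model(order = 2)
  for (i in 1:20) {
    g <- random_geometry("A5B2")
    gr <- pes_gradient(m, g, "reverse")
    gf <- pes_gradient(m, g, "forward")
    gd <- pes_gradient(m, g, "fd", step = 1e-4)
    scale <- max(abs(gr$gradient))
    expect_lt(max(abs(gr$gradient - gf$gradient)) / scale, 1e-10)
    expect_lt(max(abs(gr$gradient - gd$gradient)) / scale, 1e-6)
  }
})

test_that("net force and net torque vanish (distance-only dependence)", {
  set.seed(7)
  m <- a5b2_model(order = 2)
  for (i in 1:5) {
    g <- random_geometry("A5B2")
    gr <- matrix(pes_gradient(m, g, "reverse")$gradient, 3)
    expect_lt(max(abs(rowSums(gr))), 1e-10)
    torque <- rowSums(vapply(seq_len(ncol(gr)), function(a)
      c(g$coords[2, a] * gr[3, a] - g$coords[3, a] * gr[2, a],
        g$coords[3, a] * gr[1, a] - g$coords[1, a] * gr[3, a],
        g$coords[1, a] * gr[2, a] - g$coords[2, a] * gr[1, a]),
      numeric(3)))
    expect_lt(max(abs(torque)), 1e-10)
  }
})

test_that("gradients are equivariant under like-atom permutations", {
  set.seed(8)
  m <- a5b2_model(order = 2)
  g <- random_geometry("A5B2")
  gr0 <- matrix(pes_gradient(m, g, "reverse")$gradient, 3)
  sym <- pip_symmetry("A5B2")
  for (gi in sample(sym$group_order, 10)) {
    sigma <- sym$atom_perms[gi, ]
    gp <- geometry(g$elements, g$coords[, sigma], g$masses)
    grp <- matrix(pes_gradient(m, gp, "reverse")$gradient, 3)
    expect_equal(grp, gr0[, sigma], tolerance = 1e-10)
  }
})

test_that("zero-coefficient models have zero gradient and coincident atoms error", {
  b <- pip_basis("A2", 3)
  zero <- pes_model(b, numeric(b$size))
  g <- geometry(c("H", "H"), matrix(c(0, 0, 0, 2, 0, 0), 3))
  expect_equal(pes_gradient(zero, g, "reverse")$gradient, numeric(6))
  gc <- geometry(c("H", "H"), matrix(c(0, 0, 0, 0, 0, 1e-10), 3))
  m <- pes_model(b, rep(1, b$size))
  expect_error(pes_gradient(m, gc, "reverse"), "oincident")
})

test_that("reverse gradient cost is a small constant multiple of the energy cost", {
  for (order in 2:3) {
    ops <- count_operations(pip_basis("A5B2", order))
    expect_lt(unname(ops["reverse"] / ops["energy"]), 5)
  }
})

test_that("the numeric Hessian is symmetric, translationally null and exact on quadratics", {
  set.seed(10)
  m <- a5b2_model(order = 2)
  g <- random_geometry("A5B2")
  H_raw <- pes_hessian(m, g, symmetrize = FALSE)
  expect_lt(max(abs(H_raw - t(H_raw))), 1e-6)
  H <- pes_hessian(m, g)
  # uniform x-translation is a zero mode
  tx <- rep(c(1, 0, 0), 7)
  expect_lt(max(abs(H %*% tx)), 1e-6)

  # analytic check on a quadratic toy potential
  k <- c(0.3, 0.7, 1.1)
  quad <- harmonic_potential(k = k, m = 1, n_dof = 3)
  Hq <- pipfit:::.num_hessian(function(x) pot_gradient(quad, x),
                              c(0.2, -0.1, 0.4), step = 1e-3)
  expect_equal(Hq, diag(k), tolerance = 1e-8)
})

test_that("predict dispatches over geometries, datasets and matrices", {
  set.seed(11)
  ds <- a2b_dataset(n = 20, seed = 2)
  f <- pip_fit(ds, pip_basis("A2B", 3))
  e1 <- predict(f, ds$geoms[[1]])
  expect_equal(predict(f, ds)[1], e1, tolerance = 1e-12)
  expect_equal(predict(f, ds$geoms[[1]]$coords), e1, tolerance = 1e-12)
  expect_equal(predict(f, ds$geoms[1:3])[1], e1, tolerance = 1e-12)
})
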