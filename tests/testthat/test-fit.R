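test_that("the energy weight w(E) = delta/(E + delta) behaves as specified", {
  expect_equal(energy_weight(0, 0.1), 1)
  expect_equal(energy_weight(0.1, 0.1), 0.5)
  expect_equal(energy_weight(0.3, 0.1), 0.25)
  E <- seq(0, 1, by = 0.05)
  expect_true(all(diff(energy_weight(E)) < 0))
  expect_error(energy_weight(-0.01), "non-negative")
})

test_that("energy filtering keeps records at or below the ceiling", {
  set.seed(1)
  geoms <- lapply(1:5, function(i) random_geometry("A2"))
  rel <- cm1_to_hartree(c(0, 100, 59999, 60001, 110000))
  ds <- pip_dataset(geoms, -0.2 + rel)
  kept <- filter_by_energy(ds, 60000)
  expect_equal(length(kept), 3L)
  expect_equal(attr(kept, "n_dropped"), 2L)
  expect_equal(length(filter_by_energy(ds, Inf)), 5L)
  # a reference well below the dataset puts every record above the ceiling
  expect_warning(empty <- filter_by_energy(ds, 1, reference_energy = -0.4),
                 "every record")
  expect_equal(length(empty), 0L)
})

test_that("noiseless in-span data is recovered to numerical precision", {
  set.seed(9)
  b <- pip_basis("A2B", 3)
  geoms <- lapply(1:120, function(i) random_geometry("A2B", scale = 1.2))
  ctrue <- rnorm(b$size, sd = 0.05)
  Y <- sapply(geoms, function(g) morse_transform(interatomic_distances(g)))
  E <- as.numeric(basis_values(b, Y) %*% ctrue)
  ds <- pip_dataset(geoms, E)
  for (w in c("energy", "none")) {
    f <- pip_fit(ds, b, weights = w)
    expect_lt(max(abs(coef(f) - ctrue)) / max(abs(ctrue)), 1e-8)
    expect_lt(f$fit$rmse_cm1, 1e-6)
  }
})

test_that("constant datasets are fit exactly by the constant term", {
  set.seed(2)
  geoms <- lapply(1:10, function(i) random_geometry("A2"))
  ds <- pip_dataset(geoms, rep(-0.5, 10))
  expect_warning(f <- pip_fit(ds, pip_basis("A2", 2)), NA)
  expect_lt(f$fit$rmse_cm1, 1e-8)
})

test_that("RMSE decreases monotonically with polynomial order on a Morse-sum fixture", {
  ds <- a2b_dataset(n = 300, seed = 7)
  rmse <- vapply(2:4, function(ord)
    pip_fit(ds, pip_basis("A2B", ord))$fit$rmse_cm1, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("fit metrics satisfy their defining identities", {
  ds <- a2b_dataset(n = 80, seed = 4)
  f <- pip_fit(ds, pip_basis("A2B", 4))
  met <- fit_metrics(f, ds)
  expect_equal(met$rmse_cm1, f$fit$rmse_cm1, tolerance = 1e-10)
  expect_gte(met$rmse_cm1, met$mae_cm1)   # norm inequality
  expect_lte(met$wrmse_cm1, met$rmse_cm1) # weights <= 1, normalized
  expect_gt(met$r_squared, 0.99)

  # a perfect model: metrics of the model on data it generated
  E <- predict(f, ds)
  ds2 <- pip_dataset(ds$geoms, E)
  met2 <- fit_metrics(f, ds2)
  expect_lt(met2$rmse_cm1, 1e-8)
  expect_lt(met2$mae_cm1, 1e-8)
  expect_equal(met2$r_squared, 1, tolerance = 1e-12)
})

test_that("residuals are weight-orthogonal to the design and SVD matches QR", {
  set.seed(3)
  ds <- a2b_dataset(n = 150, seed = 5)
  b <- pip_basis("A2B", 3)
  f <- pip_fit(ds, b)
  Y <- sapply(ds$geoms, function(g) morse_transform(interatomic_distances(g)))
  B <- basis_values(b, Y)
  # filtering happened inside the fit only if emax set; here unfiltered
  w <- f$fit$weights
  r <- f$fit$fitted - ds$energies
  expect_lt(max(abs(crossprod(B, w * r))) / max(abs(crossprod(B, w * ds$energies))),
            1e-8)
  # independent solver: weighted QR
  cq <- qr.coef(qr(B * sqrt(w)), ds$energies * sqrt(w))
  expect_equal(unname(cq), coef(f), tolerance = 1e-8)
})

test_that("under-determined systems warn and return the minimum-norm solution", {
  set.seed(12)
  ds <- a2b_dataset(n = 220, seed = 8)
  ds_small <- pip_dataset(ds$geoms[1:10], ds$energies[1:10])
  expect_warning(
    expect_warning(f <- pip_fit(ds_small, pip_basis("A2B", 3)),
                   "under-determined"),
    "rank-deficient")
  expect_lt(f$fit$rmse_cm1, 1e-4)  # interpolates the 10 points
})

test_that("basis augmentation appends invariant, highest-scoring products", {
  sym <- pip_symmetry("A3")
  pot <- morse_sum_potential("A3", De = 0.03, a_morse = 1.1, r_e = 1.7)
  ds <- sample_dataset(pot, "A3", n_points = 40, seed = 3, sigma = 0.15)
  b <- pip_basis("A3", 2)
  ba <- augment_basis(b, ds, target_size = b$size + 2)
  expect_equal(ba$size, b$size + 2L)

  # appended polynomials stay exactly invariant
  set.seed(13)
  y <- runif(3, 0.1, 0.9)
  v0 <- basis_values(ba, y)
  for (g in seq_len(sym$group_order)) {
    vg <- basis_values(ba, y[sym$pair_perms[g, ]])
    expect_lt(max(abs(vg - v0)), 1e-12)
  }

  # brute-force oracle: score every candidate product by hand
  polys <- lapply(seq_len(b$size), function(j) pipfit:::.basis_poly(b, j))
  degs <- b$degree
  Y <- sapply(ds$geoms, function(g) morse_transform(interatomic_distances(g)))
  cand_scores <- c(); cand_keys <- c()
  nonconst <- which(degs >= 1)
  for (ii in seq_along(nonconst)) for (jj in ii:length(nonconst)) {
    i <- nonconst[ii]; j <- nonconst[jj]
    if (degs[i] + degs[j] > b$max_order + 1) next
    pr <- pipfit:::.poly_product(polys[[i]]$mono, polys[[i]]$coef,
                                 polys[[j]]$mono, polys[[j]]$coef)
    key <- pipfit:::.poly_key(pr$mono, pr$coef)
    if (key %in% cand_keys) next
    vals <- apply(Y, 2, function(y) sum(pr$coef * apply(pr$mono, 1, function(e)
      prod(y^e))))
    cand_keys <- c(cand_keys, key)
    cand_scores <- c(cand_scores, max(abs(vals)))
  }
  best2 <- cand_keys[order(cand_scores, decreasing = TRUE)][1:2]
  appended <- vapply((b$size + 1):ba$size, function(j) {
    p <- pipfit:::.basis_poly(ba, j)
    pipfit:::.poly_key(p$mono, p$coef)
  }, character(1))
  expect_setequal(appended, best2)
})

test_that("with a single-geometry dataset the appended product is the pointwise argmax", {
  g <- random_geometry("A3")
  ds1 <- pip_dataset(list(g), -0.1)
  b <- pip_basis("A3", 2)
  ba <- augment_basis(b, ds1, target_size = b$size + 1)
  y <- morse_transform(interatomic_distances(g))
  vals <- basis_values(ba, y)
  # recompute all candidate values at this geometry; appended must be max
  polys <- lapply(seq_len(b$size), function(j) pipfit:::.basis_poly(b, j))
  degs <- b$degree
  best <- -Inf
  nonconst <- which(degs >= 1)
  for (ii in seq_along(nonconst)) for (jj in ii:length(nonconst)) {
    i <- nonconst[ii]; j <- nonconst[jj]
    if (degs[i] + degs[j] > b$max_order + 1) next
    pr <- pipfit:::.poly_product(polys[[i]]$mono, polys[[i]]$coef,
                                 polys[[j]]$mono, polys[[j]]$coef)
    v <- sum(pr$coef * apply(pr$mono, 1, function(e) prod(y^e)))
    best <- max(best, abs(v))
  }
  expect_equal(abs(vals[ba$size]), best, tolerance = 1e-12)
})
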