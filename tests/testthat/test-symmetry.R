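test_that("symmetry strings parse into atom classes and group sizes", {
  s <- pip_symmetry("A5B2")
  expect_equal(s$n_atoms, 7L)
  expect_equal(s$n_pairs, 21L)
  expect_equal(s$group_order, 240L)   # 5! * 2!

  s2 <- pip_symmetry("A2")
  expect_equal(s2$n_atoms, 2L)
  expect_equal(s2$n_pairs, 1L)
  expect_equal(s2$group_order, 2L)

  s3 <- pip_symmetry("A1B1")
  expect_equal(s3$group_order, 1L)

  # missing count means 1
  expect_equal(pip_symmetry("A2B")$classes$count, c(2L, 1L))

  expect_error(pip_symmetry("A0B2"), "zero count")
  expect_error(pip_symmetry("5A"), "malformed")
  expect_error(pip_symmetry("A2A3"), "repeated")
})

test_that("the induced pair-permutation group is a group", {
  for (spec in c("A2", "A3", "A2B", "A5B2")) {
    s <- pip_symmetry(spec)
    pp <- s$pair_perms
    expect_equal(nrow(pp), s$group_order)
    # identity present
    expect_true(any(apply(pp, 1, function(p) all(p == seq_len(s$n_pairs)))))
    # every row a bijection
    expect_true(all(apply(pp, 1, function(p) all(sort(p) == seq_len(s$n_pairs)))))
    # closure under composition (sampled for the big group)
    keys <- apply(pp, 1, paste, collapse = ",")
    idx <- if (s$group_order > 24) {
      set.seed(1); cbind(sample(s$group_order, 30, TRUE),
                         sample(s$group_order, 30, TRUE))
    } else as.matrix(expand.grid(seq_len(s$group_order), seq_len(s$group_order)))
    for (r in seq_len(nrow(idx))) {
      comp <- pp[idx[r, 1], ][pp[idx[r, 2], ]]
      expect_true(paste(comp, collapse = ",") %in% keys)
    }
  }
  # for A2 the non-identity atom swap fixes the single (unordered) pair
  expect_equal(unname(pip_symmetry("A2")$pair_perms), matrix(1L, 2, 1))
})

test_that("orbit enumeration reproduces known per-degree counts", {
  # single pair variable: one orbit per degree
  b <- pip_basis("A1B1", 4)
  expect_equal(unname(table(b$degree)), array(rep(1L, 5)))  # degrees 0..4
  expect_equal(b$size, 5L)

  # A3 at order 2: one degree-1 orbit; squares + cross products at degree 2
  b3 <- pip_basis("A3", 2)
  expect_equal(sum(b3$degree == 1), 1L)
  expect_equal(sum(b3$degree == 2), 2L)

  # A5B2 degree 1: one orbit per pair class (AA, AB, BB)
  expect_equal(sum(pip_basis("A5B2", 1)$degree == 1), 3L)

  # trivial group: orbit count equals the number of monomials (binomial)
  b111 <- pip_basis("A1B1C1", 3, include_constant = FALSE)
  expect_equal(b111$size, choose(3 + 3, 3) - 1L)
})

test_that("Burnside counting agrees with explicit orbit enumeration", {
  cases <- list(c("A2", 5), c("A3", 4), c("A2B", 4), c("A4", 3),
                c("A1B1C1", 3), c("A5B2", 3))
  for (cs in cases) {
    spec <- cs[1]; M <- as.integer(cs[2])
    counted <- count_invariants(spec, M)
    b <- pip_basis(spec, M, include_constant = FALSE)
    enum <- tabulate(b$degree, nbins = M)
    expect_equal(as.vector(counted), enum,
                 info = paste("per-degree counts for", spec, "order", M))
    expect_equal(b$size, sum(counted))
  }
})

test_that("basis size is monotone non-decreasing in max order", {
  sizes <- vapply(1:5, function(M) pip_basis("A2B", M, expand = FALSE)$size,
                  integer(1))
  expect_true(all(diff(sizes) > 0))
})

test_that("every basis polynomial is exactly group invariant", {
  set.seed(4)
  for (spec in c("A3", "A2B", "A5B2")) {
    s <- pip_symmetry(spec)
    b <- pip_basis(spec, if (spec == "A5B2") 2 else 4)
    for (rep_ in 1:3) {
      y <- runif(s$n_pairs, 0.05, 0.95)
      v0 <- basis_values(b, y)
      gs <- if (s$group_order > 24) sample(s$group_order, 12) else seq_len(s$group_order)
      for (g in gs) {
        vg <- basis_values(b, y[s$pair_perms[g, ]])
        expect_lt(max(abs(vg - v0) / pmax(abs(v0), 1e-300)), 1e-12)
      }
    }
  }
})

test_that("monomial symmetrization returns the canonical orbit sum", {
  # A2: the single pair variable is fixed, orbit size 1
  sm <- symmetrize_monomial(c(2L), "A2")
  expect_equal(sm$orbit_size, 1L)

  # A3: y1 y2 -> y1y2 + y1y3 + y2y3
  sm3 <- symmetrize_monomial(c(1, 1, 0), "A3")
  expect_equal(sm3$orbit_size, 3L)
  expect_equal(sm3$canonical, c(1L, 1L, 0L))

  # same polynomial from any orbit member
  for (e in list(c(1, 0, 1), c(0, 1, 1))) {
    alt <- symmetrize_monomial(e, "A3")
    expect_equal(alt$mono, sm3$mono)
  }

  expect_error(symmetrize_monomial(c(0, 0, 0), "A3"), "constant")
})

test_that("combinatorially infeasible enumerations raise a resource error", {
  expect_error(pip_basis("A5B2", 7, cap = 1000), "cap")
})
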