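# shared fixtures, built in code at test time

# random geometry with atoms laid out class-by-class for a symmetry,
# displaced about a loose cluster so no two atoms coincide
random_geometry <- function(sym, scale = 2.0) {
  sym <- pip_symmetry(sym)
  n <- sym$n_atoms
  repeat {
    x <- matrix(rnorm(3 * n, sd = scale), 3, n) +
      3 * cbind(matrix(0, 3, 0), sapply(seq_len(n), function(i)
        c(cos(2 * pi * i / n), sin(2 * pi * i / n), 0.3 * i / n)))
    if (min(interatomic_distances(x)) > 0.5) break
  }
  els <- rep(c("H", "O", "C", "N")[seq_len(nrow(sym$classes))],
             sym$classes$count)
  geometry(els, x)
}

# small A5B2 model with reproducible random coefficients
a5b2_model <- function(order = 2, seed = 1, decay = TRUE) {
  b <- pip_basis("A5B2", order)
  set.seed(seed)
  coefs <- rnorm(b$size, sd = 0.1)
  if (decay) coefs <- coefs / (1 + b$degree)^2
  pes_model(b, coefs)
}

# apply an atom permutation (vector sigma, atom i -> position sigma[i])
permute_geometry <- function(geom, sigma) {
  inv <- order(sigma)
  geometry(geom$elements[inv], geom$coords[, inv], geom$masses[inv])
}

# A2B Morse-sum potential + dataset used across fitting tests
a2b_potential <- function() {
  morse_sum_potential("A2B", De = c(AA = 0.02, AB = 0.05),
                      a_morse = c(AA = 1.0, AB = 1.2),
                      r_e = c(AA = 1.8, AB = 1.6))
}

a2b_dataset <- function(n = 300, seed = 7, cap = 30000) {
  sample_dataset(a2b_potential(), "A2B", n_points = n, seed = seed,
                 sigma = 0.2, energy_cap_cm1 = cap)
}
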