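# Analytic toy potentials and synthetic datasets.  These emulate the
# structure of ab initio PES datasets — near-equilibrium sampling plus
# stretched, dissociative configurations — with closed-form energies and
# gradients, so fitting, DMC and path-following are testable end to end.

# ---- potential-callable protocol ---------------------------------------
# Anything with these generics can drive DMC, geometry optimization and
# MEP annealing: energies for a batch of configurations (columns of a
# dof x W matrix), an analytic gradient at one configuration, per-dof
# masses, a starting configuration and (if known) the potential minimum.

#' Potential-callable interface
#'
#' Generic accessors implemented by toy potentials
#' ([morse_sum_potential()], [harmonic_potential()], ...) and by fitted
#' `pip_pes` surfaces wrapped with [pes_potential()].  `pot_energy_batch`
#' evaluates columns of a `dof x W` matrix; `pot_gradient` returns the
#' analytic gradient at one configuration.
#'
#' @param pot a potential object.
#' @param x numeric configuration vector (length = degrees of freedom).
#' @param X matrix of configurations, one per column.
#' @name potential-protocol
NULL

#' @rdname potential-protocol
#' @export
pot_energy <- function(pot, x) UseMethod("pot_energy")

#' @rdname potential-protocol
#' @export
pot_energy_batch <- function(pot, X) UseMethod("pot_energy_batch")

#' @rdname potential-protocol
#' @export
pot_gradient <- function(pot, x) UseMethod("pot_gradient")

#' @rdname potential-protocol
#' @export
pot_masses <- function(pot) UseMethod("pot_masses")

#' @rdname potential-protocol
#' @export
pot_start <- function(pot) UseMethod("pot_start")

#' @rdname potential-protocol
#' @export
pot_vmin <- function(pot) UseMethod("pot_vmin")

#' @export
pot_energy.toy_potential <- function(pot, x)
  pot$energy_batch(matrix(as.numeric(x), ncol = 1L))[1L]

#' @export
pot_energy_batch.toy_potential <- function(pot, X) pot$energy_batch(X)

#' @export
pot_gradient.toy_potential <- function(pot, x) pot$gradient(as.numeric(x))

#' @export
pot_masses.toy_potential <- function(pot) pot$masses

#' @export
pot_start.toy_potential <- function(pot) pot$x_start

#' @export
pot_vmin.toy_potential <- function(pot) pot$v_min

#' @export
print.toy_potential <- function(x, ...) {
  cat("Toy potential:", x$kind, "-", x$n_dof, "degrees of freedom\n")
  invisible(x)
}

#' Wrap a fitted PIP surface as a potential callable
#'
#' @param model a `pip_pes`.
#' @param template a `pip_geometry` supplying elements, masses and the
#'   starting configuration (its coordinates, flattened column-wise).
#' @param v_min potential value at the global minimum (hartree); if
#'   `NULL`, the energy at `template` is used.
#' @return an object implementing the potential protocol.
#' @export
pes_potential <- function(model, template, v_min = NULL) {
  stopifnot(inherits(model, "pip_pes"), inherits(template, "pip_geometry"))
  .check_geom(model, template)
  structure(list(model = model, template = template,
                 v_min = v_min %||% pes_energy(model, template)),
            class = "pes_potential")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
pot_energy.pes_potential <- function(pot, x)
  pes_energy(pot$model, matrix(as.numeric(x), 3L))

#' @export
pot_energy_batch.pes_potential <- function(pot, X)
  .pes_energy_batch(pot$model, X)

#' @export
pot_gradient.pes_potential <- function(pot, x)
  pes_gradient(pot$model, matrix(as.numeric(x), 3L), "reverse")$gradient

#' @export
pot_masses.pes_potential <- function(pot) rep(pot$template$masses, each = 3L)

#' @export
pot_start.pes_potential <- function(pot) as.numeric(pot$template$coords)

#' @export
pot_vmin.pes_potential <- function(pot) pot$v_min

# ---- toy potentials -----------------------------------------------------

.toy <- function(kind, energy_batch, gradient, n_dof, masses, x_start,
                 v_min = NULL, ...) {
  structure(list(kind = kind, energy_batch = energy_batch,
                 gradient = gradient, n_dof = n_dof,
                 masses = masses, x_start = x_start, v_min = v_min,
                 params = list(...)),
            class = "toy_potential")
}

#' Harmonic toy potential
#'
#' `V = 0.5 * sum_k k_k (x_k - x0_k)^2`, separable, with exact zero-point
#' energy `0.5 * sum_k sqrt(k_k / m_k)` (hartree, atomic units).
#'
#' @param k force constants (hartree/bohr^2), recycled over dofs.
#' @param m masses in electron masses, recycled.
#' @param n_dof number of degrees of freedom.
#' @param x0 equilibrium position, recycled.
#' @return a `toy_potential`; the exact ZPE is in `$params$zpe`.
#' @export
harmonic_potential <- function(k, m = 1, n_dof = length(k), x0 = 0) {
  k <- rep_len(k, n_dof); m <- rep_len(m, n_dof); x0 <- rep_len(x0, n_dof)
  stopifnot(all(k > 0), all(m > 0))
  .toy("harmonic",
       energy_batch = function(X) colSums(0.5 * k * (X - x0)^2),
       gradient = function(x) k * (x - x0),
       n_dof = n_dof, masses = m, x_start = x0, v_min = 0,
       k = k, zpe = 0.5 * sum(sqrt(k / m)))
}

#' Pairwise Morse-sum toy potential
#'
#' `V = sum_pairs De * ((1 - exp(-a_morse (r - r_e)))^2 - 1)`: each
#' unordered atom pair contributes a Morse well of depth `De` centred at
#' `r_e`, going to 0 at dissociation.  Parameters may be scalars (shared
#' by all pairs) or named by pair class (`"AA"`, `"AB"`, ...); sharing
#' parameters within pair classes makes the potential exactly invariant
#' under the symmetry's atom permutations.
#'
#' For a diatomic the exact well depth is `De`, the minimum is at `r_e`,
#' and the harmonic frequency is `a_morse * sqrt(2 De / mu)` with `mu`
#' the reduced mass; the exact vibrational ground state lies at
#' `0.5 * omega - omega^2 / (16 De)` above the well bottom.
#'
#' @param sym a `pip_symmetry` or symmetry string.
#' @param De well depth (hartree), scalar or named per pair class.
#' @param a_morse range parameter (1/bohr), scalar or named.
#' @param r_e equilibrium pair distance (bohr), scalar or named.
#' @param elements element symbols per symmetry class (defaults to
#'   `H, O, C, N, ...` in class order) — sets the atom masses.
#' @return a `toy_potential` over `3 * n_atoms` Cartesian dofs; the
#'   starting configuration is a relaxed near-equilibrium arrangement.
#' @export
morse_sum_potential <- function(sym, De, a_morse, r_e, elements = NULL) {
  sym <- pip_symmetry(sym)
  n <- sym$n_atoms
  p <- .pair_table(n)
  cls <- rep(sym$classes$label, sym$classes$count)
  pair_class <- paste0(pmin(cls[p[, 1L]], cls[p[, 2L]]),
                       pmax(cls[p[, 1L]], cls[p[, 2L]]))
  pick <- function(par, nm) {
    if (is.null(names(par))) rep_len(par, length(nm))
    else {
      if (!all(nm %in% names(par)))
        stop("missing pair-class parameter for ",
             paste(setdiff(unique(nm), names(par)), collapse = ", "))
      unname(par[nm])
    }
  }
  De_k <- pick(De, pair_class)
  a_k <- pick(a_morse, pair_class)
  re_k <- pick(r_e, pair_class)
  stopifnot(all(De_k > 0), all(a_k > 0), all(re_k > 0))

  if (is.null(elements))
    elements <- c("H", "O", "C", "N", "S", "P")[seq_len(nrow(sym$classes))]
  el <- rep(elements, sym$classes$count)
  masses3 <- rep(atomic_mass(el), each = 3L)

  energy_batch <- function(X) {
    W <- ncol(X); V <- numeric(W)
    for (k in seq_len(nrow(p))) {
      i <- (p[k, 1L] - 1L) * 3L; j <- (p[k, 2L] - 1L) * 3L
      r <- sqrt((X[i + 1L, ] - X[j + 1L, ])^2 + (X[i + 2L, ] - X[j + 2L, ])^2 +
                  (X[i + 3L, ] - X[j + 3L, ])^2)
      q <- exp(-a_k[k] * (r - re_k[k]))
      V <- V + De_k[k] * ((1 - q)^2 - 1)
    }
    V
  }
  gradient <- function(x) {
    X <- matrix(x, 3L)
    g <- matrix(0, 3L, n)
    for (k in seq_len(nrow(p))) {
      i <- p[k, 1L]; j <- p[k, 2L]
      d <- X[, i] - X[, j]
      r <- sqrt(sum(d * d))
      q <- exp(-a_k[k] * (r - re_k[k]))
      dVdr <- 2 * De_k[k] * a_k[k] * q * (1 - q)
      u <- d / r
      g[, i] <- g[, i] + dVdr * u
      g[, j] <- g[, j] - dVdr * u
    }
    as.numeric(g)
  }

  x_start <- .relaxed_layout(n, mean(re_k), gradient, energy_batch)
  v_min <- if (n == 2L) -De_k[1L] else energy_batch(matrix(x_start, ncol = 1L))
  .toy("morse_sum", energy_batch, gradient, 3L * n, masses3, x_start,
       v_min = v_min, De = De_k, a_morse = a_k, r_e = re_k,
       pair_class = pair_class, elements = el, symmetry = sym)
}

# near-equilibrium starting layout: regular polygon scaled to the mean
# pair distance, then relaxed with the analytic gradient
.relaxed_layout <- function(n, r0, gradient, energy_batch) {
  if (n == 2L) {
    x <- rbind(c(0, r0), 0, 0)
  } else {
    th <- 2 * pi * (seq_len(n) - 1L) / n
    R <- r0 / (2 * sin(pi / n))
    x <- rbind(R * cos(th), R * sin(th), 0.1 * seq_len(n) / n)  # break planarity
  }
  x <- as.numeric(x)
  fit <- optim(x, fn = function(v) energy_batch(matrix(v, ncol = 1L)),
               gr = gradient, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit$par
}

#' One-dimensional Morse oscillator
#'
#' `V = De (1 - exp(-a_morse x))^2` in the displacement `x` from the
#' minimum.  The exact ground-state energy is
#' `omega/2 - omega^2 / (16 De)` with `omega = a_morse sqrt(2 De / m)`
#' (stored in `$params$zpe`, hartree).
#'
#' @param De well depth (hartree).
#' @param a_morse range parameter (1/bohr).
#' @param m mass in electron masses.
#' @return a `toy_potential` with one degree of freedom.
#' @export
morse_1d_potential <- function(De, a_morse, m) {
  stopifnot(De > 0, a_morse > 0, m > 0)
  omega <- a_morse * sqrt(2 * De / m)
  .toy("morse_1d",
       energy_batch = function(X) De * (1 - exp(-a_morse * X[1L, ]))^2,
       gradient = function(x)
         2 * De * a_morse * exp(-a_morse * x) * (1 - exp(-a_morse * x)),
       n_dof = 1L, masses = m, x_start = 0, v_min = 0,
       De = De, a_morse = a_morse, omega = omega,
       zpe = omega / 2 - omega^2 / (16 * De))
}

#' One-dimensional double-well toy potential
#'
#' `V = h * ((x1^2 - b^2)^2 / b^4) + 0.5 * k_other * sum(x_other^2)`:
#' minima at `x1 = +-b`, a first-order saddle of height `h` at the
#' origin, harmonic in the remaining dofs.
#'
#' @param h barrier height (hartree).
#' @param b half-separation of the wells (bohr).
#' @param k_other force constant of the spectator dofs.
#' @param n_dof total degrees of freedom (>= 1).
#' @param m masses, recycled.
#' @return a `toy_potential`.
#' @export
double_well_potential <- function(h, b, k_other = 0.5, n_dof = 1, m = 1) {
  stopifnot(h > 0, b > 0, n_dof >= 1)
  m <- rep_len(m, n_dof)
  energy_batch <- function(X) {
    v <- h * (X[1L, ]^2 - b^2)^2 / b^4
    if (nrow(X) > 1L)
      v <- v + colSums(0.5 * k_other * X[-1L, , drop = FALSE]^2)
    v
  }
  gradient <- function(x) {
    g <- numeric(length(x))
    g[1L] <- 4 * h * x[1L] * (x[1L]^2 - b^2) / b^4
    if (length(x) > 1L) g[-1L] <- k_other * x[-1L]
    g
  }
  .toy("double_well", energy_batch, gradient, n_dof, m,
       x_start = c(b, numeric(n_dof - 1L)), v_min = 0,
       h = h, b = b, k_other = k_other)
}

# ---- synthetic datasets -------------------------------------------------

#' Sample a synthetic (geometry, energy) dataset from a toy potential
#'
#' Draws geometries as Gaussian displacements about the potential's
#' relaxed configuration, plus a set of stretched configurations in
#' which a designated atom pair is pulled out along its axis to large
#' separations (default ladder reaching 300 bohr) — mimicking how PES
#' datasets cover both the well region and the dissociation channel.
#' Energies above `energy_cap_cm1` (relative to the sampled minimum)
#' are discarded.
#'
#' @param potential a `toy_potential` over Cartesian dofs (e.g.
#'   [morse_sum_potential()]).
#' @param sym a `pip_symmetry` or symmetry string matching the potential.
#' @param n_points number of displacement samples before filtering.
#' @param energy_cap_cm1 retention ceiling in cm^-1 (default `Inf`).
#' @param seed RNG seed (required for reproducibility).
#' @param sigma displacement standard deviation in bohr (default 0.25).
#' @param stretch_pair atom index pair to stretch (default first and
#'   last atoms).
#' @param stretch_distances separations in bohr for the stretched
#'   configurations (default the dissociation ladder
#'   `300, 150, 75, 35, 20, 17, 14, 11, 9, 8, 7, 6, 5, 4`).
#' @param n_stretch samples per stretch distance (default 2).
#' @return a `pip_dataset`.
#' @export
sample_dataset <- function(potential, sym, n_points, energy_cap_cm1 = Inf,
                           seed = 1, sigma = 0.25,
                           stretch_pair = NULL,
                           stretch_distances = c(300, 150, 75, 35, 20, 17,
                                                 14, 11, 9, 8, 7, 6, 5, 4),
                           n_stretch = 2) {
  stopifnot(inherits(potential, "toy_potential"), n_points >= 1)
  sym <- pip_symmetry(sym)
  n <- sym$n_atoms
  stopifnot(potential$n_dof == 3L * n)
  set.seed(seed)
  x0 <- matrix(pot_start(potential), 3L, n)
  if (is.null(stretch_pair)) stretch_pair <- c(1L, n)

  X <- matrix(rep(as.numeric(x0), n_points), nrow = 3L * n) +
    matrix(rnorm(3L * n * n_points, sd = sigma), nrow = 3L * n)

  if (length(stretch_distances) > 0 && n_stretch > 0) {
    i <- stretch_pair[1L]; j <- stretch_pair[2L]
    u <- x0[, j] - x0[, i]
    u <- u / sqrt(sum(u^2))
    Xs <- lapply(rep(stretch_distances, each = n_stretch), function(d) {
      g <- x0 + matrix(rnorm(3L * n, sd = sigma / 4), 3L, n)
      g[, j] <- g[, i] + u * d
      as.numeric(g)
    })
    X <- cbind(X, do.call(cbind, Xs))
  }

  E <- pot_energy_batch(potential, X)
  vref <- pot_vmin(potential) %||% min(E)
  keep <- hartree_to_cm1(E - vref) <= energy_cap_cm1
  if (!any(keep))
    stop("energy cap of ", energy_cap_cm1, " cm^-1 retained no points")
  X <- X[, keep, drop = FALSE]; E <- E[keep]

  els <- potential$params$elements %||%
    rep(c("H", "O", "C", "N")[seq_len(nrow(sym$classes))], sym$classes$count)
  geoms <- lapply(seq_len(ncol(X)),
                  function(c_) geometry(els, matrix(X[, c_], 3L)))
  pip_dataset(geoms, E)
}
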