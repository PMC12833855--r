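# Stationary points and harmonic normal modes on a fitted surface or toy
# potential: quasi-Newton minimization with analytic (reverse) gradients,
# mass-weighted Hessian diagonalization, frequency comparison.

# resolve (energy fn, gradient fn, masses) from a pip_pes + geometry or a
# potential callable + vector
.as_surface <- function(object, x) {
  if (inherits(object, "pip_pes")) {
    list(f = function(v) pes_energy(object, matrix(v, 3L)),
         g = function(v) pes_gradient(object, matrix(v, 3L), "reverse")$gradient)
  } else {
    list(f = function(v) pot_energy(object, v),
         g = function(v) pot_gradient(object, v))
  }
}

#' Minimize a geometry on a potential surface
#'
#' Quasi-Newton (BFGS) minimization using analytic gradients, followed by
#' Newton polishing steps on the numeric Hessian until every gradient
#' component is below `gtol`.
#'
#' @param object a `pip_pes` or potential callable.
#' @param start starting configuration: `pip_geometry`, coordinate
#'   matrix, or numeric vector.
#' @param gtol gradient infinity-norm convergence threshold in
#'   hartree/bohr (default 1e-8; must be > 0).
#' @param maxit BFGS iteration cap (default 1000).
#' @return the optimized configuration, same shape as `start`, with
#'   attributes `energy` and `grad_max`.
#' @export
optimize_geometry <- function(object, start, gtol = 1e-8, maxit = 1000) {
  if (gtol <= 0) stop("gtol must be positive: a zero gradient norm is unreachable in floating point")
  geom_in <- inherits(start, "pip_geometry")
  x <- if (geom_in) as.numeric(start$coords) else as.numeric(start)
  s <- .as_surface(object, x)

  if (max(abs(s$g(x))) > gtol) {
    opt <- optim(x, fn = s$f, gr = s$g, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-15))
    x <- opt$par
    # Newton polish: BFGS stalls near machine precision, the quadratic
    # model does not
    for (it in 1:20) {
      g <- s$g(x)
      if (max(abs(g)) <= gtol) break
      H <- .num_hessian(s$g, x, step = 1e-4)
      dx <- tryCatch(solve(H + diag(1e-10, length(x)), -g),
                     error = function(e) -g)
      if (s$f(x + dx) > s$f(x)) dx <- dx / 4
      x <- x + dx
    }
  }
  g <- s$g(x)
  if (max(abs(g)) > gtol)
    stop("geometry optimization did not reach gtol = ", gtol,
         "; last |grad|max = ", format(max(abs(g))))
  out <- if (geom_in) geometry(start$elements, matrix(x, 3L), start$masses)
         else if (is.matrix(start)) matrix(x, nrow(start)) else x
  attr(out, "energy") <- s$f(x)
  attr(out, "grad_max") <- max(abs(g))
  out
}

#' Harmonic normal-mode analysis
#'
#' Diagonalizes the mass-weighted Hessian `H_ij / sqrt(m_i m_j)`;
#' harmonic wavenumbers are `sqrt(lambda)` converted to cm^-1, with
#' negative eigenvalues (imaginary frequencies, as at saddle points)
#' reported as negative numbers.  For a `pip_pes` the Hessian comes from
#' central differences of the reverse-mode gradients.
#'
#' @param object a `pip_pes` or potential callable.
#' @param geom stationary configuration (`pip_geometry`, matrix or
#'   vector).
#' @param masses per-dof masses in electron masses; defaults to the
#'   geometry's atom masses (each repeated for x, y, z) or the
#'   potential's masses.
#' @param step Hessian finite-difference step in bohr (default 1e-3).
#' @param zero_tol_cm1 modes with `|freq|` below this count as zero
#'   modes (default 5 cm^-1).
#' @return object of class `normal_modes`: `frequencies_cm1` (ascending),
#'   `modes` (mass-weighted eigenvectors, one per column, matching the
#'   frequency order), `n_zero_modes`, `grad_max`.
#' @export
normal_modes <- function(object, geom, masses = NULL, step = 1e-3,
                         zero_tol_cm1 = 5) {
  geom_in <- inherits(geom, "pip_geometry")
  x <- if (geom_in) as.numeric(geom$coords) else as.numeric(geom)
  if (is.null(masses)) {
    masses <- if (geom_in) rep(geom$masses, each = 3L)
              else if (!inherits(object, "pip_pes")) pot_masses(object)
              else stop("masses are required when geom is a bare vector")
  }
  stopifnot(length(masses) == length(x), all(masses > 0))
  s <- .as_surface(object, x)
  gmax <- max(abs(s$g(x)))
  if (gmax > 1e-4)
    warning("input is not stationary (|grad|max = ", format(gmax),
            " hartree/bohr); frequencies will be contaminated")
  H <- .num_hessian(s$g, x, step = step)
  sm <- sqrt(masses)
  Hmw <- H / outer(sm, sm)
  ev <- eigen(Hmw, symmetric = TRUE)
  lam <- rev(ev$values)               # ascending
  vec <- ev$vectors[, rev(seq_along(lam)), drop = FALSE]
  freq <- sign(lam) * sqrt(abs(lam)) * HARTREE_CM
  structure(list(frequencies_cm1 = freq, modes = vec,
                 n_zero_modes = sum(abs(freq) < zero_tol_cm1),
                 grad_max = gmax, zero_tol_cm1 = zero_tol_cm1),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat("Normal modes:", length(x$frequencies_cm1), "dofs,",
      x$n_zero_modes, "zero modes (|freq| <", x$zero_tol_cm1, "cm^-1)\n")
  vib <- x$frequencies_cm1[abs(x$frequencies_cm1) >= x$zero_tol_cm1]
  if (length(vib))
    cat("  vibrational frequencies (cm^-1):",
        paste(sprintf("%.1f", vib), collapse = ", "), "\n")
  invisible(x)
}

#' Mean absolute difference between two frequency lists
#'
#' Compares equal-length sorted frequency lists (zero modes excluded by
#' the caller), e.g. harmonic frequencies from two surfaces.
#'
#' @param freqs_a,freqs_b numeric vectors of equal length (cm^-1).
#' @return mean absolute difference in cm^-1.
#' @export
frequency_mae <- function(freqs_a, freqs_b) {
  if (length(freqs_a) != length(freqs_b))
    stop("frequency lists differ in length: ", length(freqs_a), " vs ",
         length(freqs_b))
  mean(abs(freqs_a - freqs_b))
}
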