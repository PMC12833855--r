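# Energy evaluation of a fitted PIP surface and its analytic gradients.
# The evaluation graph is: Cartesians -> distances -> Morse variables ->
# monomials -> orbit polynomials -> energy.  Reverse differentiation
# records the forward pass and sweeps adjoints back through that graph in
# a single pass; forward differentiation applies the chain rule one Morse
# variable at a time (cost proportional to the number of variables).

#' Construct a PIP potential energy surface model
#'
#' Bundles a basis with a coefficient vector.  Usually produced by
#' [pip_fit()]; this constructor is for assembling a model from known
#' coefficients (e.g. read from file).
#'
#' @param basis an expanded `pip_basis`.
#' @param coefficients numeric vector, one per basis polynomial (hartree).
#' @param a Morse range parameter in bohr (default 3.0).
#' @return object of class `pip_pes`.
#' @export
pes_model <- function(basis, coefficients, a = 3.0) {
  stopifnot(inherits(basis, "pip_basis"))
  if (is.null(basis$mono)) basis <- .expand_basis(basis)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != basis$size)
    stop("coefficient length ", length(coefficients),
         " does not match basis size ", basis$size)
  if (a <= 0) stop("range parameter `a` must be positive")
  structure(list(basis = basis, coefficients = coefficients, a = a),
            class = "pip_pes")
}

# Morse vector of a geometry (or coordinate matrix) under a model's
# conventions; errors on coincident atoms.
.model_morse <- function(model, geom) {
  r <- interatomic_distances(geom)
  if (any(r < 1e-8))
    stop("coincident atoms (r < 1e-8 bohr): gradient of the distance is undefined")
  morse_transform(r, model$a)
}

.check_geom <- function(model, geom) {
  n <- if (inherits(geom, "pip_geometry")) length(geom$elements) else ncol(geom)
  if (n != model$basis$symmetry$n_atoms)
    stop("geometry has ", n, " atoms but the basis symmetry ",
         model$basis$symmetry$spec, " requires ", model$basis$symmetry$n_atoms)
}

#' Evaluate the PES energy at a geometry
#'
#' Computes `V = sum_a c_a p_a(y)` where `y` are the Morse variables of
#' the geometry's interatomic distances.
#'
#' @param model a `pip_pes`.
#' @param geom a `pip_geometry` or 3 x N coordinate matrix in bohr.
#' @return energy in hartree.
#' @export
pes_energy <- function(model, geom) {
  stopifnot(inherits(model, "pip_pes"))
  .check_geom(model, geom)
  y <- .model_morse(model, geom)
  b <- model$basis
  sum(model$coefficients * cpp_poly_values(b$mono, b$mcoef, b$pptr, y))
}

# energies for many coordinate columns (3N x W) — used by DMC
.pes_energy_batch <- function(model, X) {
  n <- model$basis$symmetry$n_atoms
  W <- ncol(X)
  p <- .pair_table(n)
  Y <- matrix(0, model$basis$n_var, W)
  for (k in seq_len(nrow(p))) {
    i <- (p[k, 1L] - 1L) * 3L; j <- (p[k, 2L] - 1L) * 3L
    d2 <- (X[i + 1L, ] - X[j + 1L, ])^2 + (X[i + 2L, ] - X[j + 2L, ])^2 +
      (X[i + 3L, ] - X[j + 3L, ])^2
    Y[k, ] <- exp(-sqrt(d2) / model$a)
  }
  b <- model$basis
  cpp_energy_many(b$mono, b$mcoef, b$pptr, model$coefficients, Y)
}

# chain dV/dy back to Cartesians: dy/dr = -y/a, dr/dx via unit vectors
.chain_to_cartesian <- function(model, geom, dVdy) {
  x <- if (inherits(geom, "pip_geometry")) geom$coords else geom
  n <- ncol(x)
  p <- .pair_table(n)
  r <- interatomic_distances(x)
  y <- morse_transform(r, model$a)
  dVdr <- dVdy * (-y / model$a)
  grad <- matrix(0, 3L, n)
  for (k in seq_len(nrow(p))) {
    i <- p[k, 1L]; j <- p[k, 2L]
    u <- (x[, i] - x[, j]) / r[k]
    grad[, i] <- grad[, i] + dVdr[k] * u
    grad[, j] <- grad[, j] - dVdr[k] * u
  }
  as.numeric(grad)
}

#' Analytic and finite-difference gradients of the PES
#'
#' `method = "reverse"` performs one forward evaluation that records the
#' monomial values, then one backward adjoint sweep — all 3N Cartesian
#' derivatives in a single pass whose cost is a small multiple of one
#' energy evaluation, independent of N.  `method = "forward"`
#' differentiates with respect to each Morse variable separately (cost
#' about `n_var` energy evaluations).  `method = "fd"` is central finite
#' differences of the energy, for verification.
#'
#' @param model a `pip_pes`.
#' @param geom a `pip_geometry` or 3 x N coordinate matrix (bohr).
#' @param method `"reverse"` (default), `"forward"` or `"fd"`.
#' @param step finite-difference step in bohr (method `"fd"`).
#' @return list of class `pes_gradient`: `energy` (hartree), `gradient`
#'   (length 3N, hartree/bohr), `method`.
#' @export
pes_gradient <- function(model, geom, method = c("reverse", "forward", "fd"),
                         step = 1e-4) {
  stopifnot(inherits(model, "pip_pes"))
  method <- match.arg(method)
  .check_geom(model, geom)
  b <- model$basis
  if (method == "fd") {
    x <- if (inherits(geom, "pip_geometry")) geom$coords else geom
    g <- numeric(length(x))
    for (c_ in seq_along(x)) {
      xp <- x; xp[c_] <- xp[c_] + step
      xm <- x; xm[c_] <- xm[c_] - step
      g[c_] <- (pes_energy(model, xp) - pes_energy(model, xm)) / (2 * step)
    }
    out <- list(energy = pes_energy(model, x), gradient = g, method = "fd")
  } else {
    y <- .model_morse(model, geom)
    if (method == "reverse") {
      rv <- cpp_eval_reverse(b$mono, b$mcoef, b$pptr, model$coefficients, y)
      energy <- rv$energy; dVdy <- rv$dVdy
    } else {
      dVdy <- cpp_eval_forward_dVdy(b$mono, b$mcoef, b$pptr,
                                    model$coefficients, y)
      energy <- sum(model$coefficients *
                      cpp_poly_values(b$mono, b$mcoef, b$pptr, y))
    }
    out <- list(energy = energy,
                gradient = .chain_to_cartesian(model, geom, dVdy),
                method = method)
  }
  class(out) <- "pes_gradient"
  out
}

#' @export
print.pes_gradient <- function(x, ...) {
  cat("PES gradient (", x$method, "): energy ", format(x$energy),
      " hartree, |g|max ", format(max(abs(x$gradient))), " hartree/bohr\n",
      sep = "")
  invisible(x)
}

#' Hessian by central differences of reverse-mode gradients
#'
#' Each column is a central finite difference of the analytic (reverse)
#' gradient; the result is symmetrized as `(H + t(H)) / 2`.
#'
#' @param model a `pip_pes`.
#' @param geom a `pip_geometry` or coordinate matrix (bohr).
#' @param step displacement in bohr (default 1e-3).
#' @param symmetrize return the symmetrized matrix? Default `TRUE`.
#' @return 3N x 3N matrix in hartree/bohr^2.
#' @export
pes_hessian <- function(model, geom, step = 1e-3, symmetrize = TRUE) {
  stopifnot(step > 0)
  x <- if (inherits(geom, "pip_geometry")) geom$coords else geom
  grad_fun <- function(v) pes_gradient(model, matrix(v, 3L), "reverse")$gradient
  .num_hessian(grad_fun, as.numeric(x), step, symmetrize)
}

# generic numeric Hessian from a gradient callable
.num_hessian <- function(grad_fun, x, step, symmetrize = TRUE) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (c_ in seq_len(n)) {
    xp <- x; xp[c_] <- xp[c_] + step
    xm <- x; xm[c_] <- xm[c_] - step
    H[, c_] <- (grad_fun(xp) - grad_fun(xm)) / (2 * step)
  }
  if (symmetrize) (H + t(H)) / 2 else H
}

#' Operation counts for energy and reverse-gradient evaluation
#'
#' Counts floating-point operations implied by the evaluation graph:
#' monomial products (exponentiation by repeated multiplication),
#' multiplicity and coefficient multiplies, and accumulation adds for the
#' energy; plus the per-term adjoint operations of the backward sweep.
#' The reverse count is a fixed small multiple of the energy count,
#' independent of the number of atoms.
#'
#' @param model a `pip_pes` (or expanded `pip_basis`).
#' @return named numeric vector `c(energy = ..., reverse = ...)`.
#' @export
count_operations <- function(model) {
  b <- if (inherits(model, "pip_pes")) model$basis else model
  stopifnot(inherits(b, "pip_basis"))
  if (is.null(b$mono)) stop("basis was built with expand = FALSE")
  exps <- b$mono
  n_mono <- nrow(exps)
  nnz <- sum(exps > 0L)
  # energy: per monomial sum(e) multiplies + 1 multiplicity multiply +
  # 1 add; per polynomial 1 coefficient multiply + 1 add
  energy_ops <- sum(exps) + 2 * n_mono + 2 * b$size
  # reverse adds, per nonzero exponent entry: 1 divide + 2 multiplies +
  # 1 add for the y-adjoint, plus 1 multiply per monomial for its adjoint
  reverse_ops <- energy_ops + 4 * nnz + n_mono
  c(energy = energy_ops, reverse = reverse_ops)
}

#' @export
predict.pip_pes <- function(object, newdata, ...) {
  if (inherits(newdata, "pip_geometry"))
    return(pes_energy(object, newdata))
  if (inherits(newdata, "pip_dataset")) {
    Y <- .dataset_morse(newdata, object$a)
    b <- object$basis
    return(cpp_energy_many(b$mono, b$mcoef, b$pptr, object$coefficients, Y))
  }
  if (is.list(newdata))
    return(vapply(newdata, function(g) pes_energy(object, g), numeric(1)))
  if (is.matrix(newdata))
    return(pes_energy(object, newdata))
  stop("newdata must be a geometry, dataset, list of geometries or coordinate matrix")
}

#' @export
coef.pip_pes <- function(object, ...) object$coefficients

#' Write and read PES model files
#'
#' A versioned JSON container holding the symmetry, polynomial order,
#' Morse range parameter and the coefficient vector; the basis is
#' regenerated deterministically on read, so files stay small.
#'
#' @param model a `pip_pes`.
#' @param path file path.
#' @return `read_model`: a `pip_pes`; `write_model`: the path, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pip_pes"))
  obj <- list(format = "pipfit-model", version = 1L,
              symmetry = model$basis$symmetry$spec,
              max_order = model$basis$max_order,
              include_constant = model$basis$include_constant,
              a = model$a,
              augmented = .basis_extra_spec(model$basis),
              coefficients = model$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pipfit-model"))
    stop("not a pipfit model file: ", path)
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported pipfit model format version: ", obj$version)
  basis <- pip_basis(obj$symmetry, obj$max_order,
                     include_constant = isTRUE(obj$include_constant))
  basis <- .apply_basis_extra(basis, obj$augmented)
  pes_model(basis, obj$coefficients, a = obj$a)
}

# serialize polynomials appended by augment_basis (beyond the plain
# degree-1..M orbit basis): list of monomial blocks with multiplicities
.basis_extra_spec <- function(basis) {
  n_base <- attr(basis, "n_base")
  if (is.null(n_base) || n_base == basis$size) return(NULL)
  extra <- (n_base + 1L):basis$size
  lapply(extra, function(j) {
    rows <- basis$pptr[j]:(basis$pptr[j + 1L] - 1L)
    list(mono = unname(apply(basis$mono[rows, , drop = FALSE], 1L, as.integer,
                             simplify = FALSE)),
         coef = as.integer(basis$mcoef[rows]))
  })
}

.apply_basis_extra <- function(basis, extra) {
  if (is.null(extra) || length(extra) == 0L) return(basis)
  if (is.data.frame(extra))   # jsonlite simplification of the record list
    extra <- lapply(seq_len(nrow(extra)), function(j)
      list(mono = extra$mono[[j]], coef = extra$coef[[j]]))
  for (p in extra) {
    mono <- if (is.matrix(p$mono)) matrix(as.integer(p$mono), nrow(p$mono))
            else do.call(rbind, lapply(p$mono, function(e) as.integer(unlist(e))))
    basis <- .append_polynomial(basis, mono, as.integer(unlist(p$coef)))
  }
  basis
}
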