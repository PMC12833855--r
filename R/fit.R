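# Weighted linear least-squares fitting of PIP coefficients to energy
# datasets, fit diagnostics, energy-cutoff filtering, and basis
# augmentation by the max-value criterion.

#' Energy-dependent fitting weight
#'
#' `w(E) = Delta / (E + Delta)` with `E` the energy relative to the
#' dataset minimum (hartree): low-energy points get weight near 1,
#' high-energy points are de-emphasized.  Default `Delta = 0.1` hartree.
#'
#' @param E relative energies in hartree (>= 0).
#' @param delta weighting parameter in hartree (> 0).
#' @return weights in (0, 1].
#' @export
energy_weight <- function(E, delta = 0.1) {
  stopifnot(delta > 0)
  if (any(E < 0))
    stop("relative energies must be non-negative (subtract the reference first)")
  delta / (E + delta)
}

#' Filter a dataset by relative energy
#'
#' Keeps records whose energy relative to the reference (dataset minimum
#' by default) does not exceed `emax_cm1`.
#'
#' @param ds a `pip_dataset`.
#' @param emax_cm1 energy ceiling in cm^-1 (> 0; `Inf` keeps everything).
#' @param reference_energy optional origin in hartree.
#' @return filtered `pip_dataset` with attribute `n_dropped`.
#' @export
filter_by_energy <- function(ds, emax_cm1, reference_energy = NULL) {
  stopifnot(inherits(ds, "pip_dataset"), emax_cm1 > 0)
  ref <- if (is.null(reference_energy)) min(ds$energies) else reference_energy
  rel <- hartree_to_cm1(ds$energies - ref)
  keep <- rel <= emax_cm1
  if (!any(keep)) {
    warning("energy filter at ", emax_cm1, " cm^-1 removed every record")
    out <- structure(list(geoms = list(), energies = numeric(0),
                          reference_energy = ref), class = "pip_dataset")
  } else {
    out <- pip_dataset(ds$geoms[keep], ds$energies[keep],
                       reference_energy = ref)
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Fit a PIP potential energy surface by weighted linear least squares
#'
#' Solves `min_c sum_i w_i (sum_a c_a p_a(y_i) - E_i)^2` for the linear
#' coefficients of the basis polynomials, with weights
#' `w(E) = Delta / (E + Delta)` on the energy relative to the dataset
#' minimum.  The solution uses a rank-revealing singular value
#' decomposition (singular values below `tol * sigma_max` are dropped,
#' giving the minimum-norm solution for rank-deficient systems).
#'
#' @param data a `pip_dataset`.
#' @param basis an expanded `pip_basis`.
#' @param delta weighting parameter in hartree (default 0.1).
#' @param emax_cm1 optional energy ceiling in cm^-1 applied before
#'   fitting (default `Inf`).
#' @param a Morse range parameter in bohr (default 3.0).
#' @param weights `"energy"` (default, the `w(E)` scheme) or `"none"`.
#' @param tol relative singular-value tolerance (default 1e-12).
#' @return object of class `pip_pes` (usable with [pes_energy()],
#'   [pes_gradient()], `predict`, ...) carrying a `fit` component with
#'   `n_points`, `rank`, `rmse_cm1`, `wrmse_cm1`, `mae_cm1`, `r_squared`,
#'   fitted values, residuals (cm^-1) and weights.
#' @examples
#' \donttest{
#' pot <- morse_sum_potential("A2", De = 0.05, a_morse = 1.2, r_e = 2.0)
#' ds <- sample_dataset(pot, "A2", n_points = 200, seed = 1)
#' fit <- pip_fit(ds, pip_basis("A2", 6))
#' summary(fit)
#' }
#' @export
pip_fit <- function(data, basis, delta = 0.1, emax_cm1 = Inf, a = 3.0,
                    weights = c("energy", "none"), tol = 1e-12) {
  stopifnot(inherits(data, "pip_dataset"), inherits(basis, "pip_basis"))
  weights <- match.arg(weights)
  if (is.null(basis$mono)) basis <- .expand_basis(basis)
  if (is.finite(emax_cm1)) data <- filter_by_energy(data, emax_cm1)
  n <- length(data$energies)
  if (n == 0L) stop("no records to fit")
  if (n < basis$size)
    warning("under-determined system: ", n, " points for ", basis$size,
            " coefficients; minimum-norm solution returned")

  ref <- if (is.null(data$reference_energy)) min(data$energies)
         else data$reference_energy
  rel <- data$energies - ref
  w <- if (weights == "energy") energy_weight(rel, delta) else rep(1, n)

  Y <- .dataset_morse(data, a)
  B <- cpp_design_matrix(basis$mono, basis$mcoef, basis$pptr, Y)
  sw <- sqrt(w)
  sv <- svd(B * sw)
  keep <- sv$d > tol * sv$d[1L]
  rank <- sum(keep)
  if (rank < basis$size)
    warning("rank-deficient least-squares system: effective rank ", rank,
            " of ", basis$size)
  coefs <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], data$energies * sw)) / sv$d[keep])
  coefs <- as.numeric(coefs)

  model <- pes_model(basis, coefs, a = a)
  fitted_h <- as.numeric(B %*% coefs)
  res_h <- fitted_h - data$energies
  model$fit <- c(
    .metrics(data$energies, fitted_h, w),
    list(n_points = n, rank = rank, delta = delta,
         reference_energy = ref,
         fitted = fitted_h, residuals_cm1 = hartree_to_cm1(res_h),
         weights = w, energies = data$energies)
  )
  class(model) <- c("pip_pes_fit", "pip_pes")
  model
}

# rmse / wrmse / mae in cm^-1 plus R^2, from hartree inputs
.metrics <- function(obs, pred, w) {
  r <- pred - obs
  list(
    rmse_cm1 = hartree_to_cm1(sqrt(mean(r^2))),
    wrmse_cm1 = hartree_to_cm1(sqrt(sum(w * r^2) / sum(w))),
    mae_cm1 = hartree_to_cm1(mean(abs(r))),
    r_squared = if (sum((obs - mean(obs))^2) == 0) 1
                else 1 - sum(r^2) / sum((obs - mean(obs))^2)
  )
}

#' Fit metrics of a model on a dataset
#'
#' Root-mean-square error, weighted RMSE (`sqrt(sum(w r^2) / sum(w))`,
#' reducing to the RMSE for unit weights), mean absolute error (all in
#' cm^-1) and the coefficient of determination `R^2 = 1 - SS_res/SS_tot`
#' about the dataset mean.
#'
#' @param model a `pip_pes`.
#' @param ds a `pip_dataset`.
#' @param delta weighting parameter in hartree (default 0.1).
#' @return list with `rmse_cm1`, `wrmse_cm1`, `mae_cm1`, `r_squared`.
#' @export
fit_metrics <- function(model, ds, delta = 0.1) {
  stopifnot(inherits(model, "pip_pes"), inherits(ds, "pip_dataset"))
  pred <- predict(model, ds)
  ref <- if (is.null(ds$reference_energy)) min(ds$energies)
         else ds$reference_energy
  w <- energy_weight(ds$energies - ref, delta)
  .metrics(ds$energies, pred, w)
}

#' @export
print.pip_pes <- function(x, ...) {
  cat("PIP potential energy surface\n")
  cat("  symmetry ", x$basis$symmetry$spec, ", max order ", x$basis$max_order,
      ", ", x$basis$size, " coefficients, Morse a = ", x$a, " bohr\n", sep = "")
  if (!is.null(x$fit))
    cat(sprintf("  fit: %d points, RMSE %.4g cm^-1, wRMSE %.4g cm^-1\n",
                x$fit$n_points, x$fit$rmse_cm1, x$fit$wrmse_cm1))
  invisible(x)
}

#' @export
summary.pip_pes_fit <- function(object, ...) {
  out <- list(
    symmetry = object$basis$symmetry$spec,
    max_order = object$basis$max_order,
    size = object$basis$size,
    a = object$a,
    n_points = object$fit$n_points,
    rank = object$fit$rank,
    rmse_cm1 = object$fit$rmse_cm1,
    wrmse_cm1 = object$fit$wrmse_cm1,
    mae_cm1 = object$fit$mae_cm1,
    r_squared = object$fit$r_squared
  )
  class(out) <- "summary.pip_pes_fit"
  out
}

#' @export
print.summary.pip_pes_fit <- function(x, ...) {
  cat("PIP PES fit summary\n")
  cat(sprintf("  symmetry %s, order %d, %d coefficients (rank %d), a = %g bohr\n",
              x$symmetry, x$max_order, x$size, x$rank, x$a))
  cat(sprintf("  %d points:  RMSE %.6g cm^-1   wRMSE %.6g cm^-1   MAE %.6g cm^-1   R^2 %.8f\n",
              x$n_points, x$rmse_cm1, x$wrmse_cm1, x$mae_cm1, x$r_squared))
  invisible(x)
}

#' @export
fitted.pip_pes_fit <- function(object, ...) object$fit$fitted

#' @export
residuals.pip_pes_fit <- function(object, ...) object$fit$residuals_cm1

#' @export
plot.pip_pes_fit <- function(x, ...) {
  ref <- x$fit$reference_energy
  rel <- hartree_to_cm1(x$fit$energies - ref)
  plot(rel, x$fit$residuals_cm1,
       xlab = "energy above minimum (cm^-1)",
       ylab = "fit residual (cm^-1)",
       main = "PIP fit residuals", pch = 20, ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

# ---- basis augmentation -------------------------------------------------

# multiply two polynomials stored as (mono matrix, integer coef) blocks,
# collecting duplicate exponent rows
.poly_product <- function(m1, c1, m2, c2) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  i1 <- rep(seq_len(n1), each = n2)
  i2 <- rep(seq_len(n2), times = n1)
  mono <- m1[i1, , drop = FALSE] + m2[i2, , drop = FALSE]
  coef <- c1[i1] * c2[i2]
  key <- apply(mono, 1L, paste, collapse = ",")
  agg <- rowsum(coef, key)
  first <- !duplicated(key)
  mono_u <- mono[first, , drop = FALSE]
  key_u <- key[first]
  list(mono = mono_u, coef = as.integer(agg[key_u, 1L]))
}

# canonical identity key of a polynomial: sorted "exps:coef" terms
.poly_key <- function(mono, coef) {
  terms <- paste0(apply(mono, 1L, paste, collapse = ","), ":", coef)
  paste(sort(terms), collapse = ";")
}

.basis_poly <- function(basis, j) {
  rows <- basis$pptr[j]:(basis$pptr[j + 1L] - 1L)
  list(mono = basis$mono[rows, , drop = FALSE],
       coef = basis$mcoef[rows])
}

.append_polynomial <- function(basis, mono, coef) {
  if (is.null(attr(basis, "n_base"))) attr(basis, "n_base") <- basis$size
  basis$mono <- rbind(basis$mono, mono)
  basis$mcoef <- c(basis$mcoef, as.integer(coef))
  basis$pptr <- c(basis$pptr, basis$pptr[length(basis$pptr)] + nrow(mono))
  basis$size <- basis$size + 1L
  basis$degree <- c(basis$degree, max(rowSums(mono)))
  basis$canonical <- rbind(basis$canonical, mono[1L, , drop = FALSE])
  basis
}

#' Augment a PIP basis with products of its polynomials
#'
#' The product of two invariant polynomials is again invariant, so
#' pairwise products of basis polynomials are valid candidate basis
#' functions.  Candidates (deduplicated by polynomial identity, and
#' restricted to total degree at most `max_degree`) are ranked by their
#' largest absolute value over the dataset geometries — the polynomials
#' that grow largest are those probing the closest atom pairs, where
#' flexibility is most needed — and the top scorers are appended until
#' `target_size` is reached.
#'
#' @param basis an expanded `pip_basis`.
#' @param ds a `pip_dataset` supplying the scoring geometries.
#' @param target_size desired basis size (> `basis$size`).
#' @param max_degree total-degree cap for candidates (default
#'   `basis$max_order + 1`).
#' @param a Morse range parameter for scoring (default 3.0).
#' @return enlarged `pip_basis`; a warning is issued if fewer distinct
#'   candidates exist than requested.
#' @export
augment_basis <- function(basis, ds, target_size,
                          max_degree = basis$max_order + 1L, a = 3.0) {
  stopifnot(inherits(basis, "pip_basis"), inherits(ds, "pip_dataset"))
  if (is.null(basis$mono)) basis <- .expand_basis(basis)
  if (target_size <= basis$size)
    stop("target_size must exceed the current basis size ", basis$size)
  n_add <- target_size - basis$size

  polys <- lapply(seq_len(basis$size), function(j) .basis_poly(basis, j))
  degs <- basis$degree
  existing <- vapply(polys, function(p) .poly_key(p$mono, p$coef), character(1))

  cand <- list(); seen <- character(0)
  nonconst <- which(degs >= 1L)
  for (ii in seq_along(nonconst)) {
    for (jj in ii:length(nonconst)) {
      i <- nonconst[ii]; j <- nonconst[jj]
      if (degs[i] + degs[j] > max_degree) next
      pr <- .poly_product(polys[[i]]$mono, polys[[i]]$coef,
                          polys[[j]]$mono, polys[[j]]$coef)
      key <- .poly_key(pr$mono, pr$coef)
      if (key %in% seen || key %in% existing) next
      seen <- c(seen, key)
      cand[[length(cand) + 1L]] <- pr
    }
  }
  if (length(cand) == 0L) {
    warning("no distinct candidate products below degree ", max_degree,
            "; basis returned unchanged")
    return(basis)
  }
  if (length(cand) < n_add)
    warning("only ", length(cand), " distinct candidates available; ",
            "basis grows to ", basis$size + length(cand),
            " instead of ", target_size)

  Y <- .dataset_morse(ds, a)
  score <- vapply(cand, function(p) {
    vals <- cpp_design_matrix(p$mono, as.integer(p$coef),
                              c(1L, nrow(p$mono) + 1L), Y)
    max(abs(vals))
  }, numeric(1))
  ord <- order(score, decreasing = TRUE)
  for (k in head(ord, n_add))
    basis <- .append_polynomial(basis, cand[[k]]$mono, cand[[k]]$coef)
  basis
}
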