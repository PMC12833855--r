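# Unbiased diffusion Monte Carlo.  Walkers diffuse in imaginary time with
# Gaussian steps of variance dt/m per degree of freedom; branching
# replicates each walker floor(exp(-(V - E_ref) dt) + u) times (capped);
# the reference energy tracks the population mean potential with a
# population-control feedback term.  The long-time average of E_ref above
# the potential minimum estimates the zero-point energy.

#' One diffusion Monte Carlo step
#'
#' Diffuses every walker, evaluates the potential, branches by integer
#' replication `n = floor(exp(-(V - E_ref) dt) + u)` (capped at
#' `max_rep`) and updates the reference energy
#' `E_ref' = mean(V) - alpha (N' - N_target) / N_target` over the
#' post-branching population.
#'
#' @param X matrix of walker configurations (dof x walkers).
#' @param potential a potential callable (see [potential-protocol]).
#' @param e_ref current reference energy (hartree).
#' @param dt imaginary-time step (a.u.).
#' @param masses per-dof masses (electron masses).
#' @param n_target target population for the feedback term.
#' @param alpha feedback strength (default `1/dt`).
#' @param max_rep replication cap per walker per step (default 3).
#' @return list with `X` (new population), `e_ref`, `mean_V`, `V`
#'   (post-diffusion potential values, pre-branching).
#' @export
dmc_step <- function(X, potential, e_ref, dt, masses, n_target,
                     alpha = 1 / dt, max_rep = 3L) {
  ndof <- nrow(X); W <- ncol(X)
  X <- X + matrix(rnorm(ndof * W), ndof, W) * sqrt(dt / masses)
  V <- pot_energy_batch(potential, X)
  if (anyNA(V) || any(!is.finite(V))) {
    bad <- which(!is.finite(V))[1L]
    stop("potential returned a non-finite value at walker configuration: ",
         paste(signif(X[, bad], 6), collapse = " "))
  }
  n_rep <- pmin(floor(exp(-(V - e_ref) * dt) + runif(W)), max_rep)
  if (sum(n_rep) == 0)
    stop("DMC population collapsed to zero walkers; lower dt or check E_ref feedback")
  idx <- rep(seq_len(W), n_rep)
  Xn <- X[, idx, drop = FALSE]
  mean_V <- mean(V[idx])
  e_ref_new <- mean_V - alpha * (length(idx) - n_target) / n_target
  list(X = Xn, e_ref = e_ref_new, mean_V = mean_V, V = V)
}

#' Run diffusion Monte Carlo and estimate the zero-point energy
#'
#' Replicates the standard unbiased protocol: all walkers start exactly
#' at the supplied minimum configuration, are propagated for `n_steps`
#' imaginary-time steps, and the reference energies of the steps after
#' `n_equil` are averaged; the ZPE is that average minus the potential
#' minimum.  `n_traj` independent trajectories (distinct sub-seeds) give
#' the quoted uncertainty as the standard deviation across trajectories.
#'
#' Default parameters follow the protocol used for production PIP
#' surfaces: 30,000 walkers, 55,000 steps of 5.0 a.u. with the first
#' 5,000 discarded, 10 trajectories.  Scale them down for quick checks.
#'
#' @param potential a potential callable.
#' @param start starting configuration (defaults to the potential's).
#' @param masses per-dof masses (defaults to the potential's).
#' @param n_walkers walkers per trajectory.
#' @param n_steps total steps per trajectory.
#' @param n_equil equilibration steps discarded from the average.
#' @param dt imaginary-time step in a.u.
#' @param n_traj number of independent trajectories.
#' @param alpha population-feedback strength (default `1/dt`).
#' @param seed master seed; trajectory `t` uses `seed + 10007 * t`.
#' @param v_min potential minimum (hartree); defaults to the potential's
#'   known minimum, else the energy at `start`.
#' @param hole_tol_cm1 flag walkers whose potential falls below
#'   `v_min - hole_tol_cm1` (default 10 cm^-1); see [hole_scan()].
#' @return object of class `dmc_result`: `zpe_cm1`, `stderr_cm1`,
#'   `zpe_traj_cm1`, `traces` (per-step reference energies, hartree),
#'   `population` (per-trajectory min/max), `holes`.
#' @export
run_dmc <- function(potential, start = NULL, masses = NULL,
                    n_walkers = 30000, n_steps = 55000, n_equil = 5000,
                    dt = 5.0, n_traj = 10, alpha = 1 / dt, seed = 1,
                    v_min = NULL, hole_tol_cm1 = 10) {
  stopifnot(n_walkers >= 1, n_steps > n_equil, dt > 0, n_traj >= 1)
  start <- as.numeric(start %||% pot_start(potential))
  masses <- masses %||% pot_masses(potential)
  stopifnot(length(masses) == length(start), all(masses > 0))
  v_min <- v_min %||% pot_vmin(potential) %||% pot_energy(potential, start)
  hole_tol <- cm1_to_hartree(hole_tol_cm1)

  traces <- matrix(NA_real_, n_steps, n_traj)
  zpes <- numeric(n_traj)
  pop <- matrix(NA_real_, 2L, n_traj, dimnames = list(c("min", "max"), NULL))
  holes <- list()

  for (t_ in seq_len(n_traj)) {
    set.seed((seed + 10007L * t_) %% .Machine$integer.max)
    X <- matrix(start, length(start), n_walkers)
    e_ref <- pot_energy(potential, start)
    pmin_ <- pmax_ <- n_walkers
    for (s in seq_len(n_steps)) {
      st <- dmc_step(X, potential, e_ref, dt, masses, n_walkers,
                     alpha = alpha)
      X <- st$X; e_ref <- st$e_ref
      traces[s, t_] <- e_ref
      W <- ncol(X)
      pmin_ <- min(pmin_, W); pmax_ <- max(pmax_, W)
      low <- which(st$V < v_min - hole_tol)
      if (length(low) && length(holes) < 200L) {
        for (b in head(low, 5L))
          holes[[length(holes) + 1L]] <-
            list(trajectory = t_, step = s, energy = st$V[b])
      }
    }
    zpes[t_] <- mean(traces[(n_equil + 1L):n_steps, t_]) - v_min
    pop[, t_] <- c(pmin_, pmax_)
  }

  structure(list(
    zpe_cm1 = hartree_to_cm1(mean(zpes)),
    stderr_cm1 = if (n_traj > 1L) hartree_to_cm1(sd(zpes)) else NA_real_,
    zpe_traj_cm1 = hartree_to_cm1(zpes),
    traces = traces, population = pop, holes = holes,
    v_min = v_min, n_walkers = n_walkers, n_steps = n_steps,
    n_equil = n_equil, dt = dt, n_traj = n_traj, seed = seed
  ), class = "dmc_result")
}

#' @export
print.dmc_result <- function(x, ...) {
  cat(sprintf("DMC zero-point energy: %.2f +/- %s cm^-1\n", x$zpe_cm1,
              if (is.na(x$stderr_cm1)) "NA" else sprintf("%.2f", x$stderr_cm1)))
  cat(sprintf("  %d trajectories x %d walkers x %d steps (dt = %g a.u., %d equilibration)\n",
              x$n_traj, x$n_walkers, x$n_steps, x$dt, x$n_equil))
  nh <- length(x$holes)
  cat("  holes flagged below the minimum:", nh, "\n")
  invisible(x)
}

#' Report walkers that fell below the potential minimum
#'
#' During a DMC run every walker whose potential drops more than the
#' tolerance below the known minimum is recorded — a nonempty report
#' signals a "hole" (an unphysical low-energy region) in the surface.
#'
#' @param result a `dmc_result`.
#' @return data frame with columns `trajectory`, `step`,
#'   `energy_below_min_cm1` (depth below the minimum); zero rows when no
#'   holes were found.
#' @export
hole_scan <- function(result) {
  stopifnot(inherits(result, "dmc_result"))
  if (length(result$holes) == 0L)
    return(data.frame(trajectory = integer(0), step = integer(0),
                      energy_below_min_cm1 = numeric(0)))
  data.frame(
    trajectory = vapply(result$holes, function(h) as.integer(h$trajectory), integer(1)),
    step = vapply(result$holes, function(h) as.integer(h$step), integer(1)),
    energy_below_min_cm1 = hartree_to_cm1(
      result$v_min - vapply(result$holes, `[[`, numeric(1), "energy"))
  )
}
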