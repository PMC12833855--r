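# Relaxed minimum-energy paths by simulated annealing: a classical
# trajectory (velocity Verlet) whose kinetic energy is bled off by a
# fractional loss each step, with a "brake" halving the velocity whenever
# the kinetic energy exceeds a threshold.  The relaxed profile is read
# off by binning the trajectory on a designated atom-pair distance and
# keeping the lowest energy seen in each bin.

#' Simulated-annealing minimum-energy path
#'
#' Propagates a classical trajectory from `start` with a small initial
#' kinetic energy directed so as to shrink the designated pair distance,
#' removing `loss_fraction` of the kinetic energy at every step
#' (velocity rescale by `sqrt(1 - loss_fraction)`) and halving the
#' kinetic energy (rescale by `sqrt(brake_factor)`) whenever it exceeds
#' `brake_cm1`.  The trajectory therefore slides down the potential,
#' hugging the minimum-energy path, and stops when both the kinetic
#' energy and the gradient fall below their tolerances.
#'
#' Defaults mirror the production protocol: initial kinetic energy
#' 12 cm^-1, time step 5 a.u., loss 0.01% per step, brake at 100 cm^-1
#' reducing the kinetic energy by 50%.
#'
#' @param potential a potential callable or `pip_pes`-wrapped surface
#'   (see [pes_potential()]).
#' @param start starting configuration (`pip_geometry`, matrix or
#'   vector), typically at large separation of the reaction pair.
#' @param pair integer pair `c(i, j)`: the atoms whose distance is the
#'   reaction coordinate.
#' @param initial_ke_cm1 initial kinetic energy (default 12 cm^-1).
#' @param dt time step in a.u. (default 5).
#' @param loss_fraction fraction of kinetic energy removed per step
#'   (default 1e-4, i.e. 0.01%).
#' @param brake_cm1 kinetic-energy threshold triggering the brake
#'   (default 100 cm^-1).
#' @param brake_factor kinetic-energy retention factor on braking
#'   (default 0.5).
#' @param max_steps step cap (default 2e5).
#' @param ke_tol_cm1 terminal kinetic energy (default 1e-3 cm^-1).
#' @param gtol terminal gradient infinity norm in hartree/bohr
#'   (default 1e-6).
#' @param bin_width reaction-coordinate bin width in bohr (default 0.05).
#' @param record_every store every k-th step in the raw trajectory
#'   (default 1; binned profile always uses every step).
#' @return object of class `mep_path`: `profile` (data frame with bin
#'   coordinate `coord`, relaxed energies `energy_h` and `energy_cm1`
#'   relative to the path minimum), `r_min` (coordinate of the lowest
#'   energy), `e_min` (hartree), `steps`, `terminated`
#'   (`"converged"` or `"max_steps"`), `final` (last configuration).
#' @export
anneal_mep <- function(potential, start, pair = c(1L, 2L),
                       initial_ke_cm1 = 12, dt = 5, loss_fraction = 1e-4,
                       brake_cm1 = 100, brake_factor = 0.5,
                       max_steps = 2e5, ke_tol_cm1 = 1e-3, gtol = 1e-6,
                       bin_width = 0.05, record_every = 1L) {
  stopifnot(loss_fraction > 0, loss_fraction < 1,
            brake_factor > 0, brake_factor < 1, dt > 0, bin_width > 0)
  x <- if (inherits(start, "pip_geometry")) as.numeric(start$coords)
       else as.numeric(start)
  m <- pot_masses(potential)
  stopifnot(length(m) == length(x))
  n_atoms <- length(x) / 3L
  stopifnot(pair[1L] >= 1L, pair[2L] <= n_atoms, pair[1L] != pair[2L])
  ia <- (pair[1L] - 1L) * 3L + 1:3
  ja <- (pair[2L] - 1L) * 3L + 1:3
  coord_of <- function(v) sqrt(sum((v[ia] - v[ja])^2))

  brake <- cm1_to_hartree(brake_cm1)
  ke_tol <- cm1_to_hartree(ke_tol_cm1)
  ke0 <- cm1_to_hartree(initial_ke_cm1)

  # initial velocity: shrink the reaction coordinate (annealing runs
  # fall inward from large separation)
  dir <- numeric(length(x))
  u <- (x[ia] - x[ja]) / coord_of(x)
  dir[ia] <- -u; dir[ja] <- u
  v <- dir * sqrt(2 * ke0 / sum(m * dir^2))

  g <- pot_gradient(potential, x)
  E0 <- pot_energy(potential, x)
  coords <- numeric(max_steps); energies <- numeric(max_steps)
  terminated <- "max_steps"
  steps <- 0L
  for (s in seq_len(max_steps)) {
    v <- v - 0.5 * dt * g / m
    x <- x + dt * v
    g <- pot_gradient(potential, x)
    v <- v - 0.5 * dt * g / m
    v <- v * sqrt(1 - loss_fraction)
    ke <- 0.5 * sum(m * v^2)
    if (ke > brake) {
      v <- v * sqrt(brake_factor)
      ke <- ke * brake_factor
    }
    E <- pot_energy(potential, x)
    if (!is.finite(E) || E > E0 + 1)
      stop("annealing trajectory diverged (energy rising without bound) at step ", s)
    coords[s] <- coord_of(x); energies[s] <- E
    steps <- s
    if (ke < ke_tol && max(abs(g)) < gtol) { terminated <- "converged"; break }
  }
  coords <- coords[seq_len(steps)]; energies <- energies[seq_len(steps)]

  bins <- floor(coords / bin_width)
  o <- order(bins, energies)
  first <- !duplicated(bins[o])
  prof_idx <- o[first]
  prof <- data.frame(coord = coords[prof_idx], energy_h = energies[prof_idx])
  prof <- prof[order(prof$coord), ]
  rownames(prof) <- NULL
  e_min <- min(prof$energy_h)
  prof$energy_cm1 <- hartree_to_cm1(prof$energy_h - e_min)

  structure(list(profile = prof,
                 r_min = prof$coord[which.min(prof$energy_h)],
                 e_min = e_min, steps = steps, terminated = terminated,
                 final = x, bin_width = bin_width, pair = pair),
            class = "mep_path")
}

#' @export
print.mep_path <- function(x, ...) {
  cat("Minimum-energy path:", nrow(x$profile), "bins over coordinate [",
      sprintf("%.3f, %.3f", min(x$profile$coord), max(x$profile$coord)),
      "] bohr\n")
  cat(sprintf("  minimum at %.4f bohr; %d steps (%s)\n",
              x$r_min, x$steps, x$terminated))
  invisible(x)
}

#' Merge overlapping minimum-energy paths
#'
#' Combines paths from different starting points (e.g. an inner-wall and
#' an outer dissociative trajectory) into one monotone-coordinate
#' profile, keeping the lowest energy per bin.  The maximum energy
#' difference between paths on shared bins is reported as the overlap
#' disagreement.
#'
#' @param paths list of `mep_path` objects with a common bin width and
#'   potential energy origin.
#' @return a merged `mep_path` with attribute `overlap_disagreement_cm1`.
#' @export
merge_paths <- function(paths) {
  stopifnot(length(paths) >= 2L,
            all(vapply(paths, inherits, logical(1), "mep_path")))
  bw <- paths[[1L]]$bin_width
  if (!all(vapply(paths, function(p) isTRUE(all.equal(p$bin_width, bw)),
                  logical(1))))
    stop("paths must share one bin width")
  tabs <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]$profile
    data.frame(bin = floor(p$coord / bw), coord = p$coord,
               energy_h = p$energy_h, path = i)
  })
  all_ <- do.call(rbind, tabs)
  shared <- unlist(lapply(split(all_$path, all_$bin),
                          function(v) length(unique(v)) > 1L))
  if (!any(shared)) stop("paths do not overlap in reaction coordinate")
  disagreement <- max(vapply(split(all_, all_$bin), function(d) {
    if (length(unique(d$path)) < 2L) return(0)
    per <- tapply(d$energy_h, d$path, min)
    diff(range(per))
  }, numeric(1)))

  o <- order(all_$bin, all_$energy_h)
  first <- !duplicated(all_$bin[o])
  prof <- all_[o[first], c("coord", "energy_h")]
  prof <- prof[order(prof$coord), ]
  rownames(prof) <- NULL
  e_min <- min(prof$energy_h)
  prof$energy_cm1 <- hartree_to_cm1(prof$energy_h - e_min)
  out <- structure(list(profile = prof,
                        r_min = prof$coord[which.min(prof$energy_h)],
                        e_min = e_min,
                        steps = sum(vapply(paths, `[[`, numeric(1), "steps")),
                        terminated = "merged", final = NULL,
                        bin_width = bw, pair = paths[[1L]]$pair),
                   class = "mep_path")
  attr(out, "overlap_disagreement_cm1") <- hartree_to_cm1(disagreement)
  out
}

#' Dissociation energy from a minimum-energy path
#'
#' Checks that the far (large-coordinate) end of the profile has
#' flattened out — the mean absolute slope over the outer tail must stay
#' below `plateau_tol` — and returns the plateau energy minus the path
#' minimum.
#'
#' @param path an `mep_path`.
#' @param tail_fraction fraction of the coordinate range treated as the
#'   tail (default 0.1).
#' @param plateau_tol maximum allowed |dE/dcoord| on the tail in
#'   cm^-1/bohr (default 5).
#' @return dissociation energy D_e in cm^-1.
#' @export
dissociation_energy <- function(path, tail_fraction = 0.1, plateau_tol = 5) {
  stopifnot(inherits(path, "mep_path"))
  p <- path$profile
  if (nrow(p) < 5L) stop("path too short to locate a plateau")
  cmax <- max(p$coord); cmin <- min(p$coord)
  tail_lo <- cmax - tail_fraction * (cmax - cmin)
  tl <- p[p$coord >= tail_lo, ]
  if (nrow(tl) < 2L)
    stop("no plateau: fewer than 2 profile points in the outer tail; extend the path")
  slope <- abs(diff(tl$energy_cm1) / diff(tl$coord))
  if (mean(slope) > plateau_tol)
    stop("no plateau: mean |dE/dcoord| = ", format(mean(slope)),
         " cm^-1/bohr on the tail exceeds ", plateau_tol,
         "; propagate from larger separation")
  mean(tl$energy_cm1) - min(p$energy_cm1)
}
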