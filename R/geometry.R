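# Molecular geometries, interatomic distances and the Morse-variable
# transform.  Internal units are bohr (lengths) and electron masses.

# most-abundant-isotope masses in unified amu
.ISOTOPE_AMU <- c(
  H = 1.00782503207, D = 2.01410177785, He = 4.002603254,
  Li = 7.01600455, Be = 9.0121822, B = 11.0093054,
  C = 12.0, N = 14.0030740048, O = 15.99491461956,
  F = 18.99840322, Ne = 19.9924401754, Na = 22.9897692809,
  Mg = 23.985041700, Al = 26.98153863, Si = 27.9769265325,
  P = 30.97376163, S = 31.97207100, Cl = 34.96885268,
  Ar = 39.9623831225, K = 38.96370668, Ca = 39.96259098
)

#' Atomic masses in electron-mass units
#'
#' Most-abundant-isotope masses, converted from unified amu by the factor
#' 1822.888486.
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses in electron masses.
#' @export
atomic_mass <- function(elements) {
  m <- .ISOTOPE_AMU[elements]
  if (anyNA(m))
    stop("unknown element symbol: ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  unname(m) * AMU_ME
}

#' Construct a molecular geometry
#'
#' @param elements character vector of element symbols.
#' @param coords 3 x N matrix of Cartesian coordinates in bohr (a plain
#'   length-3N vector is reshaped column-wise).
#' @param masses optional per-atom masses in electron masses; defaults to
#'   most-abundant-isotope values via [atomic_mass()].
#' @return object of class `pip_geometry`.
#' @export
geometry <- function(elements, coords, masses = NULL) {
  elements <- as.character(elements)
  n <- length(elements)
  stopifnot(n >= 2L)
  coords <- matrix(as.numeric(coords), nrow = 3L)
  stopifnot(ncol(coords) == n)
  if (is.null(masses)) masses <- atomic_mass(elements)
  stopifnot(length(masses) == n, all(masses > 0))
  structure(list(elements = elements, coords = coords, masses = masses),
            class = "pip_geometry")
}

#' @export
print.pip_geometry <- function(x, ...) {
  cat("Geometry:", length(x$elements), "atoms (bohr)\n")
  for (i in seq_along(x$elements))
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$elements[i],
                x$coords[1, i], x$coords[2, i], x$coords[3, i]))
  invisible(x)
}

#' Interatomic distances
#'
#' Distances for all unordered pairs (i, j), i < j, in lexicographic
#' order — the same pair ordering used by the symmetry machinery.
#'
#' @param geom a `pip_geometry`, or a 3 x N coordinate matrix.
#' @return numeric vector of length `N * (N - 1) / 2` in bohr.
#' @export
interatomic_distances <- function(geom) {
  x <- if (inherits(geom, "pip_geometry")) geom$coords else geom
  n <- ncol(x)
  p <- .pair_table(n)
  d <- x[, p[, 1L], drop = FALSE] - x[, p[, 2L], drop = FALSE]
  sqrt(colSums(d * d))
}

#' Morse-variable transform
#'
#' `y = exp(-r / a)`: a bounded, monotonically decreasing transform of
#' the internuclear distances that tends to 0 at dissociation.  The
#' default range parameter is `a = 3.0` bohr.
#'
#' @param r distance vector in bohr (non-negative).
#' @param a range parameter in bohr, > 0.
#' @return Morse variables in (0, 1].
#' @export
morse_transform <- function(r, a = 3.0) {
  stopifnot(length(a) == 1L, is.finite(a))
  if (a <= 0) stop("range parameter `a` must be positive")
  stopifnot(all(r >= 0))
  exp(-r / a)
}

#' Map a geometry onto a symmetry's class layout
#'
#' Verifies that atoms are arranged class by class (all atoms of the
#' first class first, and so on) and that per-class counts match.  By
#' default distinct elements are assigned to classes in order of first
#' appearance; supply `element_map` (named character vector, element ->
#' class label) when the correspondence is not positional.
#'
#' @param geom a `pip_geometry`.
#' @param sym a `pip_symmetry` or symmetry string.
#' @param element_map optional named character vector mapping element
#'   symbols to class labels.
#' @return invisibly `TRUE`; errors describe any mismatch.
#' @export
match_symmetry <- function(geom, sym, element_map = NULL) {
  sym <- pip_symmetry(sym)
  if (length(geom$elements) != sym$n_atoms)
    stop("geometry has ", length(geom$elements), " atoms but symmetry ",
         sym$spec, " requires ", sym$n_atoms)
  if (is.null(element_map)) {
    els <- unique(geom$elements)
    if (length(els) != nrow(sym$classes))
      stop("geometry has ", length(els), " distinct elements but symmetry ",
           sym$spec, " has ", nrow(sym$classes), " classes")
    element_map <- setNames(sym$classes$label, els)
  }
  expected <- rep(sym$classes$label, sym$classes$count)
  got <- unname(element_map[geom$elements])
  if (anyNA(got)) stop("element(s) missing from element_map: ",
                       paste(unique(geom$elements[is.na(got)]), collapse = ", "))
  if (!identical(got, expected))
    stop("atom order does not follow the class-by-class layout of ", sym$spec,
         " (expected class sequence ", paste(expected, collapse = ""), ")")
  invisible(TRUE)
}

#' Read and write XYZ files
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `element x y z` line per atom.  Coordinates are assumed to be in
#' Angstrom (the de facto XYZ convention) unless the comment line
#' contains the word "bohr" or `units` overrides; internally everything
#' is stored in bohr.
#'
#' @param path file path.
#' @param units `"auto"` (default), `"angstrom"` or `"bohr"`.
#' @return `read_xyz`: a `pip_geometry`.
#' @export
read_xyz <- function(path, units = c("auto", "angstrom", "bohr")) {
  units <- match.arg(units)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("line 1: invalid atom count in ", path)
  comment <- lines[2L]
  if (length(lines) < 2L + n)
    stop("XYZ header declares ", n, " atoms but file has only ",
         length(lines) - 2L, " atom lines")
  body <- lines[3L:(2L + n)]
  el <- character(n); xyz <- matrix(NA_real_, 3L, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(f) < 4L) stop("line ", i + 2L, ": malformed atom line in ", path)
    el[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(v)) stop("line ", i + 2L, ": non-numeric coordinate in ", path)
    xyz[, i] <- v
  }
  in_bohr <- switch(units,
                    auto = grepl("bohr", comment, ignore.case = TRUE),
                    bohr = TRUE, angstrom = FALSE)
  if (!in_bohr) xyz <- angstrom_to_bohr(xyz)
  geometry(el, xyz)
}

#' @param geom a `pip_geometry` (coordinates in bohr).
#' @param comment comment-line text; "bohr" is appended automatically
#'   when writing in bohr.
#' @rdname read_xyz
#' @return `write_xyz`: the path, invisibly.
#' @export
write_xyz <- function(geom, path, units = c("bohr", "angstrom"),
                      comment = "") {
  units <- match.arg(units)
  xyz <- geom$coords
  if (units == "bohr") {
    if (!grepl("bohr", comment, ignore.case = TRUE))
      comment <- trimws(paste(comment, "[bohr]"))
  } else xyz <- bohr_to_angstrom(xyz)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(as.character(length(geom$elements)), comment), con)
  for (i in seq_along(geom$elements))
    writeLines(sprintf("%-2s %18.12f %18.12f %18.12f", geom$elements[i],
                       xyz[1, i], xyz[2, i], xyz[3, i]), con)
  invisible(path)
}

#' Datasets of (geometry, energy) records
#'
#' A `pip_dataset` holds geometries sharing one atom count and class
#' layout together with their electronic energies in hartree.
#'
#' @param geoms list of `pip_geometry`.
#' @param energies numeric vector of energies in hartree.
#' @param reference_energy optional energy origin (hartree); defaults to
#'   the dataset minimum when needed.
#' @return object of class `pip_dataset`.
#' @export
pip_dataset <- function(geoms, energies, reference_energy = NULL) {
  stopifnot(length(geoms) == length(energies), length(geoms) >= 1L)
  n0 <- length(geoms[[1L]]$elements)
  el0 <- geoms[[1L]]$elements
  for (g in geoms)
    if (!identical(g$elements, el0))
      stop("all dataset records must share atom count and element order")
  structure(list(geoms = geoms, energies = as.numeric(energies),
                 reference_energy = reference_energy),
            class = "pip_dataset")
}

#' @export
print.pip_dataset <- function(x, ...) {
  e <- x$energies
  cat("PIP dataset:", length(e), "records,",
      length(x$geoms[[1L]]$elements), "atoms each\n")
  cat(sprintf("  energy range [%.6f, %.6f] hartree (span %.1f cm^-1)\n",
              min(e), max(e), hartree_to_cm1(diff(range(e)))))
  invisible(x)
}

#' @export
length.pip_dataset <- function(x) length(x$energies)

#' Read and write the plain-text dataset format
#'
#' One record per geometry: a line `N energy` (atom count, energy in
#' hartree), then `N` lines `element x y z` with coordinates in bohr.
#' The first line of the file is the format tag `pipfit-dataset v1`.
#'
#' @param path file path.
#' @return `read_dataset`: a `pip_dataset`.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || !grepl("^pipfit-dataset v1", lines[1L]))
    stop("not a pipfit dataset file (missing 'pipfit-dataset v1' header): ", path)
  i <- 2L; geoms <- list(); energies <- numeric(0)
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    hd <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    n <- as.integer(hd[1L]); e <- as.numeric(hd[2L])
    if (is.na(n) || is.na(e)) stop("line ", i, ": malformed record header")
    if (i + n > length(lines)) stop("line ", i, ": truncated record")
    el <- character(n); xyz <- matrix(0, 3L, n)
    for (k in seq_len(n)) {
      f <- strsplit(trimws(lines[i + k]), "\\s+")[[1L]]
      el[k] <- f[1L]; xyz[, k] <- as.numeric(f[2:4])
    }
    geoms[[length(geoms) + 1L]] <- geometry(el, xyz)
    energies <- c(energies, e)
    i <- i + n + 1L
  }
  pip_dataset(geoms, energies)
}

#' @param ds a `pip_dataset`.
#' @rdname read_dataset
#' @return `write_dataset`: the path, invisibly.
#' @export
write_dataset <- function(ds, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("pipfit-dataset v1", con)
  for (r in seq_along(ds$energies)) {
    g <- ds$geoms[[r]]
    writeLines(sprintf("%d %.12e", length(g$elements), ds$energies[r]), con)
    for (k in seq_along(g$elements))
      writeLines(sprintf("%-2s %18.12f %18.12f %18.12f", g$elements[k],
                         g$coords[1, k], g$coords[2, k], g$coords[3, k]), con)
  }
  invisible(path)
}

# morse vectors for every record: n_var x n_records matrix
.dataset_morse <- function(ds, a) {
  np <- length(interatomic_distances(ds$geoms[[1L]]))
  out <- vapply(ds$geoms,
                function(g) morse_transform(interatomic_distances(g), a),
                numeric(np))
  matrix(out, nrow = np)
}
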