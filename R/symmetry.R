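# Permutational symmetry of an atom set and its induced action on
# unordered atom pairs.  Atoms are numbered class by class in the order
# the classes appear in the symmetry string; pairs (i, j), i < j, are
# ordered lexicographically, so e.g. A5B2 has 21 pair variables.

#' Parse a permutational symmetry specification
#'
#' A symmetry string such as `"A5B2"` declares classes of interchangeable
#' atoms: 5 atoms of one element and 2 of another.  The permutation group
#' is the direct product of the symmetric groups of the classes (order
#' `prod(factorial(counts))`), acting on atoms and, by induction, on the
#' `n * (n - 1) / 2` unordered atom pairs.
#'
#' @param spec character scalar, letter+count groups (`"A5B2"`, `"A2"`,
#'   `"A2B"`; a missing count means 1).
#' @return an object of class `pip_symmetry` with fields `classes`
#'   (data frame of `label`, `count`), `n_atoms`, `n_pairs`,
#'   `group_order`, the atom permutations (`atom_perms`, one row per
#'   group element) and the induced pair permutations (`pair_perms`).
#' @examples
#' sym <- pip_symmetry("A5B2")
#' sym$n_atoms     # 7
#' sym$n_pairs     # 21
#' sym$group_order # 240
#' @export
pip_symmetry <- function(spec) {
  if (inherits(spec, "pip_symmetry")) return(spec)
  stopifnot(is.character(spec), length(spec) == 1L, !is.na(spec))
  toks <- regmatches(spec, gregexpr("[A-Za-z][0-9]*", spec))[[1]]
  if (length(toks) == 0L || nchar(paste(toks, collapse = "")) != nchar(spec))
    stop("malformed symmetry string '", spec, "': expected letter+count groups like 'A5B2'")
  labels <- substr(toks, 1L, 1L)
  counts <- suppressWarnings(as.integer(sub("^[A-Za-z]", "", toks)))
  counts[is.na(counts)] <- 1L
  if (any(counts < 1L))
    stop("malformed symmetry string '", spec, "': zero count in token '",
         toks[which(counts < 1L)[1L]], "'")
  if (anyDuplicated(labels))
    stop("malformed symmetry string '", spec, "': repeated class label '",
         labels[duplicated(labels)][1L], "'")
  n <- sum(counts)
  if (n < 2L) stop("symmetry must describe at least 2 atoms")

  # atom permutations: direct product of per-class symmetric groups
  offs <- c(0L, cumsum(counts))
  blocks <- lapply(seq_along(counts), function(k) .all_perms(counts[k]) + offs[k])
  atom_perms <- blocks[[1L]]
  if (length(blocks) > 1L) {
    for (k in 2L:length(blocks)) {
      a <- atom_perms; b <- blocks[[k]]
      ia <- rep(seq_len(nrow(a)), each = nrow(b))
      ib <- rep(seq_len(nrow(b)), times = nrow(a))
      atom_perms <- cbind(a[ia, , drop = FALSE], b[ib, , drop = FALSE])
    }
  }

  pairs <- .pair_table(n)
  np <- nrow(pairs)
  pidx <- matrix(0L, n, n)
  pidx[cbind(pairs[, 1L], pairs[, 2L])] <- seq_len(np)
  pidx[cbind(pairs[, 2L], pairs[, 1L])] <- seq_len(np)
  pair_perms <- matrix(0L, nrow(atom_perms), np)
  for (g in seq_len(nrow(atom_perms))) {
    s <- atom_perms[g, ]
    pair_perms[g, ] <- pidx[cbind(s[pairs[, 1L]], s[pairs[, 2L]])]
  }

  structure(list(
    spec = spec,
    classes = data.frame(label = labels, count = counts,
                         stringsAsFactors = FALSE),
    n_atoms = n,
    n_pairs = np,
    group_order = nrow(atom_perms),
    pairs = pairs,
    atom_perms = atom_perms,
    pair_perms = pair_perms
  ), class = "pip_symmetry")
}

# all permutations of 1..n as rows
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    m <- sub
    m[m >= i] <- m[m >= i] + 1L
    cbind(rep(i, nrow(m)), m)
  }))
}

# unordered pairs (i, j), i < j, in lexicographic order
.pair_table <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  cbind(i = i, j = j)
}

#' @export
print.pip_symmetry <- function(x, ...) {
  cat("Permutational symmetry ", x$spec, ": ", x$n_atoms, " atoms, ",
      x$n_pairs, " pair variables, group order ", x$group_order, "\n", sep = "")
  invisible(x)
}

#' Count invariant polynomials per degree without enumerating orbits
#'
#' Burnside / Molien counting: the number of monomial orbits of total
#' degree d equals the group average of the number of monomials fixed by
#' each element, and a monomial is fixed by a pair permutation iff its
#' exponent vector is constant on each cycle.  The per-element generating
#' function is therefore the product over cycles of `1 / (1 - t^len)`,
#' truncated at `max_order`; averaging over the group and reading off
#' coefficients gives exact per-degree orbit counts.
#'
#' This is the independent cross-check for [pip_basis()]: it never touches
#' individual monomials.
#'
#' @param sym a `pip_symmetry` or symmetry string.
#' @param max_order maximum total polynomial degree.
#' @return integer vector of orbit counts for degrees `1..max_order`, with
#'   attribute `cumulative` (running totals, constant term excluded).
#' @examples
#' count_invariants("A3", 2)   # degrees 1, 2 -> counts 1, 2
#' @export
count_invariants <- function(sym, max_order) {
  sym <- pip_symmetry(sym)
  stopifnot(max_order >= 1L)
  M <- as.integer(max_order)
  total <- numeric(M + 1L)
  for (g in seq_len(nrow(sym$pair_perms))) {
    cyc <- .cycle_lengths(sym$pair_perms[g, ])
    gf <- c(1, numeric(M))
    for (len in cyc) {
      f <- numeric(M + 1L)
      f[seq.int(1L, M + 1L, by = len)] <- 1  # 1/(1 - t^len) truncated
      gf <- .series_mult(gf, f, M)
    }
    total <- total + gf
  }
  total <- total / sym$group_order
  counts <- round(total[-1L])
  if (max(abs(total[-1L] - counts)) > 1e-6)
    stop("Burnside averages did not round to integers; group construction is inconsistent")
  counts <- as.integer(counts)
  names(counts) <- as.character(seq_len(M))
  attr(counts, "cumulative") <- cumsum(counts)
  counts
}

.cycle_lengths <- function(p) {
  n <- length(p)
  seen <- logical(n)
  out <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    len <- 0L; x <- s
    while (!seen[x]) { seen[x] <- TRUE; x <- p[x]; len <- len + 1L }
    out <- c(out, len)
  }
  out
}

.series_mult <- function(a, b, M) {
  out <- numeric(M + 1L)
  for (d in 0:M)
    out[d + 1L] <- sum(a[1:(d + 1L)] * b[(d + 1L):1L])
  out
}

#' Build a permutationally invariant polynomial basis
#'
#' Enumerates one basis polynomial per orbit of monomials in the pair
#' (Morse) variables under the induced pair-permutation group, for total
#' degrees 1 to `max_order`; each polynomial is the plain sum of the
#' distinct monomials in its orbit, so invariance is exact by
#' construction.  Orbits are identified by their lexicographically
#' maximal member (the canonical representative); polynomials are ordered
#' by total degree, then by descending lexicographic order of the
#' canonical exponent vector.
#'
#' The degree-0 constant polynomial is included by default, matching the
#' basis-size convention of the standard monomial-symmetrization (MSA)
#' codes; set `include_constant = FALSE` for the strictly degree >= 1
#' basis.
#'
#' @param sym a `pip_symmetry` or symmetry string.
#' @param max_order maximum total degree (>= 1).
#' @param include_constant include the degree-0 polynomial? Default `TRUE`.
#' @param expand build the monomial evaluation graph (needed to evaluate
#'   or fit)?  Set `FALSE` to only count and store canonical
#'   representatives, e.g. for large bases.
#' @param cap resource guard: maximum number of monomials visited during
#'   enumeration (default 2e7); exceeding it raises an error.
#' @return object of class `pip_basis`: fields `symmetry`, `max_order`,
#'   `size`, `degree`, `canonical` (matrix of canonical exponent vectors)
#'   and, when expanded, the evaluation graph `mono` (monomial exponent
#'   rows), `mcoef` (integer multiplicities) and `pptr` (1-based offsets
#'   delimiting each polynomial's monomial block).
#' @examples
#' b <- pip_basis("A3", 2)
#' b$size  # 4: constant + 1 orbit at degree 1 + 2 at degree 2
#' @export
pip_basis <- function(sym, max_order, include_constant = TRUE,
                      expand = TRUE, cap = 2e7) {
  sym <- pip_symmetry(sym)
  stopifnot(max_order >= 1L, cap > 0)
  est <- choose(sym$n_pairs + max_order, max_order)
  if (est > cap)
    stop("enumeration of ~", format(est, big.mark = ","),
         " monomials exceeds cap of ", format(cap, big.mark = ","),
         "; raise `cap` to proceed")
  enum <- cpp_enumerate_orbits(sym$pair_perms - 1L, sym$n_pairs,
                               as.integer(max_order), cap)
  canon <- enum$canonical
  degree <- as.integer(enum$degree)
  if (include_constant) {
    canon <- rbind(matrix(0L, 1L, sym$n_pairs), canon)
    degree <- c(0L, degree)
  }
  basis <- structure(list(
    symmetry = sym,
    max_order = as.integer(max_order),
    include_constant = include_constant,
    n_var = sym$n_pairs,
    size = length(degree),
    degree = degree,
    canonical = canon,
    mono = NULL, mcoef = NULL, pptr = NULL
  ), class = "pip_basis")
  if (expand) basis <- .expand_basis(basis)
  basis
}

.expand_basis <- function(basis) {
  sym <- basis$symmetry
  ex <- cpp_expand_orbits(basis$canonical, sym$pair_perms - 1L)
  basis$mono <- ex$mono
  basis$mcoef <- rep(1L, nrow(ex$mono))
  basis$pptr <- ex$pptr
  basis
}

#' @export
print.pip_basis <- function(x, ...) {
  cat("PIP basis: symmetry ", x$symmetry$spec, ", max order ", x$max_order,
      ", ", x$size, " polynomials (constant term ",
      if (x$include_constant) "included" else "excluded", ")\n", sep = "")
  tab <- table(x$degree)
  cat("  per degree:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  if (is.null(x$mono)) cat("  evaluation graph not expanded\n")
  invisible(x)
}

#' Symmetrize a single monomial into its orbit sum
#'
#' Applies every group element to the exponent vector and returns the sum
#' of the distinct images: the smallest invariant polynomial containing
#' the monomial.  Any member of the same orbit yields the identical
#' polynomial (same canonical representative).
#'
#' @param exponents non-negative integer vector over the pair variables,
#'   not all zero.
#' @param sym a `pip_symmetry` or symmetry string.
#' @return list with `canonical` (lex-maximal exponent vector), `mono`
#'   (matrix of the orbit's distinct exponent vectors), `orbit_size`.
#' @export
symmetrize_monomial <- function(exponents, sym) {
  sym <- pip_symmetry(sym)
  e <- as.integer(exponents)
  stopifnot(length(e) == sym$n_pairs, all(e >= 0L))
  if (all(e == 0L))
    stop("the all-zero exponent vector is the constant term, not a monomial orbit")
  imgs <- matrix(e[t(sym$pair_perms)], nrow = sym$group_order,
                 ncol = sym$n_pairs, byrow = TRUE)
  imgs <- unique(imgs)
  ord <- do.call(order, c(lapply(seq_len(ncol(imgs)), function(k) -imgs[, k])))
  imgs <- imgs[ord, , drop = FALSE]
  list(canonical = imgs[1L, ], mono = imgs, orbit_size = nrow(imgs))
}

#' Evaluate basis polynomial values at a Morse vector
#'
#' @param basis an expanded `pip_basis`.
#' @param y Morse-variable vector of length `basis$n_var`, or a matrix
#'   with one column per configuration.
#' @return numeric vector of length `basis$size`, or a matrix
#'   (configurations x polynomials).
#' @export
basis_values <- function(basis, y) {
  stopifnot(inherits(basis, "pip_basis"))
  if (is.null(basis$mono)) stop("basis was built with expand = FALSE")
  if (is.matrix(y)) {
    stopifnot(nrow(y) == basis$n_var)
    cpp_design_matrix(basis$mono, basis$mcoef, basis$pptr, y)
  } else {
    stopifnot(length(y) == basis$n_var)
    cpp_poly_values(basis$mono, basis$mcoef, basis$pptr, as.numeric(y))
  }
}
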