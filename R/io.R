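# Versioned JSON serialization of PIP bases.  The file lists the
# symmetry, order and every polynomial's monomial block explicitly
# (exponent vectors over the pair variables, integer multiplicities), so
# a basis file is self-contained and round-trips exactly.  Variable k is
# the k-th unordered atom pair (i, j), i < j, pairs sorted
# lexicographically with atoms numbered class by class.

#' Write and read PIP basis files
#'
#' @param basis an expanded `pip_basis`.
#' @param path file path (JSON).
#' @return `read_basis`: a `pip_basis`; `write_basis`: the path,
#'   invisibly.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "pip_basis"))
  if (is.null(basis$mono)) basis <- .expand_basis(basis)
  polys <- lapply(seq_len(basis$size), function(j) {
    rows <- basis$pptr[j]:(basis$pptr[j + 1L] - 1L)
    list(degree = basis$degree[j],
         mono = unname(lapply(rows, function(r) as.integer(basis$mono[r, ]))),
         coef = as.integer(basis$mcoef[rows]))
  })
  obj <- list(format = "pipfit-basis", version = 1L,
              symmetry = basis$symmetry$spec,
              max_order = basis$max_order,
              include_constant = basis$include_constant,
              n_var = basis$n_var,
              variable_order = "pairs (i,j), i<j, lexicographic; atoms class-by-class",
              size = basis$size,
              polynomials = polys)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "pipfit-basis"))
    stop("not a pipfit basis file: ", path)
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported pipfit basis format version: ", obj$version)
  sym <- pip_symmetry(obj$symmetry)
  n_var <- as.integer(obj$n_var)
  if (n_var != sym$n_pairs)
    stop("basis file n_var ", n_var, " does not match symmetry ", obj$symmetry)
  size <- length(obj$polynomials)
  mono <- list(); mcoef <- integer(0); pptr <- 1L
  degree <- integer(size); canon <- matrix(0L, size, n_var)
  for (j in seq_len(size)) {
    p <- obj$polynomials[[j]]
    block <- do.call(rbind, lapply(p$mono, function(e) as.integer(unlist(e))))
    mono[[j]] <- block
    mcoef <- c(mcoef, as.integer(unlist(p$coef)))
    pptr <- c(pptr, pptr[length(pptr)] + nrow(block))
    degree[j] <- as.integer(p$degree)
    canon[j, ] <- block[1L, ]
  }
  structure(list(symmetry = sym,
                 max_order = as.integer(obj$max_order),
                 include_constant = isTRUE(obj$include_constant),
                 n_var = n_var, size = size, degree = degree,
                 canonical = canon,
                 mono = do.call(rbind, mono),
                 mcoef = mcoef, pptr = pptr),
            class = "pip_basis")
}
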