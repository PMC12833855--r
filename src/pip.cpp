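#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

// Kernels for PIP basis construction and evaluation-graph differentiation.
// Conventions shared with the R side:
//  - perms: group_order x n_var integer matrix, 0-based, row g maps variable
//    slot i to source slot perms(g, i), i.e. (g.e)[i] = e[perms(g, i)].
//  - monomials: n_mono x n_var exponent matrix; each basis polynomial is a
//    contiguous block of monomial rows given by 1-based offsets pptr
//    (length n_poly + 1), each row weighted by an integer multiplicity.

static bool is_identity_row(const IntegerMatrix& perms, int g) {
  for (int i = 0; i < perms.ncol(); ++i)
    if (perms(g, i) != i) return false;
  return true;
}

// true iff e is lexicographically >= every image of e under the group
static bool is_canonical(const std::vector<int>& e, const IntegerMatrix& perms,
                         const std::vector<bool>& skip) {
  const int G = perms.nrow(), n = perms.ncol();
  for (int g = 0; g < G; ++g) {
    if (skip[g]) continue;
    for (int i = 0; i < n; ++i) {
      const int a = e[perms(g, i)], b = e[i];
      if (a > b) return false;   // image beats e: not canonical
      if (a < b) break;          // e beats this image
    }
  }
  return true;
}

// Enumerate canonical representatives (lex-maximal orbit members) of all
// monomials with total degree 1..max_order. Vectors are visited in
// degree-ascending, lex-descending order so the output ordering is
// deterministic. `cap` bounds the number of monomials visited.
// [[Rcpp::export]]
List cpp_enumerate_orbits(IntegerMatrix perms, int n_var, int max_order,
                          double cap) {
  std::vector<bool> skip(perms.nrow());
  for (int g = 0; g < perms.nrow(); ++g) skip[g] = is_identity_row(perms, g);

  std::vector<int> canon;          // flattened canonical exponent vectors
  std::vector<int> canon_deg;
  std::vector<int> e(n_var, 0);
  double visited = 0;

  for (int d = 1; d <= max_order; ++d) {
    // iterative enumeration of compositions of d into n_var parts,
    // lex-descending: start at (d, 0, ..., 0)
    std::fill(e.begin(), e.end(), 0);
    e[0] = d;
    for (;;) {
      if (++visited > cap)
        stop("monomial enumeration exceeded cap of %.0f; raise `cap` if this is intended", cap);
      if (is_canonical(e, perms, skip)) {
        canon.insert(canon.end(), e.begin(), e.end());
        canon_deg.push_back(d);
      }
      // next composition in lex-descending order: find rightmost position
      // before the last with a positive entry, decrement it, move the
      // remainder (tail sum + 1) into the next slot
      int k = n_var - 2;
      while (k >= 0 && e[k] == 0) --k;
      if (k < 0) break;
      int rest = e[n_var - 1] + 1;
      e[n_var - 1] = 0;
      --e[k];
      e[k + 1] = rest;
    }
  }

  const int n_orb = canon_deg.size();
  IntegerMatrix cm(n_orb, n_var);
  for (int r = 0; r < n_orb; ++r)
    for (int c = 0; c < n_var; ++c) cm(r, c) = canon[(size_t)r * n_var + c];
  return List::create(_["canonical"] = cm,
                      _["degree"] = wrap(canon_deg),
                      _["visited"] = visited);
}

// Expand canonical representatives into full orbits (each distinct orbit
// member once). Returns the concatenated monomial matrix plus 1-based
// polynomial offsets.
// [[Rcpp::export]]
List cpp_expand_orbits(IntegerMatrix canon, IntegerMatrix perms) {
  const int n_orb = canon.nrow(), n = canon.ncol(), G = perms.nrow();
  std::vector<int> mono;
  IntegerVector pptr(n_orb + 1);
  pptr[0] = 1;
  std::vector<int> e(n), img(n);
  for (int r = 0; r < n_orb; ++r) {
    for (int c = 0; c < n; ++c) e[c] = canon(r, c);
    std::set<std::vector<int>, std::greater<std::vector<int> > > orbit;
    for (int g = 0; g < G; ++g) {
      for (int i = 0; i < n; ++i) img[i] = e[perms(g, i)];
      orbit.insert(img);
    }
    for (std::set<std::vector<int>, std::greater<std::vector<int> > >::iterator
           it = orbit.begin(); it != orbit.end(); ++it)
      mono.insert(mono.end(), it->begin(), it->end());
    pptr[r + 1] = pptr[r] + (int)orbit.size();
  }
  const int n_mono = (pptr[n_orb] - 1);
  IntegerMatrix mm(n_mono, n);
  for (int r = 0; r < n_mono; ++r)
    for (int c = 0; c < n; ++c) mm(r, c) = mono[(size_t)r * n + c];
  return List::create(_["mono"] = mm, _["pptr"] = pptr);
}

static inline double mono_value(const IntegerMatrix& mono, int m,
                                const double* y, int n_var) {
  double v = 1.0;
  for (int k = 0; k < n_var; ++k) {
    int e = mono(m, k);
    const double yk = y[k];
    while (e-- > 0) v *= yk;
  }
  return v;
}

// Values of every basis polynomial at one configuration.
// [[Rcpp::export]]
NumericVector cpp_poly_values(IntegerMatrix mono, IntegerVector mcoef,
                              IntegerVector pptr, NumericVector y) {
  const int n_poly = pptr.size() - 1, n_var = mono.ncol();
  NumericVector out(n_poly);
  for (int j = 0; j < n_poly; ++j) {
    double s = 0.0;
    for (int m = pptr[j] - 1; m < pptr[j + 1] - 1; ++m)
      s += mcoef[m] * mono_value(mono, m, REAL(y), n_var);
    out[j] = s;
  }
  return out;
}

// Design matrix: polynomial values for many configurations
// (Y is n_var x n_geom); result n_geom x n_poly.
// [[Rcpp::export]]
NumericMatrix cpp_design_matrix(IntegerMatrix mono, IntegerVector mcoef,
                                IntegerVector pptr, NumericMatrix Y) {
  const int n_poly = pptr.size() - 1, n_var = mono.ncol(), n_geom = Y.ncol();
  NumericMatrix out(n_geom, n_poly);
  for (int gidx = 0; gidx < n_geom; ++gidx) {
    const double* y = &Y(0, gidx);
    for (int j = 0; j < n_poly; ++j) {
      double s = 0.0;
      for (int m = pptr[j] - 1; m < pptr[j + 1] - 1; ++m)
        s += mcoef[m] * mono_value(mono, m, y, n_var);
      out(gidx, j) = s;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_energy_many(IntegerMatrix mono, IntegerVector mcoef,
                              IntegerVector pptr, NumericVector coef,
                              NumericMatrix Y) {
  const int n_poly = pptr.size() - 1, n_var = mono.ncol(), n_geom = Y.ncol();
  NumericVector out(n_geom);
  for (int gidx = 0; gidx < n_geom; ++gidx) {
    const double* y = &Y(0, gidx);
    double V = 0.0;
    for (int j = 0; j < n_poly; ++j) {
      double s = 0.0;
      for (int m = pptr[j] - 1; m < pptr[j + 1] - 1; ++m)
        s += mcoef[m] * mono_value(mono, m, y, n_var);
      V += coef[j] * s;
    }
    out[gidx] = V;
  }
  return out;
}

// One forward evaluation recording monomial values, then one backward sweep
// accumulating adjoints: polynomial -> monomial -> Morse variable. The
// adjoint of y_k receives mbar * e_k * v / y_k for every monomial with
// e_k > 0 (y is strictly positive for Morse variables).
// [[Rcpp::export]]
List cpp_eval_reverse(IntegerMatrix mono, IntegerVector mcoef,
                      IntegerVector pptr, NumericVector coef,
                      NumericVector y) {
  const int n_poly = pptr.size() - 1, n_var = mono.ncol(), n_mono = mono.nrow();
  std::vector<double> mval(n_mono);
  double V = 0.0;
  for (int j = 0; j < n_poly; ++j) {
    double s = 0.0;
    for (int m = pptr[j] - 1; m < pptr[j + 1] - 1; ++m) {
      mval[m] = mono_value(mono, m, REAL(y), n_var);
      s += mcoef[m] * mval[m];
    }
    V += coef[j] * s;
  }
  NumericVector ybar(n_var);
  for (int j = 0; j < n_poly; ++j) {
    const double pbar = coef[j];
    if (pbar == 0.0) continue;
    for (int m = pptr[j] - 1; m < pptr[j + 1] - 1; ++m) {
      const double mbar = pbar * mcoef[m];
      for (int k = 0; k < n_var; ++k) {
        const int e = mono(m, k);
        if (e > 0) ybar[k] += mbar * e * mval[m] / y[k];
      }
    }
  }
  return List::create(_["energy"] = V, _["dVdy"] = ybar);
}

// Forward-mode dV/dy: one independent derivative-polynomial evaluation per
// Morse variable (cost ~ n_var energy evaluations, no value reuse).
// [[Rcpp::export]]
NumericVector cpp_eval_forward_dVdy(IntegerMatrix mono, IntegerVector mcoef,
                                    IntegerVector pptr, NumericVector coef,
                                    NumericVector y) {
  const int n_poly = pptr.size() - 1, n_var = mono.ncol();
  NumericVector ybar(n_var);
  for (int k = 0; k < n_var; ++k) {
    double acc = 0.0;
    for (int j = 0; j < n_poly; ++j) {
      if (coef[j] == 0.0) continue;
      double s = 0.0;
      for (int m = pptr[j] - 1; m < pptr[j + 1] - 1; ++m) {
        const int ek = mono(m, k);
        if (ek == 0) continue;
        double v = (double)ek;
        for (int l = 0; l < n_var; ++l) {
          int e = mono(m, l);
          if (l == k) e -= 1;
          const double yl = y[l];
          while (e-- > 0) v *= yl;
        }
        s += mcoef[m] * v;
      }
      acc += coef[j] * s;
    }
    ybar[k] = acc;
  }
  return ybar;
}
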