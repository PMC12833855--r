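---
title: "Permutationally invariant polynomial surfaces: methods and design"
author: "pipfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutationally invariant polynomial surfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipfit)
```

# The model

A potential energy surface for a molecule with interchangeable atoms is
represented as a linear expansion

$$V(\mathbf y) = \sum_{\alpha} c_\alpha\, p_\alpha(\mathbf y),
\qquad y_{ij} = e^{-r_{ij}/a},$$

where $r_{ij}$ are the internuclear distances, $a$ is the Morse range
parameter, and each $p_\alpha$ is a *permutationally invariant
polynomial* (PIP): the sum of the distinct images of a monomial in the
pair variables under the group of like-atom permutations.  The Morse
transform maps $[0,\infty)$ into $(0,1]$, decays smoothly toward
dissociation, and keeps the linear fit well behaved at stretched
geometries where raw distances diverge.  The default $a = 3.0$ bohr is
the value commonly used for protonated-water systems; larger $a$
flattens the variables and shifts flexibility toward long range.

A symmetry string such as `"A5B2"` declares the atom classes.  Atoms
are numbered class by class; unordered pairs $(i,j)$, $i<j$, are
ordered lexicographically, giving $n(n-1)/2$ pair variables.  The atom
group is the direct product of per-class symmetric groups (order
$\prod_k n_k!$, 240 for A5B2) and acts on pairs by
$(i,j) \mapsto (\sigma i, \sigma j)$.  Because every basis polynomial
is a full orbit sum, invariance of the fitted surface is exact by
construction, not a property to be approximated by the fit.

## Counting and enumerating the basis

Two independent routes produce the basis size, and the package insists
they agree:

* **Enumeration.**  All exponent vectors of total degree $1..M$ are
  visited degree by degree in descending lexicographic order; a vector
  is kept iff it is the lexicographic maximum of its orbit ("canonical
  representative").  This needs no hash table and supports the
  A5B2/order-7 case (1.18 million monomials against 240 group elements)
  in about a second of compiled code.  A configurable cap on the number
  of monomials visited turns combinatorially infeasible requests into
  an explicit resource error.
* **Burnside/Molien counting.**  The number of degree-$d$ orbits equals
  the group average of the number of monomials fixed by each element; a
  monomial is fixed iff its exponent vector is constant on each cycle
  of the induced pair permutation, so each element contributes
  $\prod_{\text{cycles}} (1-t^{\ell})^{-1}$ and the averaged truncated
  series gives exact per-degree counts without touching any monomial.

**Constant-term convention.**  The degree-0 polynomial is *included* in
the basis and in reported sizes.  With it, the A5B2 sizes at maximum
order 3–7 are 59, 218, 772, 2651 and 8717, matching the sizes quoted
for the standard monomial-symmetrization (MSA) bases; the degree-1..7
orbit counts alone are 58/217/771/2650/8716.  Including the constant
also lets a fit absorb an arbitrary energy origin, so no separate
intercept option is needed.

**Ordering.**  Polynomials are sorted by total degree, then by
descending lexicographic order of the canonical exponent vector.  Any
deterministic ordering would do; this one makes coefficient files
reproducible across runs and platforms.

## Fitting

`pip_fit()` minimizes $\sum_i w_i (V(\mathbf y_i) - E_i)^2$ with
weights $w(E) = \Delta/(E+\Delta)$ on the energy relative to the
dataset minimum ($\Delta = 0.1$ hartree by default, so configurations
0.1 hartree up get half weight).  Design decisions:

* The solver is a rank-revealing SVD with singular values below
  $10^{-12}\sigma_\max$ dropped; under-determined or rank-deficient
  systems return the minimum-norm solution with a warning stating the
  effective rank.  Normal equations are never formed.
* The weighted RMSE is $\sqrt{\sum w_i r_i^2 / \sum w_i}$, which
  reduces to the plain RMSE for unit weights.  $R^2$ is
  $1 - SS_{res}/SS_{tot}$ about the dataset mean.
* Relative energies for weighting and filtering are measured from the
  dataset minimum unless a `reference_energy` is supplied.

`augment_basis()` exploits closure under multiplication: the product
of two PIPs is a PIP.  Candidates are pairwise products of basis
polynomials up to a degree cap (default: base order + 1), deduplicated
by polynomial identity, scored by their largest absolute value over
the dataset geometries — the polynomials that grow largest probe the
closest-approach configurations where the basis needs flexibility —
and the top scorers are appended.  Product polynomials can be linearly
dependent on the base within the span of the data; the rank-revealing
solver handles this and says so.

## Reverse differentiation

The evaluation graph is
Cartesians → distances → Morse variables → monomials → orbit
polynomials → energy.  The reverse gradient performs one forward pass
that stores every monomial value, then one backward sweep in reverse
topological order: the adjoint of polynomial $\alpha$ is $c_\alpha$,
each monomial inherits $c_\alpha$ times its integer multiplicity, and
a monomial with value $v$ and exponent $e_k>0$ adds
$\bar m\, e_k v / y_k$ to the adjoint of $y_k$ (safe because Morse
variables are strictly positive).  Finally
$\partial y_k/\partial r_k = -y_k/a$ is computed from the stored
$y_k$, and unit bond vectors map $\partial V/\partial r$ to Cartesians.
All $3N$ derivatives emerge from a single pass whose floating-point
cost is a fixed small multiple of one energy evaluation —
`count_operations()` bounds the ratio below 5, and in practice it is
about 2–3 — independent of the number of atoms.

Forward-mode differentiation (one derivative polynomial per Morse
variable, cost $\sim n_{var}$ energies) and central finite differences
are kept as independent oracles; the test suite requires three-way
agreement ($10^{-10}$ relative between the analytic modes, $10^{-6}$
against finite differences).  Coincident atoms ($r < 10^{-8}$ bohr)
raise an explicit error since the distance gradient is undefined there.

The Hessian is built from central differences of reverse gradients
(default step $10^{-3}$ bohr) and symmetrized as $(H + H^T)/2$; the
pre-symmetrization defect is itself a consistency diagnostic.

# Diffusion Monte Carlo

`run_dmc()` implements the standard unbiased (unweighted-walker)
protocol.  Per step: every Cartesian degree of freedom diffuses by
Gaussian noise of standard deviation $\sqrt{\delta\tau/m}$; each walker
is replicated $\lfloor e^{-(V - E_{ref})\delta\tau} + u \rfloor$ times
($u$ uniform, cap 3 per step); the reference energy is updated to the
population mean potential minus a feedback term
$\alpha (N' - N_{target})/N_{target}$ with $\alpha = 1/\delta\tau$ by
default.  Walkers start exactly at the supplied minimum configuration,
not thermally spread.  The ZPE of one trajectory is the average
reference energy over the post-equilibration steps minus the potential
minimum; independent trajectories (counter-derived sub-seeds, so runs
are bit-for-bit reproducible per seed) give the quoted uncertainty as
their standard deviation.  The production-scale defaults are 30,000
walkers, 55,000 steps of 5 a.u. with 5,000 discarded, 10 trajectories.

The branching cap and feedback constants are not uniquely fixed by the
protocol's usual description; the defaults above are the common
choices, and both are exposed in the interface.  A hole scan records
any walker whose potential falls more than a tolerance (default
10 cm⁻¹) below the declared minimum — a nonempty report means the
fitted surface has an unphysical low-energy region.

The automated checks run scaled-down problems chosen to finish in
minutes while keeping the statistical error a few cm⁻¹: 2,000 walkers
and 20,000 steps on harmonic ($\omega = 0.005$ a.u.) and Morse
oscillators, compared to closed forms ($\omega/2$ per mode;
$\omega/2 - \omega^2/16D_e$ for Morse) within three standard errors.
The time-step bias test uses a deliberately stiff oscillator
($\omega = 0.02$ a.u.) at $\delta\tau = 20$ vs 10 a.u. so the bias
(tens of cm⁻¹ there) stands clear of the noise; halving the step must
shrink it.

# Stationary points and harmonic frequencies

`optimize_geometry()` runs BFGS on the analytic gradients and then
polishes with Newton steps on the numeric Hessian until the gradient
infinity norm is below `gtol` (default $10^{-8}$ hartree/bohr; zero is
rejected as unreachable).  `normal_modes()` diagonalizes the
mass-weighted Hessian $H_{ij}/\sqrt{m_i m_j}$; wavenumbers are
$\sqrt{\lambda}$ in atomic units converted by 219474.6313632 cm⁻¹ per
hartree, with negative eigenvalues reported as negative (imaginary)
frequencies.  Raw eigenvalues are reported — translations and rotations
are *not* projected out — and modes with $|\nu| < 5$ cm⁻¹ are counted
as zero modes; frequency comparisons (`frequency_mae()`) are meant to
be applied to the vibrational modes only.  Masses default to
most-abundant-isotope values (H = 1.00782503207 u etc., converted by
1822.888486 m$_e$/u) and can be overridden per call.  Saddle-point
location is out of scope: saddle geometries must be supplied.

# Minimum-energy paths by simulated annealing

`anneal_mep()` integrates classical dynamics with velocity Verlet
(forces from reverse gradients), removing a fixed fraction of the
kinetic energy every step (velocity rescale by
$\sqrt{1 - \text{loss}}$) and halving it whenever it exceeds a brake
threshold.  Defaults mirror the production protocol: initial KE
12 cm⁻¹, $\delta t = 5$ a.u., loss $10^{-4}$ per step, brake at
100 cm⁻¹ with factor 0.5.  The initial velocity points along the
direction that shrinks the designated reaction-coordinate pair, since
annealing runs fall inward from large separation.  The relaxed profile
is the per-bin minimum of the trajectory energy binned on the pair
distance (default width 0.05 bohr); the termination test requires both
the kinetic energy and the gradient norm to be small, so turning
points (KE $\approx 0$, large gradient) do not stop the run.
`merge_paths()` combines overlapping profiles and reports the maximum
energy disagreement on shared bins; `dissociation_energy()` demands a
flat outer tail (mean $|dE/d\xi|$ below a tolerance) before returning
plateau minus minimum.

Two balances govern parameter choice, and the test problem is sized
accordingly.  The travel budget $v_0\,\delta t \cdot 2/\text{loss}$
must exceed the distance to the well (otherwise the KE dies on the
flat dissociative plateau, where the gradient is also small and the
run would terminate early); and the annealing time to a target
displacement $\Delta r$ scales as $(2/\text{loss})\ln(KE_0/KE_{end})$
steps.  The Morse-diatomic recovery check therefore starts at
$10 r_e = 12$ bohr with loss $2\times10^{-4}$, which recovers $r_e$ to
$5\times10^{-4}$ bohr and $D_e$ to $10^{-4}$ relative in roughly
$10^5$ steps.

# Synthetic data

The toy potentials stand in for ab initio datasets.
`morse_sum_potential()` sums a Morse well over every atom pair with
parameters shared within pair classes, which makes it exactly
permutationally invariant — the same invariance the PIP basis encodes —
and gives closed forms for the diatomic well depth, minimum and
harmonic frequency.  `sample_dataset()` draws Gaussian displacements
about the relaxed configuration (default $\sigma = 0.25$ bohr) plus
stretched configurations along a designated pair at separations
reaching 300 bohr, mimicking how real datasets cover both the well and
the dissociation channel; energies above a cap relative to the
potential minimum are discarded.  Near-equilibrium sampling makes the
retained energy distribution right-skewed, as in real datasets.

What the toys do *not* emulate: electronic-structure noise and basis
set artifacts, many-body (non-pairwise) interactions, conical
intersections or multiple dissociation channels, and dataset sizes in
the $10^4$–$10^5$ range.  Passing tests therefore demonstrate the
correctness of the machinery (symmetrization, fitting, derivatives,
samplers) at desk scale, not the physical accuracy of any particular
production surface.

# Numerical choices and limitations

* Units are bohr/hartree/electron-mass throughout; conversions are
  single named constants.
* XYZ files are assumed to be in Angstrom unless the comment line says
  "bohr" (or the reader is told otherwise), matching the format's
  de facto convention; the dataset format is bohr-native and versioned.
* Geometry/symmetry correspondence is positional (atoms class by
  class); an explicit element-to-class map can be supplied when the
  element order of external data differs.
* Orbit expansion stores each distinct orbit member once with an
  integer multiplicity (relevant for product polynomials), and all
  invariance tests are run against the full group, not generators.
* The basis cap defaults to $2\times10^7$ monomials visited; A5B2 at
  order 8 ($\sim$3.9M monomials) is feasible, order 10+ is not meant
  to be.
* Fitting is linear and unregularized by design; gradient data cannot
  be used as fitting targets.
* DMC provides no importance sampling or trial wavefunctions, so very
  stiff modes need small time steps; the linear-in-$\delta\tau$ bias
  of the branching scheme is measurable and must shrink when the step
  is halved.
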