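---
title: "Methods: surface hopping on a spin-orbit-coupled vibronic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface hopping on a spin-orbit-coupled vibronic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`surfhop` studies nonadiabatic relaxation of a photo-excited
heteroaromatic — the built-in default emulates 2-thiopyridone (2-TP) —
with mixed quantum–classical trajectory surface hopping.  The electronic
structure is a linear vibronic coupling (LVC) Hamiltonian: each spin-pure
(MCH) state `n` is a harmonic surface over dimensionless
mass-frequency-scaled normal-mode coordinates, shifted linearly by
intrastate gradients `kappa_i^(n)`; states of the same multiplicity mix
through linear couplings `lambda_i^(nm) q_i`; singlet–triplet blocks
carry constant spin–orbit couplings `V_SO`.  Diagonalizing the full
matrix at the current geometry yields the spin-mixed ("diagonal") basis
in which the dynamics are propagated.  All internal computation uses
Hartree atomic units (hbar = 1); the interfaces use eV, fs and Angstrom,
with conversion constants defined once in `sh_units`.

The assumptions inherited from the LVC form: harmonic diabatic surfaces
(no bond breaking — see limitations), geometry-independent interstate
couplings' gradients, and spin–orbit couplings that do not vary with
geometry.  By default each triplet enters as a single component with a
scalar effective coupling; `triplet_components = 3` switches to three
degenerate sublevels sharing the coupling constant, in which case the
effective singlet–triplet coupling strength grows by sqrt(3) — the
simplification is a deliberate reduction, not an approximation claim.

# The propagation algorithm

Each classical step of `dt = 0.5` fs does, in order:

1. **Nuclear motion** — velocity Verlet on the active diagonal surface
   with analytic Hellmann–Feynman forces.  The Verlet integration is
   internally subdivided (`nuc_substeps = 40`, i.e. a 0.0125 fs nuclear
   step).  This subdivision exists because the active adiabatic surface
   bends on very short length scales near narrowly avoided crossings;
   at 0.5 fs resolution those passages cost up to 1e-3 Hartree each,
   while at 0.0125 fs the worst inter-hop energy drift over 100 ps of
   ensemble dynamics is below 1e-4 Hartree.  Hop decisions, decoherence,
   amplitude propagation and stored frames all remain at `dt`, so the
   surface-hopping protocol itself is unchanged.
2. **Amplitude propagation** by local diabatization: the overlap of
   consecutive eigenvector sets (exact in an LVC model, because the MCH
   basis is geometry-independent) is Löwdin-orthogonalized to the nearest
   unitary `T`, the Hamiltonian is interpolated linearly between the step
   endpoints in the old frame, and the step propagator is
   `T^dagger prod_m exp(-i Hbar_m dt/substeps)` with 100 substeps.
3. **Hop decision** — fewest-switches probabilities in the propagator
   formulation: the fractional decrease of the active population is
   apportioned among targets by the propagator cross terms, negative
   contributions clamped at zero (and the vector rescaled in the rare
   case clamping pushes its sum above one).  One uniform variate per
   step.  The formula follows the overlap-based scheme; nonadiabatic
   coupling vectors are never computed.
4. **Momentum rescaling** at accepted hops along the full momentum
   vector, `p' = p sqrt(1 - gap/ekin)`, making total energy conservation
   across hops exact.  Frustrated hops (gap > kinetic energy) keep the
   momentum by default (`"continue"`); `"reflect"` is available.  The
   reference protocol does not state these settings; the defaults are
   declared, not inferred.
5. **Decoherence** — the energy-based correction with C = 0.1 Hartree,
   applied once per classical step after the hop decision:
   `tau_k = (1/|E_k - E_active|)(1 + C/ekin)`, non-active amplitudes
   damped, the active amplitude rescaled to restore unit population,
   phases untouched.  Steps with zero kinetic energy skip the correction
   and are counted in the trajectory log.

Eigenvector phase convention: eigenvalues ascending; each eigenvector's
largest-magnitude component is made real and positive, then the phase is
locked to the previous geometry by maximal overlap.  Overlaps below 0.5
are counted as tracking failures in the trajectory log; propagation
continues with the best-overlap assignment.

State labels are kept in both pictures.  The MCH parent of a diagonal
state is the MCH state of largest weight `|U[n,k]|^2`; hop events record
both the diagonal indices and the MCH parents, and all three population
pictures (active-diagonal, active-MCH, amplitude) are computed by
`compute_populations()` so their agreement can be checked.

# Initial conditions

The ground-state Wigner distribution of a harmonic mode in dimensionless
coordinates is a product of independent Gaussians in `q` and `p` with
variance 1/2, giving a mean classical mode energy equal to the zero-point
energy `omega/2`.  Sampling is exact (no thermal excitation, matching the
reference protocol).  One master seed streams per-trajectory sub-seeds
for both the sample and the hopping randomness, so any single trajectory
can be re-run in isolation and the whole pipeline is reproducible from
one integer.

# The default model as a synthetic study system

`default_2tp_model()` defines the study conditions: five states with the
Franck–Condon vertical energies 3.16 (S1), 3.82 (S2), 2.64 (T1), 2.90
(T2) eV, over six modes of an idealized planar 12-atom 2-TP geometry —
in-plane S/ring rocking (225 cm^-1), N–H rocking (1120 cm^-1) and ring
stretching (1590 cm^-1), and out-of-plane ring torsion (310 cm^-1) plus
two N–H wags (460, 570 cm^-1), with hand-drawn displacement patterns
orthonormalized within each symmetry class.

No coupling constants are published for this system, so the defaults are
illustrative, set from physical scales: intrastate gradients giving
reorganization energies of 0.01–0.3 eV, placed only on in-plane modes
(out-of-plane gradients vanish by planar symmetry), with the (n,pi*)
states S1/T2 displaced most strongly along the N–H rocking mode;
same-multiplicity couplings of 0.02–0.08 eV, S1/S2 on the in-plane
rocking modes and T1/T2 on the out-of-plane modes; spin–orbit constants
of 20–80 cm^-1, the scale of a sulfur heavy-atom effect.  They were
chosen to realize the qualitative relaxation pattern of the reference
system — prompt S2→S1 internal conversion (mean first hop ~44 fs in the
default ensemble) followed by markedly slower intersystem crossing (first
S1→T2 hop ~250 fs on average) with abundant backward transitions — and
are not fitted to any published observable.

What the generator does **not** emulate, and hence what passing tests do
not show about real data:

* **Dimensionality.**  Six modes instead of thirty: the ~1 eV of excess
  energy stays concentrated, so vibrational amplitudes (and derived
  bond-length fluctuations) are much larger than a full-dimensional
  simulation would give, and the manifolds drift toward microcanonical
  equilibrium rather than funneling irreversibly into T1.
* **Ground-state recovery.**  The harmonic model cannot reach the S1/S0
  conical intersection (a 3.2 eV diabatic gap closes only at
  displacements far outside the harmonic regime), so the minority
  S1'→S0 channel is essentially dark in the default ensemble; the
  kinetic machinery for it is exercised with scripted fixtures and
  synthetic rate models instead.
* **Character mixing.**  Constant spin–orbit couplings cannot reproduce
  the geometry-dependent orbital-character mixing that makes the real
  S1→T2 channel formally El-Sayed forbidden yet dominant; the model
  simply assigns that channel the largest coupling constant.

# Ensemble kinetics

`simulate_kinetics()` solves the first-order mass-action system
`dP/dt = K P` exactly by eigendecomposition of the rate matrix, with a
stiff `deSolve::lsoda` fallback if the eigenbasis is ill-conditioned
(condition number below 1e10 of unity); population conservation is then
structural.  The default network has nine rate constants: the main
forward chain S2→S1→T2→T1, its three backward partners, and three
minority forward channels S2→S1', S1'→S0 and S2→T2.  The S1' species
separates trajectories that leave S1 by internal conversion from those
that cross to the triplets; following the reference analysis the split
is implemented in the decay from S2, and S1' is unobservable — reported
inside S1 everywhere.

`fit_kinetic_model()` minimizes the unweighted sum of squared deviations
over all observable species simultaneously on the data grid
(Levenberg–Marquardt via `minpack.lm::nls.lm`, rates bounded to
[0, 1] fs^-1), with a multi-start over eight log-uniform initial guesses
in [1e-5, 1e-1] fs^-1 under a recorded seed.  Two numerical safeguards:
a tiny ridge term (`1e-4 * k` appended to the residual vector) gives the
optimizer a well-defined minimum along directions the data cannot see,
and after the best start is selected, any rate whose removal leaves the
data-only SSE unchanged (to 1e-9 relative) is pruned to zero — both
affect only unidentifiable rates (flows out of species that are never
populated); identified rates are recovered from noiseless synthetic data
to well within 0.1%.  Parameter uncertainties are asymptotic standard
errors from the Levenberg–Marquardt covariance; the exponential manifold
fit instead reports a trajectory-level bootstrap standard error, which
is the more honest uncertainty for ensemble fractions.

`fit_exponential_manifold()` fits `P(t) = exp(-t/tau)` to the summed
manifold population by 1-D least squares over `log10(tau)`
(`stats::optimize`, tolerance 1e-12); data that do not decay (final
value above 99.9% of the initial one, or the optimizer at its upper
bound) are flagged `converged = FALSE` rather than given a meaningless
lifetime.

# Structural analysis

Mode projections are mass-unweighted Cartesian scalar products with the
normalized displacement vectors, in Angstrom; the convention is stamped
into every output header.  For trajectories generated by the package the
projection of mode `i` is computed directly as
`q_i / sqrt(mu_i omega_i)` (in Angstrom), which equals the Cartesian
projection exactly for orthonormal mode vectors.  No Eckart/rotational
pre-alignment is applied by default (the dynamics never rotate the
frame); distances are translation-invariant by construction.

Out-of-plane modes of a planar molecule have an arbitrary sign.  Before
averaging hop-inducing geometries, every geometry with a negative
projection on the reference out-of-plane mode (by default the first one;
for the 2-TP set, the 570 cm^-1 N–H wag) is mirrored through the
molecular plane — a sign flip of all out-of-plane projections, in-plane
projections untouched, idempotent.  Hop statistics use the population
(denominator n) standard deviation, and the "hop-inducing geometry" is
the frame at the beginning of the classical step in which the hop fired.
MECP comparison follows the manifold geometry of the problem: in-plane
modes compare as `|mu - p_mecp|`; out-of-plane modes, whose sign is
arbitrary, compare as whether `|p_mecp| <= |mu| + 2 sigma`.

# Numerical choices and degenerate inputs

* Hamiltonian assembly, diagonalization and the propagation loop are
  compiled (RcppArmadillo); everything else is plain R.
* Hop probabilities: exact zeros when the active population did not
  decrease, when its starting population is below 1e-30, or when the
  apportioning denominator is non-positive.
* Momentum rescaling with zero kinetic energy allows only zero-gap hops.
* Decoherence with a zero gap applies no damping for that state; with a
  depleted active state the vector is renormalized as a whole.
* The kinetic eigen-solver falls back to `lsoda` (rtol = atol = 1e-12)
  for defective rate matrices.
* Test and acceptance problem sizes — 10–100 trajectories, 0.025–1 ps,
  1e5 Wigner samples, 50 fit repeats — were chosen so the full suite
  completes in a few minutes on one CPU while leaving every statistical
  check far from its noise floor.

# Known limitations

Beyond the generator items above: independent-trajectory surface hopping
itself does not conserve nuclear coherence (the decoherence correction
is a remedy, not a cure); uniform momentum rescaling ignores the
direction of the nonadiabatic coupling, which is unavailable in the
overlap scheme; the microcanonical six-mode ensemble lacks solvent
dissipation, so backward transitions are overrepresented at long times
relative to a condensed-phase experiment; and lifetimes extracted from
100 trajectories carry bootstrap errors of order 15%, which is why the
package reports them with an uncertainty instead of as a point value.
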