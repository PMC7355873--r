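---
title: "Isotope effects on NMR shieldings and the vibration hole: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope effects on NMR shieldings and the vibration hole: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibhole)
```

## The problem

An isotopic substitution leaves the Born–Oppenheimer potential-energy and
property surfaces untouched and changes only the nuclear masses.  The
observed NMR shielding of a nucleus is a vibrational average over the
shielding surface, so the substitution shifts it — the secondary isotope
shift, conventionally

$$ {}^{n}\Delta\delta \;=\; \delta(\mathrm{B}) - \delta(\mathrm{A})
   \;=\; \sigma(\mathrm{A}) - \sigma(\mathrm{B}), $$

where A is the unsubstituted and B the substituted isotopologue and $n$
counts the bonds between the substitution site and the reporting nucleus.
The region of the molecule where the vibration motif (average geometry,
mean-square amplitudes, amplitude covariances) responds to the substitution
is the *vibration hole*.  This package computes both the shifts and the hole
descriptors, at zero temperature, for any pair of isotopologues of a system
whose potential and shielding surfaces are supplied as evaluator functions.

## Zero-point averaging at second order (VPT2)

All formulas use dimensionless normal coordinates: the Cartesian
displacement is $\Delta x = \sum_i l_i q_i$ with
$l_i = m^{-1/2} e_i \,(\hbar/\omega_i)^{1/2}$, $e_i$ the orthonormal
eigenvectors of the mass-weighted Hessian.  In this convention the harmonic
ground state has $\langle q_i^2\rangle = 1/2$, which fixes the $-1/4$
prefactors below.  Per isotopologue $X$,

$$ \Delta\delta_{\mathrm{harm}}(X) = -\tfrac14\sum_i^{v} D^2\sigma[l_i], \qquad
   \Delta R(X) = -\tfrac14 \sum_k^{v} \frac{1}{\omega_k}
       \sum_i^{v} \phi_{iik}\, l_k, \qquad
   \Delta\delta_{\mathrm{anh}}(X) = -D\sigma[\Delta R], $$

with $\phi_{iik}$ the semi-diagonal cubic force constants and
$D^n\sigma[l]$ the $n$-th directional derivative of the shielding surface
along mode $l$.  $\Delta R$ is the shift of the vibrationally averaged
Cartesian geometry, $R_z = R_e + \Delta R$.  The isotope shift is the
explicit difference B $-$ A.  The index pairing in $\Delta R$ (the
$1/\omega$ weight and the displacement vector go with the singly
differentiated mode) is fixed by the one-dimensional closed form, where the
Morse oscillator gives
$\langle q\rangle = -\phi_{111}/4\omega$, and is confirmed by the
equivalence test below.

Derivatives are obtained by central two-point differences along mode
vectors: the cubic constants from mode-projected Hessians displaced by
$h_{\mathrm{FF}} = 0.005$ in the dimensionless coordinate (or, in the
force-difference variant, from second differences of mode-projected
gradients), and the shielding derivatives with $h_{\mathrm{NMR}} = 0.05$.
The cost per isotopologue is exactly two Hessian and two shielding
evaluations per normal mode, plus the equilibrium point.  Steps are applied
as $R_e + h\,l$; because non-canonic difference-dedicated directions can
have Cartesian norms far above the vibrational scale (several bohr for
rotation-dominated directions), the per-direction step is capped so that
the Cartesian displacement never exceeds what the largest vibrational mode
vector would produce — vibrational modes are unaffected by construction,
and the cap only protects the stencil accuracy of the rigid-dominated
directions.

## Difference-dedicated modes (DD-VPT2)

Standard VPT2 prices the *difference* of two isotopologues at twice the
cost of a full calculation.  The difference-dedicated reformulation
concentrates the difference into a few directions.  Both mode sets are
completed by rigid translations and rotations; B's modes are expanded
exactly in A's complete basis,

$$ l_i(\mathrm{B}) = \sum_{i'}^{v+r+t} J_{ii'}\, l_{i'}(\mathrm{A}), $$

and the weight matrix

$$ M_{kk'} = \sum_i^{v} J_{ik} J_{ik'} - \Theta_v(k)\,\delta_{kk'} $$

(outer sum over B's vibrations; $k,k'$ over A's vibrations and rotations)
is diagonalized.  Its eigenvalues $\kappa$ measure how much the zero-point
amplitude along each eigendirection differs between the isotopologues; the
eigenvectors define the difference-dedicated modes
$l^{(\Delta)}_i = \sum_k K_{ki}\, l_k(\mathrm{A})$.  The shifts follow from

$$ {}^{n}\Delta\delta_{\mathrm{harm}} = -\tfrac14\sum_k \kappa_k\,
      D^2\sigma[l_k^{(\Delta)}], \qquad
   {}^{n}\Delta R = -\tfrac14 \sum_k \kappa_k \sum_{ii'} G_{ii'}\,
      \phi(l_i^{(\Delta)};\, l_k^{(\Delta)}, l_k^{(\Delta)})\,
      l_{i'}^{(\Delta)}, \qquad
   G_{ii'} = \sum_j^{v} \frac{K_{ji} K_{ji'}}{\omega_j}, $$

and ${}^{n}\Delta\delta_{\mathrm{anh}} = -D\sigma[{}^{n}\Delta R]$.  With
every mode retained this reproduces the explicit VPT2 difference
identically; truncating at a $|\kappa|$ cutoff (default $10^{-3}$;
$10^{-2}$ and $10^{-4}$ are used contextually) keeps only a handful of
displacement directions, because for a single substitution only about three
weights are large — roughly $-1+\sqrt{\mu_A/\mu_B}$ with the local reduced
masses — and the rest decay rapidly.

Three implementation points deserve emphasis:

* **Only the $k$-sum is truncated.**  The inner $i,i'$ sums of the
  geometry-relaxation formula run over the complete $v{+}r$ basis; the
  required projections $\phi(l_i; l_k, l_k)$ come from the *same* displaced
  Hessians along the retained $k$ (the cost stays $2\,n_{\mathrm{ret}}$
  Hessian evaluations).  Truncating the inner sums as well loses the
  harmonically mediated relaxation through soft modes and degrades the
  cutoff convergence by orders of magnitude.  The anharmonic shift is then
  evaluated as a central difference of $\sigma$ along the assembled
  ${}^{n}\Delta R$ direction (two extra evaluations), which remains exact
  under truncation.
* **Rigid-mode parameterization.**  Rotational modes are angle-parameterized
  ($l_{\mathrm{rot}} = \hat n \times (r - r_{\mathrm{com}})$, bohr per
  radian): the rigid "dimensionless coordinate" is the rotation angle, the
  natural companion of the dimensionless vibrational coordinates.  With a
  unit mass-weighted norm instead, the Eckart-frame rotational admixture of
  B's vibrations acquires coefficients of order
  $\Delta m\, x\, l/\sqrt{I}$ — of order five for H/D in a small molecule —
  and $M$ grows a spurious dominating rotation-block eigenvalue.  The
  *results* are invariant to this scaling choice (the contraction
  $\sum_{kk'} M_{kk'}\, l_k \otimes l_{k'}$ is scale-free, which the tests
  assert to the finite-difference noise floor); the $\kappa$ *spectrum* is
  interpretable only in the angle parameterization.
* **Reported ${}^{n}\Delta R$ is Eckart-projected.**  The explicit
  difference $\Delta R(\mathrm{B}) - \Delta R(\mathrm{A})$ and the DD
  expression differ by a rigid-body component only: the cubic tensor
  contracted once with a rotation generator and twice with an
  isotopologue's full amplitude tensor vanishes identically, because
  per-atom mass scaling commutes with per-atom rotation generators.
  Projecting out the rigid components (with the unsubstituted masses) makes
  the two channels agree and leaves every shift unchanged, since first and
  second derivatives of a translation/rotation-invariant surface along
  exact rigid directions vanish.

### What the mass-ratio limit does and does not predict

The printed limits $-1+\sqrt{m_A/m_B}$ ($-0.2926$ for H/D, $-0.0393$ for
$^{12}$C/$^{13}$C) hold when the substituted atom moves against an
effectively infinite mass.  The package reproduces them exactly in that
limit (the `xh_heavy` fixture, frame masses $10^6$ amu, gives three weights
at $-0.29262$ to $10^{-4}$).  For light environments the weights are
diluted twice over: the local reduced mass replaces the bare isotope mass
(a $^{12}$C partner turns $-0.2926$ into $-0.266$ for the C–H stretch; four
hydrogens give a $^{13}$C substitution $-0.0098$ instead of $-0.0393$), and
for bends the Eckart rotational share of a single atom's transverse motion
— large when that atom carries an appreciable fraction of the total inertia,
as in a methane-like system — moves weight into rotation-admixed directions
(bend weights near $-0.155$).  These are properties of the physics, not of
the implementation, and they saturate for any rigid-mode scaling at or
above the angle parameterization.

A related finding concerns truncation on small, slim molecules: the
rotation-admixed directions have small $\kappa$ (of order
$(\Delta m\,x\,l/I)^2$, which only drops below $10^{-4}$ for molecules with
sizable inertia) but large shielding curvature, so the $\kappa$-ranked tail
converges non-uniformly there.  On the chain fixture these weights sit near
$3\times10^{-4}$; with the full inner sums described above their effect on
the shifts is at the 0.1-ppb level, but they are the reason a cutoff should
not be pushed below the molecule's rotation-admixture scale without care.

## The local comparators

**loc-VPT2** freezes every nucleus except the substitution site: the
$3\times3$ block of the Cartesian Hessian at the mobile atom is
mass-weighted with that atom's mass alone and diagonalized without rigid
projection; the VPT2 formulas then run with three local modes.  Harmonic
couplings among the local stretch and bends are retained.  In the
infinite-frame-mass limit loc-VPT2 equals standard VPT2 (asserted to
0.1 ppb on `xh_heavy`).

**LMZL** treats the three polar coordinates of the mobile atom about its
bonded partner — the bond length and the azimuth/altitude bending arcs — as
independent one-dimensional oscillators and solves each perturbatively
(zero-point level, cubic shift
$\Delta\langle s\rangle = -c_3/4\mu^2\omega^3$, amplitude
$\langle s^2\rangle = 1/2\mu\omega$), so its bond-length changes are
$r_g$-type averages.  Because the polar coordinates hold $r$ fixed along
the bending arcs, the separable treatment misses the centrifugal stretch of
the bond by the angular zero-point motion.  The optional correction
augments the radial potential with

$$ V_{\mathrm{cent}}(r) = \frac{\langle L^2\rangle}{2\mu r^2}, \qquad
   \langle L^2\rangle = \mu r_e^2\,
   \frac{\omega_{\mathrm{az}} + \omega_{\mathrm{alt}}}{2}, $$

the angular momentum expectation assembled from the two angular zero-point
energies; the radial constants and equilibrium response are then re-derived
from the augmented potential.  This form is the package's own derivation of
the centrifugal term (the harmonic $\langle p_s^2\rangle = \mu\omega/2$ per
bending mode, leverage $r_e^2$).  In Cartesian VPT2 the same physics enters
through the geometric cubic constant
$\phi_{yyx} = k_r/r_e + \dots - 2k_{\mathrm{ang}}/r_e^3$, and the two
routes agree at leading order; what remains is a genuine second-order
difference, measured here at 2–4 % of the shift even on a polar-separable
potential.  That margin matches the behaviour of published local-model
benchmarks and is the reason the comparison tests assert the VPT2 family to
$10^{-3}$ relative but the centrifugally corrected local model only to a
few percent.  The systematic inequality
$|\Delta r_g(\mathrm{LMZL})| \le |\Delta r_g(\mathrm{LMZL+cent})| \le
|\Delta r_g(\mathrm{loc\mbox{-}VPT2})|$ holds on every bending-coupled
fixture.

The radial oscillator uses the mobile atom's bare mass by default
(consistent with the frozen environment); the two-body reduced mass is
available behind a flag.

## Vibration-hole descriptors

For internal coordinates $f$ (distances, interior angles,
azimuth/altitude), evaluated with analytic first derivatives and
finite-difference Hessians of those analytic gradients:

$$ f_z = f(R_e + \Delta R), \qquad
   f_g = f_z + \tfrac14\sum_i^{v} l_i^{T} (\nabla^2 f)\, l_i, \qquad
   \langle\Delta f^2\rangle = \tfrac12\sum_i^{v} (Df[l_i])^2, \qquad
   \langle\Delta f\,\Delta g\rangle = \tfrac12\sum_i^{v} Df[l_i]\,Dg[l_i].$$

The $f_g$ expression is the second-order expansion of the individual
average $\langle f(R)\rangle$ with $\langle q_i^2\rangle = 1/2$; it
reproduces the classic lateral-averaging stretch
$\langle r\rangle - r_z = s^2/r_e$ for a diatomic with isotropic transverse
amplitude $s^2$ per direction, and converges to the exact grid average as
the anharmonicity shrinks.  Isotope effects come either from the explicit
difference of two isotopologue tables or from $\kappa$-weighted sums over
the difference-dedicated modes; the channels agree at cutoff 0 to $10^{-9}$
relative.  Hole-decay profiles group per-bond effects by the bond-path
distance from the substitution site (0 for the substituted bond, 1 for
geminal bonds, ...), with magnitudes plotted on a log scale and signs kept
as marker flags.

## The synthetic model systems

The fixtures stand in for ab initio surfaces: force fields are sums of
Morse bonds and low-order polynomials in internal-coordinate displacements
(always of total degree two or higher, so the stored geometry is a
stationary point by construction), and each reporting nucleus carries a
shielding surface that is a polynomial in the same internal coordinates —
hence exactly rotation- and translation-invariant, infinitely
differentiable, and analytically checkable.  Magnitudes are chosen once at
realistic scales: X–H stretches near 3000–3500 cm$^{-1}$ (Morse $D_e
\approx 0.18$ hartree, $a \approx 1.1$ bohr$^{-1}$), bends of 900–1500
cm$^{-1}$, shielding slopes of tens of ppm/bohr and curvatures of a few to
tens of ppm/bohr$^2$, which put the computed H/D shifts in the hundreds of
ppb — the range observed for such substitutions.

* `diatomic_morse` — the one-dimensional workhorse with closed-form checks.
* `xh_heavy` — a mobile H on a $10^6$ amu frame, H along the bisector of
  the two frame bonds so the azimuth/altitude frame is orthogonal and the
  potential polar-separable; the limit in which all four methods must
  coincide.  `params$c_rtt` switches on strong bending–stretch coupling.
* `water_like`, `methane_like` — bent triatomic and five-atom tetrahedral
  systems; the latter enables the multi-bond $^{12}$C/$^{13}$C substitution
  and the equivalent-bond locality checks.
* `chain_n` — an H-terminated heavy-atom gauche-helix chain (weak 1–4
  distance terms pin the torsions) for topological-distance profiles.
* `hbond_toy` — a three-center O–H$\cdots$O motif whose sign-switchable
  stretch–stretch coupling moves the hole between bond-localized and
  delocalized (donor–acceptor-distance-closing) morphologies.

A nonzero `jitter` parameter perturbs every coefficient deterministically
from the seed to generate random variants.  What the fixtures do *not*
emulate: electronic-structure noise, quartic and higher anharmonicity
beyond what the Morse bonds imply, double-well hydrogen-bond potentials,
conformational averaging, and temperature.  Passing tests therefore
demonstrate the correctness of the averaging machinery on smooth
single-minimum surfaces, not the fidelity of any electronic-structure
model.

The exact oracle is a sinc-DVR (discrete variable representation) solver:
dense-grid diagonalization in one or two dimensions, with automatic range
widening while the ground state leaks into the grid edges and grid doubling
to a $10^{-8}$ convergence target.  It verifies the harmonic and Morse
closed forms to $10^{-8}$ and anchors the VPT2 truncation-error scans: with
the Morse cubic strength scaled by $s$ at fixed harmonic curvature, the
relative error of the VPT2 bond-length correction and the error of the
shielding correction both fall as $s^2$.  The scan is run at
$s = 0.4, 0.2, 0.1$ — inside the asymptotic regime, because at $s = 1$ the
next-order ($s^3$) term partially cancels the quadratic one and corrupts a
three-point order fit.

## Numerical choices and degenerate cases

* Internal units are Hartree atomic units; reports use Å-derived length
  units, cm$^{-1}$, ppm for surfaces and ppb for shifts.
* Rigid-space separation uses analytic translation/rotation generators and
  projection, not an eigenvalue threshold; a warning fires when the lowest
  vibration comes within 1 cm$^{-1}$ of the rigid space, and saddle points
  are rejected.
* Degenerate eigenvector pairs (frequencies or $\kappa$) are fixed by a
  deterministic rotation onto the canonical Cartesian axes followed by a
  sign convention, so repeated runs are bit-identical.
* Hessians must be symmetric to $10^{-8}$ (smaller asymmetry is
  symmetrized); derivative containers carry a basis identifier and refuse
  to combine across mode sets.
* Degenerate internal coordinates (zero-length bonds, collinear angle arms,
  collinear azimuth frames) raise explicit errors.
* Problem sizes in the shipped tests — up to six atoms, 2D grids up to
  $108^2$ points — are chosen so the whole suite, including every
  cross-method comparison and oracle scan, completes in a few minutes;
  the machinery itself is dimension-agnostic.

## Known limitations

* Zero temperature only; no finite-temperature occupation or rotational
  averaging.
* Cubic anharmonicity only (no quartic contributions to geometry or
  amplitudes), and no resonance handling — strongly anharmonic or
  double-well potentials (low-barrier hydrogen bonds) are outside the
  model's validity, as the delocalized-hole fixture is designed to probe
  qualitatively, not quantitatively.
* LMZL is restricted to substitution sites with a single bond.
* The job schema stores desk-scale systems inline as YAML; there is no
  interface to electronic-structure programs, only the evaluator contract
  that such an interface would satisfy.
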