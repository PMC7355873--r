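# vibhole

Secondary isotope shifts on NMR chemical shieldings, and the "vibration
hole" behind them, from second-order vibrational perturbation theory.

## The problem

Replacing a nucleus by a heavier isotope leaves the molecular potential and
shielding surfaces unchanged but alters the zero-point vibrational motion,
and with it the vibrationally averaged shielding of every nucleus nearby.
The observed quantity is the intrinsic isotope shift

```
nΔδ = δ(B) − δ(A) = σ(A) − σ(B)
```

(A unsubstituted, B substituted, n bonds between the substitution site and
the reporting nucleus).  The region where the vibrational motif — average
geometry, mean-square amplitudes, amplitude covariances — responds to the
substitution is the *vibration hole*.  This package is for computational
spectroscopists who want to compute both at VPT2 level, compare the
standard, difference-dedicated and a-priori local routes, and test the
machinery against exact grid solutions — all on analytic model surfaces,
with no electronic-structure program required.

## What it computes

* **Standard VPT2** per isotopologue, in dimensionless normal coordinates
  (`⟨q²⟩ = 1/2`):
  `Δδ_harm = −¼ Σᵢ D²σ[lᵢ]`,
  `ΔR = −¼ Σₖ ωₖ⁻¹ Σᵢ φ_iik lₖ`,
  `Δδ_anh = −Dσ[ΔR]`; the shift is the explicit B − A difference.
* **DD-VPT2**: B's modes are expanded exactly in A's complete
  (vibration+rotation+translation) basis; the weight matrix
  `M = Jᵛᵀ Jᵛ − 1` is diagonalized, and its eigenvalues κ rank
  difference-dedicated modes `l^(Δ)`.  Shifts follow from κ-weighted sums,
  with derivative evaluations only along the retained modes (about 3 per
  substitution site); at cutoff 0 the standard result is reproduced
  identically.
* **loc-VPT2** (all atoms frozen except the substitution site) and **LMZL**
  (independent 1D oscillators in the bond/azimuth/altitude polar
  coordinates), the latter with an optional centrifugal correction
  `V_cent = ⟨L²⟩/2μr²` that restores the bond stretch driven by angular
  zero-point motion.
* **Vibration-hole descriptors**: isotope effects on r_z and r_g geometry
  parameters, harmonic mean-square amplitudes and amplitude covariances,
  and their decay profile with topological distance from the substitution
  site.
* **Oracles and fixtures**: six synthetic anharmonic model systems
  (Morse/polynomial force fields and polynomial shielding surfaces in
  internal coordinates) and a sinc-DVR grid solver for exact 1D/2D
  ground-state averages.

I/O: a versioned YAML job schema, Molden export of normal and
difference-dedicated modes, XYZ export of exaggerated `R_e + λ·ΔR`
structures, and a thin command-line front end
(`inst/cli/vibhole-cli.R run|compare|fixtures|profile`).

## Worked example

Deuterate one hydrogen of the synthetic methane-like system and compute the
shifts by DD-VPT2:

```r
library(vibhole)

fix <- make_fixture("methane_like")       # CH4-like analytic surfaces
ev  <- make_evaluators(fix)               # energy/gradient/Hessian/sigma
rep <- ddvpt2_shift(fix$system, fix$isoA, fix$isoB, ev, cutoff = 1e-3)
rep
#> # Isotope-shift report [DD-VPT2] CH4 -> CH3D
#> # A tibble: 5 x 6
#>   nucleus  atom n_bonds shift_ppb harm_ppb anh_ppb
#>   <chr>   <int>   <int>     <dbl>    <dbl>   <dbl>
#> 1 C1          1       1   -269.       39.4  -309.
#> 2 H2          2       0   -131.      -65.2   -66.2
#> 3 H3          3       2     -9.00     32.1   -41.1
#> 4 H4          4       2     -9.00     32.1   -41.1
#> 5 H5          5       2     -9.00     32.1   -41.1
attr(rep, "details")$dd
#> <dd_basis> 12 modes, 6 retained (|kappa| >= 0.001)
#> leading kappa: -0.26984, -0.15539, -0.15539, 0.00430, 0.00430
```

The substituted hydrogen (`n_bonds = 0`) moves by −131 ppb, the attached
carbon (one bond) by −269 ppb, the geminal hydrogens by −9 ppb — the
strong-to-weak decay with bond distance that isotope-shift measurements
show.  The three leading weights are the stretch (−0.270, close to the
reduced-mass limit −1+√(μ_H/μ_D) = −0.266 for a 12 amu partner) and the
two transverse modes of the substituted H.  Only 6 of 12 directions are
retained: this run cost 13 Hessian and 15 shielding evaluations, against
37 Hessian and 38 shielding evaluations for the standard route over both
isotopologues — and agrees with it to 0.15 ppb:

```r
full <- vpt2_shift(fix$system, fix$isoA, fix$isoB, make_evaluators(fix))
max(abs(rep$shift_ppb - full$shift_ppb))
#> [1] 0.1480394
```

The vibration hole behind these numbers:

```r
det <- attr(full, "details")
gA <- geometry_statistics(fix$coords, det$corrA$modes, det$corrA$dR,
                          reference = fix$coords[["r2"]])
gB <- geometry_statistics(fix$coords, det$corrB$modes, det$corrB$dR,
                          reference = fix$coords[["r2"]])
geometry_isotope_effect(gA, gB)
#> # A tibble: 4 x 7
#>   coordinate kind    f_e delta_f_z delta_f_g   delta_msa  delta_cov
#>   <chr>      <chr> <dbl>     <dbl>     <dbl>       <dbl>      <dbl>
#> 1 r(C-H2)    bond   2.06  -0.00381 -0.0111   -0.00556    -0.00556
#> 2 r(C-H3)    bond   2.06  -0.00216 -0.000316 -0.00000276 -0.0000798
#> 3 r(C-H4)    bond   2.06  -0.00216 -0.000316 -0.00000276 -0.0000798
#> 4 r(C-H5)    bond   2.06  -0.00216 -0.000316 -0.00000276 -0.0000798
```

(bohr units: the substituted bond contracts by 5.9 mÅ in its individually
averaged length `f_g`, and its mean-square amplitude drops by
1.56×10⁻³ Å² ≈ 1560 (mÅ)², while the unsubstituted bonds barely respond —
the hole is localized.)  `hole_profile()` and `autoplot()` turn such
tables into decay-versus-bond-distance plots; `write_molden()` and
`write_xyz()` export the retained modes and the exaggerated geometry
change for molecular viewers.  See `vignette("vibration-hole")` for the
model and its assumptions.

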