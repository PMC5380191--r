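---
title: "Coupled 2D torsion potentials, polarization and desk-scale folding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled 2D torsion potentials, polarization and desk-scale folding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepfold2d)
```

## The model

Additive force fields write the backbone torsion energy as independent
one-dimensional Fourier series in φ and ψ. Because the two angles are
coupled on the Ramachandran map, this package instead treats the torsion
correction as a single doubly periodic surface expanded in the full tensor
trigonometric basis,

$$E(\varphi,\psi)=\sum_{m,n=0}^{M}\big[c^{cc}_{mn}\cos m\varphi\cos n\psi
+c^{cs}_{mn}\cos m\varphi\sin n\psi
+c^{sc}_{mn}\sin m\varphi\cos n\psi
+c^{ss}_{mn}\sin m\varphi\sin n\psi\big],$$

with coefficients in kcal/mol. Terms with a zero-order sine vanish
identically, so the first row of the $sc$/$ss$ matrices and the first
column of the $cs$/$ss$ matrices are structural zeros, enforced exactly.
The input is a tabulated torsion grid — in the canonical workflow the
difference between a target total energy, the non-torsion internal terms,
and a solvation free energy (`decompose_grid()`), on a 24 × 24 lattice at
15° spacing. Atomic forces follow from the chain rule through the analytic
dihedral gradient (`dihedral_gradient()`, the standard cross-product
formulation), giving exactly zero net force and net torque by construction;
both identities are tested to 1e-10 along with agreement with central
finite differences.

### Fitting choices

* **Least squares, not FFT.** The fit (`fit_fourier()`) is ordinary least
  squares on the tensor basis. On the uniform periodic lattice the basis is
  orthogonal, so the solution coincides with the discrete transform, but the
  same code path supports non-square or partially masked grids. Robustness
  was preferred over the marginal speed of an FFT at a 576-node problem
  size.
* **Truncation order.** The aliasing bound for an n-point axis is
  `floor((n-1)/2)`; for 24 points that is `M = 11`, the default ceiling. A
  24-point axis spans 24 lattice functions while the order-11 trig basis
  spans 23 per axis, so *arbitrary* grid data is fitted in the
  least-squares sense; any surface actually lying in the basis span
  (including everything `random_coefficients()` generates) is reproduced at
  the nodes to machine precision, which is the property the tests pin down.
* **Offset convention.** `decompose_grid()` shifts the grid minimum to zero
  and records the offset; only energy differences matter downstream and the
  shift keeps the constant coefficient small.
* **Units.** Angles are degrees at every interface; derivatives are
  reported per radian because that is what the Cartesian chain rule needs.

## Hydrogen-bond polarization

When a backbone hydrogen bond forms, electron density redistributes; a
fixed-charge model misses the resulting stabilisation. The package
implements a distance-dependent charge-transfer correction: for each
detected N–H···O=C bond with donor–acceptor (N···O) distance $d$,

$$\Delta q_{N}=a_N e^{-b_N d},\qquad \Delta q_{O}=a_O e^{-b_O d},$$

applied as paired transfers (N gains what H loses; O gains what C loses),
so total charge is conserved exactly, for any bond set and any parameters.
Design decisions, since the functional form leaves them open:

* $d$ is the **heavy-atom (N···O) distance**; the geometric criteria
  (N···O ≤ 3.5 Å, N–H···O angle ≥ 120°, |Δresidue| ≥ 2) are configurable
  defaults.
* Outside the fitted range [2.5, 6.5] Å the exponential is **clamped**, not
  extrapolated.
* An atom engaged by several candidate bonds is polarized by its
  **shortest-distance partner only** (the model was parameterized on an
  isolated hydrogen-bonded pair); a bond acts only if it is the shortest
  for all four of its atoms, with deterministic tie-breaking.
* The shipped amplitudes are **unofficial placeholders** of plausible
  magnitude; `fit_exponential()` (log-linear start, Levenberg–Marquardt
  refinement via minpack.lm) recovers generating parameters from noiseless
  samples to better than 1e-6 relative and is the intended route to real
  parameter sets.

## What the samplers and generators emulate — and what they do not

Real folding studies behind this kind of force-field work use hundreds of
nanoseconds of replica-exchange MD and microseconds of direct MD of real
peptides in implicit solvent. Those budgets (and an MM engine) are out of
scope here. The package replaces them with two deliberately small, exactly
checkable stand-ins:

* **Metropolis MC in (φ, ψ)** (`metropolis_mc()`): joint uniform angular
  proposals with periodic wrap and the standard acceptance rule, exercising
  the same torsion surfaces the fitting module produces. On quadrature
  solvable surfaces the sampled marginals match Boltzmann integrals within
  Monte-Carlo error (3% on the variance at 10^6 steps is the acceptance
  bar); detailed balance is verified empirically on a coarse partition.
* **Replica-exchange MC** (`replica_exchange_mc()`): one walker per ladder
  temperature, neighbour swaps with acceptance
  $\min(1,e^{(\beta_i-\beta_j)(E_i-E_j)})$, alternating even/odd pairing,
  per-pair statistics recorded. The two 12-replica ladders used in the
  helix (267–577 K) and hairpin (255–597 K) folding studies ship as the
  presets `"2i9m"` and `"trpzip2"`.
* **Two-state ensemble generator** (`synth_two_state_ensemble()`): i.i.d.
  draws from a solvable system — unique folded state at energy 0,
  g-degenerate unfolded state at ΔE, folded probability
  $1/(1+g e^{-\Delta E/k_BT})$. Defaults in the tests are ΔE = 2 kcal/mol
  and g = 30, which place the folded/unfolded crossing at
  $\Delta E/(k_B\ln g)=295.9$ K, conveniently inside both ladders.

Because the generators produce independent draws on exactly solvable
models, a passing test demonstrates the *estimators* (WHAM, Cv, landscape
code) are correct — it says nothing about force-field accuracy on real
peptides, conformational autocorrelation, or solvation. No statistical
inefficiency correction is applied (samples are i.i.d. by construction);
the flag is reserved for future autocorrelated input.

## WHAM, specific heat and the melting temperature

`wham_solve()` implements binned temperature-WHAM over the density of
states (200 bins over the pooled energy range ± 1%, tolerance 1e-7 on
max|Δf|, 10^5 iteration cap, f₁ ≡ 0, with an internal energy shift for
numerical stability that cancels in all observables). Reweighting to an
arbitrary temperature uses the per-sample denominators
$\sum_j N_j e^{f_j-\beta_j E_s}$, which are temperature independent and
computed once. Free-energy surfaces are $-k_BT\ln P$ with empty bins
masked and the occupied minimum shifted to zero;
`specific_heat_curve()` evaluates $C_v(T)=(\langle E^2\rangle_T-\langle
E\rangle_T^2)/k_BT^2$ on a 1 K scan and takes the argmax as the melting
temperature, ties broken toward the lowest temperature.

One subtlety deserves emphasis. For the discrete two-state system the
temperature at which the folded fraction crosses ½ is
$T_{1/2}=\Delta E/(k_B\ln g)$, but the specific-heat peak is **not** at
$T_{1/2}$: $C_v\propto p(1-p)/T^2$, and the $1/T^2$ factor pulls the
maximum down — for ΔE = 2, g = 30 the exact peak (from the closed-form
$C_v$, `two_state_cv_peak()`) sits at 229.5 K, fully 66 K below
$T_{1/2}$; the two coincide only in the sharp-transition limit
$\ln g\to\infty$. The thermodynamic tests therefore validate the WHAM
pipeline against the exact $C_v$ peak (recovered within 5 K at
5 × 10^4 samples/replica) and the free-energy gap against
$\Delta F=\Delta E-k_BT\ln g$ (within 0.05 kcal/mol).

## Structural model and analysis conventions

* `build_ideal_peptide()` constructs chains by internal coordinates (NeRF)
  with fixed standard geometry (bond lengths/angles collected in
  `backbone_geometry`), ω fixed at 180°, and reproduces requested (φ, ψ)
  exactly; it is bit-deterministic. Atom indices are **1-based**
  throughout, matching both R convention and PDB numbering. Hydrogens are
  limited to the amide H and HA; side chains are a CB pseudo-atom, plus an
  indole-centroid pseudo-atom (`IND`) on tryptophan so stacking distances
  are defined. For structures read from full PDB files the indole centroid
  falls back to the mean of the ring heavy atoms.
* Terminal residues lacking one of φ/ψ contribute no torsion term (a
  coupled 2D map needs both angles); ACE/NME caps supply the missing atoms
  when present. Proline exclusion from the 2D term is available as a flag,
  and one coefficient set is shared by all residues.
* Reaction coordinates: the collective hydrogen-bond distance `d` is the
  **arithmetic mean** of the native-pair N···O distances (max and rms are
  options — any norm serves as a reaction coordinate; the mean is the most
  interpretable). The stacking distance `l` is the mean of indole-centroid
  distances over the configured pairs; the default pairing for a
  12-residue tryptophan zipper follows the published coordinate definition
  verbatim (2–11 and 4–11) even though the native stacking partners are
  arguably 2–11/4–9 — the definition is implemented as written and the
  pairs are overridable rather than silently "corrected".
* Ramachandran regions are ordered rectangles with first-match priority
  and `other` as fallback; the shipped boxes (alpha φ∈[−100,−30],
  ψ∈[−67,−7]; PPII φ∈[−110,−50], ψ∈[120,180]; beta φ∈[−180,−90],
  ψ∈[90,180]∪[−180,−150], plus a tightened alpha option) are configurable
  stand-ins — the exact literature boundaries are not published with the
  method, so tests pin behaviour to the configured values, not to the
  literature.
* Karplus coefficients default to the widely used HN–HA set
  (A = 7.09, B = −1.42, C = 1.55 Hz, θ = φ − 60°) and are plain
  configuration.
* Clustering featurizes frames as superposed selection coordinates and
  delegates to `stats::kmeans` (10 seeded starts); the reported centroid
  of each cluster is the member frame closest to the cluster mean, and
  populations sum to one exactly.

## Numerical choices and degenerate inputs

* k_B = 0.0019872041 kcal/(mol K), defined once.
* Dihedrals are undefined for collinear bonded triples; the geometry
  routines raise an error (cross-product norm < 1e-10) rather than
  returning NaN, because silent NaNs poison samplers.
* Degenerate WHAM inputs: a constant-energy ensemble gets an artificially
  widened single-bin range and yields Cv ≡ 0; disconnected histograms
  trigger an overlap warning (their relative shifts are indeterminate).
* Problem sizes in the shipped tests — 10^5–10^6 MC steps, 5 × 10^4
  samples per replica over 12 temperatures, 100-conformation force
  checks — were chosen as the smallest sizes at which the stochastic
  tolerances above are comfortably resolved.

## Known limitations

The sampler works directly in dihedral space: there are no nonbonded
terms, no solvent, and no Cartesian dynamics, so quantities that depend on
excluded volume or solvation (real compactness distributions, barrier
heights) are outside what the toolkit can claim. The polarization module
applies per-snapshot charge updates only, and ships placeholder
amplitudes. Residue-specific coefficient sets are not provided — one
surface applies to all residues, with proline optionally exempted.
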