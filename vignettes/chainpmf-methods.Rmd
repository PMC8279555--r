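---
title: "Free-energy landscapes of confined alkane chains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy landscapes of confined alkane chains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainpmf)
```

## The scientific problem

Medium-length n-alkanes (C11-C22) confined in a sealed deep-cavity
cavitand dimer trade conformational entropy against packing: a chain that
fits the roughly 13 Å long, prolate-ellipsoidal interior when extended
must fold into hairpin or chicane motifs once it outgrows the cavity.  The
quantity that organises this physics is the potential of mean force (PMF)
along the end-to-end distance `r_ee` between the terminal carbons,
`G(r_ee) = -kT ln P(r_ee)`, together with its decomposition into enthalpic
and entropic parts.

`chainpmf` implements the complete analysis chain on a coarse-grained,
desk-scale chain-in-cavity model: umbrella-sampled Monte Carlo along
`r_ee`, WHAM reconstruction of the PMF, replica exchange over a
temperature ladder, a constant-heat-capacity fit yielding `H(r)` and
`-TS(r)`, dihedral principal component analysis (DPCA) for
dominant-conformer extraction, and the geometric diagnostics (all-trans
lengths, gauche content, van der Waals volumes, packing fractions) used to
interpret the landscapes.  Every stage is validated against an exactly
enumerable rotational-isomeric-state (RIS) chain.

## The chain model

A chain of `n` carbons is built from internal coordinates: C-C bonds of
1.53 Å and C-C-C angles of 112.7° (typical alkane values, both
configurable), with the `n - 3` backbone dihedrals as the degrees of
freedom (IUPAC sign convention, trans = 180°).  The closed-form all-trans
length is `m·p` for an even number of bonds `m` and
`sqrt((m·p)² + q²)` for odd `m`, with `p = l·sin(θ/2)`,
`q = l·cos(θ/2)`; for C11 this gives 12.74 Å.

The coarse-grained potential has three terms:

* **Torsion.**  A cosine polynomial `Σ c_k cos^k(φ - 180°)` with the
  classic Ryckaert-Bellemans butane coefficients as defaults: trans is the
  global minimum at 0, the gauche states sit 2.93 kJ/mol higher, and the
  trans-gauche barrier is 12.3 kJ/mol — the literature-typical range for
  alkane backbones.  All six coefficients are configurable.
* **Intramolecular Lennard-Jones.**  One united-atom site per carbon
  (ε = 0.40 kJ/mol, σ = 3.95 Å, close to common united-atom CH2
  parameters), with pairs separated by three or fewer bonds excluded and
  no 1-4 scaling.  This term supplies the ring-closure attraction at
  short `r_ee`.  Hydrogens are materialised only for volume calculations,
  at tetrahedral positions with C-H = 1.09 Å.
* **Confinement.**  The sealed dimer interior is modelled as a soft
  prolate ellipsoid: a site at scaled radius
  `s = sqrt((x² + y²)/a² + z²/c²)` pays `k_w·max(0, s - 1)²`.  Defaults
  `a = 4 Å` (an 8 Å wide pocket) and `c = 6.5 Å` (13 Å total interior
  length) reproduce the host geometry; `k_w = 50 kJ/mol` makes the wall
  stiff but differentiable.  The host interior shape is not published as
  a functional form, so the soft ellipsoid is an explicit modelling
  choice of this package.

Before the wall term is evaluated, the conformation is centred on its
centroid and its principal gyration axis is rotated onto the cavity axis.
This encodes the guest's freedom to translate and orient inside the host
without adding rigid-body degrees of freedom to the sampler; the energy
is a deterministic function of the dihedrals, so the sampled distribution
is exactly Boltzmann for the composite energy.

## Sampling

Every observable here is an equilibrium average, so any ergodic canonical
sampler gives the same answer; where all-atom studies of this system
integrate molecular dynamics, `chainpmf` deliberately uses Metropolis
Monte Carlo in torsion space: moves perturb one dihedral by up
to 30° (80 % of moves) or redraw one dihedral uniformly — a torsion-space
pivot that rotates the whole tail (20 %).  MC step counts are therefore
calibrated by acceptance and autocorrelation rather than by nanoseconds
of simulated time; the defaults (2 000-10 000
equilibration, 10 000+ production steps per window) run a full PMF in
seconds, and the heavier validation runs used in the tests
(10^5-10^6 steps per window) still complete in minutes on one CPU.

Umbrella windows apply `½ k (r_ee - r0)²` with `k = 50 kJ/(mol Å²)` and
centres evenly spaced by 0.5 Å (0.32 Å for replica-exchange runs),
spanning terminal contact to full extension.  Windows are visited from
the extended end inwards, each warm-started from its predecessor.
Replica exchange runs one replica per ladder temperature — the default
ten-temperature ladder spans 298.15 K to 500 K — and attempts a swap
between a random adjacent pair every 200 steps with the standard
acceptance `min(1, exp((β_i - β_j)(E_i - E_j)))`.

## WHAM

Per-window histograms of `r_ee` (0.1 Å bins by default) are combined by
self-consistent iteration of

```
P(r) ∝ Σ_i n_i(r) / Σ_i N_i exp(β(F_i - U_i(r))),
exp(-β F_i) = Σ_r P(r) exp(-β U_i(r)),
```

in log space, until the largest change in any window free energy is below
10⁻⁶ kJ/mol (at most 10⁵ iterations).  Two numerical choices matter:

* Bias energies are evaluated at the *per-bin mean coordinate* of the
  samples rather than the bin centre.  For smooth densities this is a
  second-order refinement; for the discrete RIS oracle, whose `r_ee`
  values form spikes inside bins, it removes a systematic error of
  several tenths of kT.
* Bins with zero aggregate counts are reported as `NA`, never
  interpolated, and the window-overlap graph must be connected — a
  disconnected schedule is an error naming the components, since relative
  free energies between components are undefined.

Uncertainties come from a Bayesian bootstrap over windows (Dirichlet
weights, 50 resamples by default).  The returned PMF is anchored so its minimum is exactly zero.

## Enthalpy/entropy decomposition

Multi-temperature PMFs are fitted, bin by bin and by ordinary (optionally
uncertainty-weighted) least squares, to the constant-heat-capacity form

```
G(T, r) = A(r) + B(r)(T - T0) + C(r)·T·ln(T/T0),    T0 = 298.15 K,
```

the general solution of `∂Cp/∂T = 0`.  The identities
`G(T0) = A`, `H(T0) = A - (B + C)T0`, `-T0·S(T0) = (B + C)T0` and
`G = H - TS` at every temperature hold exactly by construction, and
`dH/dT = -C` is the (temperature-independent) heat capacity.  A quadratic
extension term fitted to data generated by this model comes back at zero,
so the three-term family is closed under its own assumption.

Two gauge subtleties are worth recording.  First, PMFs are defined up to
a per-temperature additive constant; min-anchoring each PMF before the
fit (mirroring the normalisation used when the landscapes are plotted)
injects a temperature-dependent gauge into `A` that cancels in profile
*shapes* but not in absolute values.  When the fit is compared against
exact temperature derivatives (as the test suite does with the RIS
oracle), both surfaces are therefore put in a common gauge by subtracting
the value at a fixed reference bin — the all-trans bin, which contains a
single chain state.  Second, adding a constant to the surface at a single
temperature shifts every bin's fitted `C` by the same amount: the heat
capacity *profile shape* is gauge-robust even though its absolute level
is not, and the suite asserts exactly that property.

Error amplification is intrinsic to this fit: `H(T0)` is the
Gibbs-Helmholtz intercept `G(T0) - T0·G'(T0)`, and exact error
propagation over the ten-temperature ladder gives
`sd(H) ≈ 6.6 × sd(G)`.  The property tests check that the estimator
attains this analytic bound; consumers should expect enthalpy profiles to
be an order of magnitude noisier than the free energies they derive from.

## DPCA and motif assignment

Dihedrals are embedded as `(cos φ, sin φ)` pairs to remove angular
periodicity, the (weighted) covariance matrix is diagonalised, and frames
are projected on the two leading eigenvectors (signs fixed so the
largest-magnitude loading is positive).  The dominant conformation is the
frame closest to the mode of a 50×50 histogram of the projections —
a direct reading of "maximum in probability"; kernel density estimation
was considered and rejected as an extra smoothing parameter with no
qualitative effect on well-separated clusters.  Ties break to the lowest
frame index.

Motif labels are assigned from the built geometry: direction vectors over
successive 3-bond segments are projected on the chain's principal axis,
and a *turn* is a sign reversal persisting for at least two segments.
Zero turns is *linear*, one is *hairpin*, two or more is *chicane*.  The
extended and helical families are deliberately not distinguished — they
are not thermodynamically distinct basins in this system.  These rules
are this package's own operationalisation of motif assignment that is
otherwise done by visual inspection; the thresholds (3-bond segments, 2-segment
persistence, and the reported `r_ee` consistency checks at 0.75 and 0.5
of the all-trans length) are exposed as arguments and validated only on
constructed fixtures.

## The RIS oracle

The ground-truth generator is a rotational-isomeric-state chain: each of
`m ≤ 12` dihedrals takes states {180°, +60°, -60°}, a gauche state costs
`ε_g = 2.9 kJ/mol`, and adjacent g+g-/g-g+ pairs (the pentane effect)
cost `ε_pent = 8 kJ/mol` more (or are excluded outright).  All `3^m`
states are enumerated in compiled code, giving exact `G(T, r)` surfaces,
trans fractions and RMS end-to-end distances at any temperature.  A
discrete-state Metropolis sampler on the same model (with optional
umbrella biases) closes the loop: sampler + WHAM is validated against
enumeration to < 0.1 kT RMSE, and the full WHAM + Gibbs-Helmholtz
pipeline to < 0.2 kJ/mol RMS in `H` and `-TS`.

What the synthetic models do **not** emulate: continuous torsional
vibrations within RIS states, solvent (free-chain landscapes in water
are close to their vacuum counterparts, but unsealed-complex physics in
solution is not reproduced here), host flexibility, electrostatics, and
the spinning-top motif that requires a host opening.  Tests passing on
these models certify the estimators and the pipeline plumbing, not
all-atom energetics.

## Geometric diagnostics

Van der Waals volumes are Monte Carlo integrals of the union of atomic
spheres (Bondi radii, C 1.70 Å / H 1.20 Å) over the bounding box, with
binomial standard errors; 10⁶ points give ±0.7 Å³ on C20H42.  The
all-atom all-trans C20 volume comes out at 346 Å³, consistent with the
accepted ~350 Å³ Bondi volume of eicosane, and dividing by the 740 Å³
interior of the sealed cavitand dimer
gives packing fractions of 0.468, 0.490 and 0.514 for C20-C22.  The
packing fraction at which hard spheres freeze (0.49) is the interpretive
anchor: chains at or above it are packing-frustrated.

## Problem sizes and reproducibility

The bundled validation runs use: 12-28 umbrella windows per chain,
10⁴-1.2×10⁶ production steps per window, ten ladder temperatures,
10⁶-point volume integrals, and RIS chains of 5-6 dihedrals (243-729
states).  These sizes were chosen so each estimator's statistical error
sits comfortably below the tolerance being asserted (e.g. the per-bin
WHAM error at 2×10⁴ samples per window is ≈ 0.02-0.03 kT against a
0.05 kT assertion) — the binomial/block-average error models in the test
helpers document the calculation.  Every stochastic function takes a
seed; identical seeds give bit-identical histograms, configurations and
output files.

## Known limitations

* The confinement term is a smooth stand-in for a molecular cavity; wall
  softness and the principal-axis placement rule are modelling choices,
  and no host-guest atomistic energetics are included.
* Quantitative reproduction of the reference all-atom landscapes
  (basin gaps in kJ/mol, minimum positions to 0.1 Å) is out of scope by
  design; the package reproduces the geometric observables quantitatively
  and the confinement physics qualitatively.
* WHAM assumes uncorrelated samples within windows; autocorrelation
  inflates the bootstrap errors' optimism.  Block-averaged standard
  errors are used wherever means are compared.
* MBAR-style per-sample reweighting is intentionally not the primary
  estimator; the histogram-based WHAM is the primary method, and an
  independent naive implementation serves as its cross-check in the
  test suite.
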