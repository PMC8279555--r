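# chainpmf

Free-energy landscapes of n-alkane chains, free or confined in a
prolate-ellipsoidal host cavity, from umbrella-sampled Monte Carlo.

## What this package is for

Medium-length alkanes (C11–C22) encapsulated in a sealed deep-cavity
cavitand dimer fold against the cavity walls: a chain that fits when
extended must adopt hairpin or chicane motifs once it outgrows the
roughly 13 Å interior.  The central object is the potential of mean force
(PMF) along the end-to-end distance between the terminal carbons,

    G(r_ee) = -kT ln P(r_ee),

and its decomposition into enthalpy and entropy via the
constant-heat-capacity Gibbs–Helmholtz form

    G(T, r) = A(r) + B(r) (T - T0) + C(r) T ln(T/T0),     T0 = 298.15 K,

so that `H(T0) = A - (B + C) T0` and `-T0 S(T0) = (B + C) T0`.

The package provides, as composable functions:

* a chain builder (internal coordinates → Cartesian, optional all-atom
  hydrogens) and geometric observables: end-to-end distance, closed-form
  all-trans lengths, trans/gauche classification, RMS end-to-end
  distances, union-of-spheres van der Waals volumes, packing fractions;
* a coarse-grained chain potential (Ryckaert–Bellemans torsions,
  united-atom Lennard-Jones, soft prolate-ellipsoid confinement,
  harmonic umbrella bias) with a compiled Metropolis sampler in torsion
  space, umbrella-window orchestration and replica exchange over a
  ten-temperature ladder (298.15–500 K);
* a WHAM solver with convergence diagnostics, overlap-graph checking and
  Bayesian-bootstrap uncertainties;
* per-bin Gibbs–Helmholtz fitting returning G, H and -TS profiles;
* dihedral principal component analysis (cos/sin embedding) with
  dominant-conformer extraction and linear/hairpin/chicane motif
  classification;
* exactly enumerable rotational-isomeric-state (RIS) chains that serve
  as ground truth for every pipeline stage;
* plain-text I/O (XYZ, metadata-headed TSV/CSV, YAML configs) and a CLI
  (`run_cli()`, wrapped by `inst/scripts/chainpmf`).

## Worked example

Compute the vacuum end-to-end PMF of n-undecane (C11) at 298.15 K from
19 umbrella windows, and the packing diagnostics of n-eicosane (C20):

```r
library(chainpmf)

top  <- chain_topology(11)                      # C-C 1.53 A, CCC 112.7 deg
all_trans_length(top)
#> [1] 12.7363

sch  <- window_schedule(seq(4, 13.2, by = 0.5), k = 50,
                        equilibration = 5000, production = 40000)
hist <- run_umbrella_windows(top, schedule = sch, mc = mc_config(seed = 1))
pmf  <- align_pmf(wham_solve(hist))
pmf
#> pmf_profile: 94/140 populated bins on [1.55, 15.45] A, T = 298.15 K
#>   minimum 0.000 kJ/mol at r = 11.05 A (2003 WHAM iterations, max|dF| = 9.99e-07)

find_minima(pmf, prominence = 1)
#>       r    G prominence
#> 1 11.05 0.00        Inf
#> 2 12.65 2.41      4.889
```

The primary minimum sits at 11.05 Å, below the 12.74 Å all-trans length:
even though all-trans has the lowest energy, the chain entropically
favours a minority gauche population, leaving the extended conformation
as a secondary minimum near 12.6 Å.

```r
conf <- build_cartesian(chain_topology(20, with_hydrogens = TRUE), rep(180, 17))
v    <- vdw_volume(conf, bondi_radii(), n_points = 1e6, seed = 1)
sprintf("C20H42 vdW volume: %.1f +/- %.1f A^3", v$volume, v$stderr)
#> [1] "C20H42 vdW volume: 344.0 +/- 0.7 A^3"
packing_fraction(v, 740)    # 740 A^3 = sealed dimer interior
#> [1] 0.465
```

A packing fraction near 0.47 — at the hard-sphere freezing value of
0.49 — signals the onset of packing frustration for C20 and longer
chains.  Confined runs add `wall = cavity_wall()` (an 8 Å wide, 13 Å
long soft ellipsoid); multi-temperature decomposition chains
`run_remd_umbrella()` into `decompose_pmf_pipeline()`; DPCA on saved
window frames runs through `top2_pca()` / `dominant_conformation()` /
`classify_motif()`.

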