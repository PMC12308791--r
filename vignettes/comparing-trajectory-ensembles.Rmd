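---
title: "Comparing trajectory ensembles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing trajectory ensembles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajcomp)
```

## The comparative procedure

`trajcomp` addresses one recurring analysis design: a wild-type protein
complex and one or more point variants are each simulated in several
independent replicas, and the question is whether the variants shift a
set of ensemble observables in a consistent direction — typically whether
a detachable region loses grip on the rest of the complex. The pipeline
(`run_comparison()`) executes a fixed stage order per system:

1. **pool** — drop a per-replica equilibration span, concatenate the
   remainder (`pool_equilibrated()`);
2. **superpose** — iterated-mean Kabsch fit (`superpose()`);
3. **interface** — per-frame heavy-atom contact count and buried area for
   one configured region pair, plus optional hydrogen-bond occupancies;
4. **fluctuations** — distance-fluctuation matrix and NDF profile;
5. **correlation** — dynamic cross-correlation matrix (DCCM);
6. **essential dynamics** — PCA of the positional covariance;

and then derives every wild-type-relative quantity: percent changes of
the interface means, per-residue ΔNDF with per-region summaries and a
three-way classification, pairwise similarity of the variants'
difference-DCCMs, and per-system top-*k* variance with region
involvement.

The underlying assumptions are the usual ones for ensemble comparison:
frames are treated as exchangeable draws (time structure is used only for
equilibration trimming and replica bookkeeping), the systems share a
residue-level correspondence (same chains and numbering), and differences
of ensemble means are meaningful because each system is sampled long
enough that the mean is stable. The package quantifies the last point,
when replicas are available, with a replica-block bootstrap (each replica
is one block, 1000 resamples by default) rather than asserting
significance: how error bars on such means should be computed is not
standardised, so the report carries percentile intervals and leaves
significance labels to the user.

## Observables and parameters

| parameter | default | unit | why |
|---|---|---|---|
| contact cutoff | 5.0 | Å | conventional heavy-atom contact criterion for interface contact counts |
| vdW contact cutoff | 4.5 | Å | stricter display cutoff for per-residue shortest-contact lists |
| H-bond distance / angle | 3.5 / 150 | Å / ° | field-standard geometric criterion (donor–acceptor distance, D–H···A angle) |
| heavy-only H-bond distance | 3.0 | Å | distance-only fallback for hydrogen-free topologies |
| SASA probe / points | 1.4 / 960 | Å / – | water-sized probe; golden-spiral sampling with ≥960 points keeps single-sphere error below 0.5 % |
| NDF classification threshold | 0.1 | – | separates small \|ΔNDF\| from meaningful disorder/stiffening shifts |
| PCA components *k* | 3 | – | leading collective motions |
| equilibration discard | 0 (config) | ns | dataset-specific; a typical choice for 2 μs replicas is 500 ns |

All are exposed in `comparison_config()`; the element radius table
(C 1.70, N 1.55, O 1.52, S 1.80 Å, default 1.70 for pseudo-atoms) is
fixed in the package so areas are stable across releases.

**Interface area.** "Interfacial area" is operationalised as half the
solvent-accessible surface buried on complex formation,
`(SASA(a) + SASA(b) − SASA(a∪b))/2`, the standard choice when a single
number per frame is wanted. Note that the partition is by *region*
membership, not chain identity: if the detachable region is part of one
chain, contacts between that region and the remainder of its own chain
count toward the interface. Percent changes are computed on ensemble
means, not per frame, matching how such changes are usually reported.

**NDF.** The distance-fluctuation matrix is
`DF_ij = ⟨d_ij²⟩ − ⟨d_ij⟩²` over pooled frames, with one representative
atom per residue (Cα by default, first heavy atom as fallback). The
per-residue score is the row mean over the global off-diagonal mean:

`NDF_i = mean_{j≠i}(DF_ij) / mean_{i<j}(DF_ij)`

This normalisation is a documented package decision: the
distance-fluctuation literature contains several variants (global-mean,
median, per-domain), and the global mean makes the score dimensionless
with residue-mean exactly 1, so ΔNDF values of a few tenths are directly
interpretable. A median-based normalisation is available
(`ndf_profile(..., normalization = "median")`). Each system is normalised
within itself before differencing, since the score is relative to each
system's own average flexibility. Whether to compute NDF over the whole
complex or per subunit is also open; the default is the whole complex,
with `region` arguments for restriction.

A consequence of the normalisation worth knowing: adding a large new
source of distance variance anywhere (for instance a region that hops
between attached and detached poses) inflates the global denominator and
deflates every other residue's NDF. Disorder comparisons are therefore
most interpretable between systems whose global fluctuation budgets are
similar; the detachment generator's constant-offset mode (fraction 1,
small displacement) exists precisely to weaken an interface without
injecting such bimodal variance.

**DCCM, similarity, PCA.** The DCCM uses isotropic dot-product
correlations of Cα displacements about the ensemble mean. Difference
matrices (variant − WT) are compared by cosine and Spearman correlation
over the strict upper triangle only — the diagonal is identically zero
and the lower triangle is redundant, so including them would double-count
or bias both scores; Spearman uses average ranks on ties. PCA
diagonalises the 3N×3N covariance; "total motion" is its trace, so
variance fractions sum to 1 by construction. Region involvement is the
eigenvalue-weighted squared-eigenvector mass on the region's coordinates,
`Σ_m λ_m s_m / Σ_m λ_m` over the top *k* modes — one of several
defensible definitions (an unweighted per-mode average is available via
`weighted = FALSE`); the weighted form is the default because it reduces
to the intuitive answer when one mode dominates. Involvements of any
residue partition sum to 1 for every *k*.

## Numerical choices

- **Superposition** fits Cα atoms of the configured fit region onto an
  iteratively refined mean structure (2 passes, first frame as the
  initial reference); rotations use SVD with determinant correction, so
  reflections are never introduced. Fewer than 3 fit atoms or a collinear
  reference is an error.
- **Eigenvector signs** are fixed (largest-magnitude component positive)
  so PCA output is reproducible across BLAS implementations; numerically
  negative eigenvalues of rank-deficient covariances are clipped at zero
  and retained.
- **Zero-variance residues** in the DCCM get zero off-diagonal entries
  (diagonal 1) with a warning rather than NaNs.
- **Empty selections** in contact counting warn and return 0, so batch
  scans over all chain pairs never abort; an all-zero difference matrix
  is an error for similarity (undefined), as is a single-frame ensemble
  for any variance-based quantity and an all-zero DF matrix for NDF.
- **Degenerate recipe covariances** (jointly infeasible correlation
  blocks) are repaired by clipping negative eigenvalues at zero; the
  recipe records a `repaired` flag and warns.
- **Determinism**: every sampler is a pure function of its recipe (seeded
  locally, caller RNG state untouched); reports are written with full
  float precision, so identical configurations give byte-identical
  `report.json`.
- The contact counter uses a cell-list grid but is contractually equal to
  the all-pairs answer (verified against a brute-force oracle in the
  tests); the Shrake–Rupley sampler uses a deterministic golden-spiral
  point set.

## The synthetic generator: what it does and does not emulate

`make_toy_complex()` lays out Cα chains as parallel 3.8 Å-spaced curves
(one shared backbone wiggle plus small per-chain perturbation, so
inter-chain interfaces exist at any seed), optionally decorated with
backbone N/C/O and a sidechain pseudo-atom. `ensemble_recipe()` +
`sample_gaussian_ensemble()` draw residue displacements from a zero-mean
multivariate Gaussian with programmable per-residue variance and
region-block correlations, applied independently per Cartesian axis and
rigidly per residue. `sample_detachment_ensemble()` rigidly displaces a
mobile region along the interface normal in a seeded fraction of frames;
`sample_hbond_series()` toggles an N–H···O triad between a geometry that
satisfies the bond criterion (2.9 Å, 170°) and one that violates the
distance (6 Å), with exact (shuffled) or Bernoulli occupancy.

These ensembles provide exact ground truth for correlation recovery,
occupancy, interface weakening and disorder contrasts, which is what the
test suite exercises. They are *statistical* stand-ins, not physics: no
force field, no solvent, no anisotropic or time-correlated motion, no
secondary structure, no unfolding, and Gaussian (unimodal) fluctuations
except for the explicit detachment mode. Passing tests therefore
demonstrate that the analysis code measures what it claims on data whose
truth is known — not that any particular biological system behaves
accordingly.

## Problem sizes used by the tests

Unit tests run on toys of 2–40 residues with 10–5000 frames. The
sampling-accuracy tests use the sizes at which their tolerances were
derived: correlation recovery ±0.05 at 5000 frames, dominant-mode
variance ±0.03 and scale-invariance ±0.05 at 8000 frames. The end-to-end
sign-recovery test runs 20 seed pairs of a 500-residue, 5-chain complex
at 2000 frames per system, with the interface weakened by a constant
0.2 Å pull (≈20 % contact loss on this geometry) and a 31-residue region
at 3× base variance; interface areas there are computed every 20th frame
with 256 sphere points, which leaves the mean estimate far more precise
than the effect being detected. `scripts/acceptance.R` reruns the same
conditions once per invocation seed.

## Known limitations

- Trajectory input is limited to multi-model PDB, DCD and multi-frame
  GRO; compressed XDR formats (XTC/TRR) are not read — convert upstream.
- No periodic-boundary handling: frames must contain whole molecules.
- No solvent or energetic scoring; interfaces are geometric.
- NDF cross-system comparability degrades when global fluctuation
  budgets differ strongly (see above).
- DCCM/PCA convergence is the user's responsibility; the package reports
  what the pooled frames contain and exposes replica labels so
  convergence can be probed by splitting.
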