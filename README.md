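# trajcomp

Comparative analysis of molecular-dynamics trajectory ensembles for
wild-type-versus-variant studies of protein complexes.

When a point mutation is suspected of destabilising one region of a
multi-subunit assembly — for example, a detachable activation domain held
against the rest of a regulatory complex — the question is rarely answered
by a single observable. Practitioners compare, between the wild-type and
each variant ensemble: how much interface is buried and how many atomic
contacts hold it; which hydrogen bonds survive and how often; whether
individual residues fluctuate more against the rest of the structure; and
whether the complex's collective motions change. `trajcomp` packages that
comparative workflow for R users (computational structural biologists and
biophysicists), together with a synthetic-ensemble generator that provides
exact ground truth for validating every stage.

## What it computes

For two residue sets *a*, *b* and pooled frames:

- **Contacts** `Nc = |{(i,j) : d_ij <= 5 Å}|` over heavy atoms, and the
  **buried interface area** `(SASA(a) + SASA(b) − SASA(a ∪ b)) / 2`
  (Shrake–Rupley sphere sampling, probe 1.4 Å). Variant effects are
  reported as percent change of the ensemble means,
  `100 (x_var − x_wt) / x_wt`.
- **Hydrogen-bond occupancy**: fraction of frames with donor–acceptor
  distance ≤ 3.5 Å and D–H···A angle ≥ 150°.
- **Shortest van der Waals contacts** between residue pairs (minimum
  inter-atomic distance over frames, ≤ 4.5 Å).
- **Distance fluctuations** `DF_ij = ⟨d_ij²⟩ − ⟨d_ij⟩²` and the
  **normalized distance fluctuation score**
  `NDF_i = mean_{j≠i}(DF_ij) / mean_{i<j}(DF_ij)`, whose per-residue
  variant-minus-wild-type difference ΔNDF_i classifies residues as
  increased disorder (> 0.1), stiffened (< −0.1) or unchanged.
- **Dynamic cross-correlation**
  `C_ij = ⟨Δr_i·Δr_j⟩ / sqrt(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)`, variant − WT
  difference matrices, and their pairwise cosine / Spearman similarity
  over the strict upper triangle.
- **Essential dynamics**: eigendecomposition of the 3N×3N positional
  covariance; top-k variance fractions and the eigenvalue-weighted
  fraction of the leading motion carried by a named region
  (`Σ_m λ_m s_m(region) / Σ_m λ_m`, with `s_m` the squared eigenvector
  mass on the region).

Trajectories are read from multi-model PDB, DCD or multi-frame GRO files
(or generated synthetically), pooled after discarding a per-replica
equilibration span, and superposed by iterated-mean Kabsch fitting before
any displacement-based analysis.

## Worked example

A two-chain toy complex; the variant has its detachable chain pulled
0.3 Å off the interface and fluctuating three times harder:

```r
library(trajcomp)
top  <- make_toy_complex(list(c("A", 40), c("B", 40)), seed = 1)
acr  <- region_chain(top, "A", name = "detachable")
rest <- region_chain(top, "B", name = "rest")

wt_rec  <- ensemble_recipe(top, base_variance = 0.4, n_frames = 1000, seed = 10)
mut_rec <- detachment_recipe(
  ensemble_recipe(top, base_variance = 0.4, n_frames = 1000, seed = 11,
                  variance_overrides = list(list(acr, 1.2))),
  acr, separation_fraction = 1.0, displacement = 0.3)

cfg <- comparison_config(
  systems   = list(wt = list(recipe = wt_rec), mut = list(recipe = mut_rec)),
  wt        = "wt",
  regions   = list(detachable = acr, rest = rest),
  interface = c("detachable", "rest"),
  bootstrap = 0, sasa_points = 480, area_stride = 10)

rep <- run_comparison(cfg)
```

which logs each stage and prints:

```
[contacts] wt: Nc 12.5, area 318.8 A^2
[contacts] mut: Nc 11.9, area 273.2 A^2
dNc   = -4.8%
dArea = -14.3%
      region n_residues   mean    min    max
1 detachable         40  0.241  0.154  0.316
2       rest         40 -0.241 -0.295 -0.165
detachable-region involvement: wt 50.0%, mut 95.9%
```

The variant loses contacts and buried area at the programmed interface
(negative ΔNc and Δarea); every residue of the noisier detachable region
shows positive ΔNDF (mean +0.24, classified increased disorder above the
0.1 threshold); and the leading principal components of the variant are
carried almost entirely by that region. `comparison_config(...,
output_dir = )` additionally writes `report.json` and CSV tables; reruns
with the same configuration are byte-identical.

A thin command-line wrapper is installed at `inst/cli/compare.R`
(`compare.R run config.yaml`, `compare.R interfaces config.yaml`,
`compare.R fixtures recipe.yaml outdir`).

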