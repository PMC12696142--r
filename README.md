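# fwtract

Free-water-corrected tractometry of peritumoral white matter.

## The problem

Diffuse gliomas alter white matter far beyond their radiologically visible
margins. Conventional DTI metrics are confounded there by vasogenic edema:
the isotropic free-water signal dilutes fractional anisotropy (FA) and
inflates mean diffusivity (MD), so "damage" and "water" are conflated.
`fwtract` implements an analysis pipeline that separates the two and then
quantifies how tract microstructure changes with distance from the tumor:

1. **Free-water elimination (FWE).** Each voxel's single-shell diffusion
   signal is modeled as a two-compartment mixture,

   S_i = S0 [ (1 − f) · exp(−b g_iᵀ D g_i) + f · exp(−b d_iso) ],

   with tissue tensor D, free-water fraction f ∈ [0, 1], and fixed
   d_iso = 3.0 × 10⁻³ mm²/s. The fit minimizes the squared signal residual
   plus a spatial-continuity penalty λ · Σ‖∇f‖², yielding FW-FA, FW-MD and
   FWF maps. Because a single shell cannot separate f from a uniform
   eigenvalue shift of D, the tissue mean diffusivity is capped at a
   plausible white-matter value (0.7 × 10⁻³ mm²/s by default), which makes
   the decomposition identifiable.
2. **Tractometry.** Each bundle is resampled to 100 equidistant nodes;
   node values are trilinear samples of the metric maps averaged over
   streamlines, and each node's tumor involvement is the fraction of its
   streamline points inside the enhancing / necrotic / edema compartments
   of the segmentation. A node is *involved* when that fraction exceeds a
   threshold (default 5%, strict).
3. **Hemispheric asymmetry beyond the margins.** At nodes with < 5%
   combined involvement, homologous nodes are paired across hemispheres
   and the directional percent asymmetry

   A(%) = (ipsilateral − contralateral) / ((ipsilateral + contralateral)/2) × 100

   is averaged tract-then-subject (whole-tract), and within along-tract
   distance segments from the tumor margin (1–5, 6–10, 11–15, 16–20, ≥21
   nodes).
4. **Inference.** Kruskal–Wallis omnibus and pairwise Mann–Whitney tests
   across pathology groups (glioblastoma, astrocytoma, oligodendroglioma),
   dummy-coded linear/logistic regressions (glioblastoma reference), a
   Shapiro–Wilk normality screen, Spearman correlation of FWF with edema
   involvement, and Benjamini–Hochberg FDR stratified by test family.

A synthetic phantom-cohort generator (nested ellipsoidal tumor
compartments, mirror-image bilateral bundles, bi-tensor DWI signals with
Rician noise, pathology-specific asymmetry gradients that decay with
distance from the margin) makes the whole pipeline testable without any
imaging download. Real data enter through NIfTI volumes, TRK/TCK
streamline bundles, FSL gradient tables, or precomputed long-format
profile CSVs.

## Worked example

```r
library(fwtract)
library(dplyr)

cfg <- cohort_config(n_subjects = c(glioblastoma = 4, astrocytoma = 4,
                                    oligodendroglioma = 4), seed = 42)
cp  <- cohort_profiles(cfg)                 # generate + profile 12 subjects
res <- analyze_cohort(cp$profiles, cp$subjects, threshold = 5)

res$distance_asymmetry |>
  filter(metric == "fw_fa", !is.na(asymmetry)) |>
  group_by(pathology, segment) |>
  summarise(mean_asym = round(mean(asymmetry), 2), .groups = "drop") |>
  tidyr::pivot_wider(names_from = segment, values_from = mean_asym)
#>           pathology   1-5  6-10 11-15 16-20  >=21
#> 1       astrocytoma -2.10 -1.50 -0.82 -0.44 -0.12
#> 2      glioblastoma -4.31 -3.04 -1.66 -0.89 -0.25
#> 3 oligodendroglioma  4.00  2.82  1.54  0.83  0.20
```

Mean FW-FA asymmetry is negative near the margin for glioblastoma and
astrocytoma (lower anisotropy on the tumor side), positive for
oligodendroglioma (relatively preserved tissue), and every group's effect
decays toward zero with distance — the peritumoral gradient the pipeline
exists to resolve. The pairwise group tests on whole-tract asymmetry
(`res$asymmetry_pairwise`) carry family-stratified q-values:

```r
res$asymmetry_pairwise |> filter(metric == "fw_fa") |> select(group1, group2, p, q)
#>         group1            group2     p     q
#> 1  astrocytoma      glioblastoma 0.029 0.029
#> 2  astrocytoma oligodendroglioma 0.029 0.029
#> 3 glioblastoma oligodendroglioma 0.029 0.029
```

and the per-subject Spearman correlation between FWF node values and edema
involvement (`res$fwf_edema`) ranges 0.73–0.94 in this cohort, confirming
that the injected free water is where the edema is.

`plot_distance_asymmetry(res$distance_asymmetry)` draws the standard
grouped-bar figure (group means ± SEM per segment, faceted by metric);
`autoplot(fit)` shows a fitted FWF slice.

A thin CLI wrapper over the same functions lives in `inst/cli/fwtract.R`:

```sh
Rscript inst/cli/fwtract.R all --seed 1 --out ws
Rscript inst/cli/fwtract.R analyze --threshold 5 --sweep 1:15 --out ws
```

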