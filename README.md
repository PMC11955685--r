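# conngrad

Structural connectome gradient analysis with group inference and
transcriptomic association, in R.

## The problem

Diffusion-MRI tractography summarizes a brain as a parcels × parcels
structural connectome. Gradient mapping compresses that high-dimensional
object into a few continuous spatial axes — *gradients* — that order
regions by the similarity of their connectivity profiles: an affinity
matrix `A` (cosine similarity of connectome rows) is embedded with
anisotropic diffusion maps,

```
W' = D^(-α) A D^(-α),   P = D'^(-1) W',   α = 0.5, t = 0,
```

and the leading non-trivial eigenvectors of `P` (scaled by `λ/(1−λ)`)
are the gradients, ordered by explained variance `λ² / Σλ²`. To compare
groups, each subject's gradients are aligned to a group template (the
embedding of the mean connectome) by orthogonal Procrustes — the rotation
`S` minimizing `‖GS − M‖²_F`, no scaling — and the first three aligned
gradients are tested with a multivariate general linear model: Hotelling's
T² for the group contrast with age and sex as covariates, exact F
reference, Benjamini–Hochberg FDR across networks or regions. Subcortical
involvement is measured by *subcortical-weighted gradients* (a structure's
cortical connectivity profile times each gradient, averaged to a degree
value per structure and gradient). Finally, the spatial pattern of the
group difference is linked to a regions × genes expression matrix by
single-response PLS regression with spin-permutation significance testing,
2000-resample bootstrap Z scores per gene, and signed FDR-selected gene
sets.

The package is aimed at connectome researchers who want this chain as
tested, reusable functions rather than a one-off collection of scripts.
Because the real inputs (clinical diffusion-MRI cohorts, donor microarray
atlases) are large and access-restricted, the package ships a
synthetic-cohort generator with known injected effects, so every stage has
a parameter-recovery test and the whole pipeline can be exercised offline.

## Worked example

Simulate a 60-region cohort of 15 + 15 subjects with a +40% within-network
connectivity increase confined to the somatomotor (Smn) network in the
patient group, embed, align, and test at the network level:

```r
library(conngrad)

co <- simulate_cohort(sim_params(n_regions = 60, n_subjects_per_group = 15, seed = 7))
vols <- co$region_table$volume[co$region_table$is_cortical]
conn <- lapply(co$connectomes, volume_scale, volumes = vols)

template <- build_template(conn, co$region_table)
template
#> gradient_set: 60 regions x 10 components (alpha=0.5, t=0)
#> explained variance: 41.8% 32.1% 18.3% 4.1% 1.3% 0.3% 0.2% 0.2% 0.1% 0.1%

aligned <- align_cohort(conn, template)
nets <- rownames(network_average(aligned[[1]]$coordinates[, 1:3], co$region_table))
ns <- vapply(aligned, function(g) network_average(g$coordinates[, 1:3], co$region_table),
             matrix(0, length(nets), 3))
arr <- aperm(ns, c(3, 1, 2)); dimnames(arr)[[2]] <- nets

stats <- compare_multivariate(arr, design_matrix(co$manifest), family = "7 networks")
stats[order(-stats$statistic), ]
#>  unit statistic        p        q significant
#>   Smn     73.63 3.50e-07 2.45e-06        TRUE
#>   Van     11.75 2.76e-02 7.01e-02       FALSE
#>   Lim     11.34 3.12e-02 7.01e-02       FALSE
#>   Fpn      9.98 4.70e-02 7.01e-02       FALSE
#>   Dan      9.78 5.01e-02 7.01e-02       FALSE
#>   Dmn      6.14 1.58e-01 1.85e-01       FALSE
#>   Vis      2.61 5.05e-01 5.05e-01       FALSE
```

The first three gradients carry ~92% of the template variance, and the
perturbed network is recovered as the only FDR-significant network-level
result (T² = 73.6, q = 2.4e-06): the injected shift in somatomotor
connectivity moved that network's position in gradient space, and the
multivariate test localizes it correctly while the unperturbed networks
stay at chance.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the reference
synthetic cohort, each stage reading only the previous stage's written
artifacts (restartable; all outputs under `results/`):

| script | stage |
|---|---|
| `01_simulate.R` | write the synthetic cohort + ground truth |
| `02_gradients.R` | template, explained variance, aligned gradients |
| `03_group_differences.R` | network/region multivariate + univariate stat maps |
| `04_subcortical.R` | subcortical-weighted gradient degrees and comparison |
| `05_transcriptomics.R` | PLS, spin tests, bootstrap Z, gene sets |
| `06_calibration.R` | type-I error, spin calibration, recovery summary |

`run_pipeline(pipeline_config(...), out_dir)` performs the same chain in
one call with a JSON manifest of parameters, per-stage seeds and artifact
hashes; reruns with the same config are bit-identical.

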