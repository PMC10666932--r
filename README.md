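# chalign

Searchlight connectivity hyperalignment (CHA) for predicting
individualized category-selective cortical topographies from responses to
naturalistic stimuli.

Category-selective areas (faces, bodies, scenes, objects) sit in roughly
the same place in everyone's brain, but their precise conformation is
idiosyncratic, which is why they are traditionally mapped with a
subject-specific functional localizer scan. `chalign` implements the
alternative: collect movie-viewing fMRI and localizer data in a normative
sample, and for a new participant collect only movie data — possibly a
*different* movie. Functional alignment of fine-grained connectomes then
projects the normative localizer data into the new participant's cortical
anatomy, and averaging the projected contrast maps yields that person's
individualized topography without scanning a localizer.

## The method

All data live on a shared spherical cortical mesh (a subdivided
icosahedron; order *k* has 10·4^k + 2 vertices per hemisphere, 642 at
order 3, 2562 at order 4, 10,242 at order 5). For each subject and
hemisphere, every cortical vertex (seed) gets a **connectivity profile**:
its Pearson correlations with whole-brain connectivity targets — coarse
grid vertices whose time series are averaged over 13 mm searchlights —
computed from run-wise z-scored movie data and row-normalized.

For an ordered subject pair (source → target), every 15 mm searchlight
contributes an orthogonal Procrustes rotation

  R̂ = argmin‖R A − B‖_F  over orthogonal R,  R̂ = U Vᵀ where B Aᵀ = U Σ Vᵀ,

where the rows of A and B are the two subjects' profile rows for the
searchlight's vertices. The per-searchlight rotations are aggregated by
block summation into one sparse vertex-space transformation matrix per
hemisphere; the per-vertex scale this introduces is absorbed by re-z-
scoring after application. Transforms are pairwise and directional — no
common model space is built.

An iterative coarse-to-fine schedule refines the fit: the transform is
applied to the source movie, profiles are recomputed against denser target
grids, and new transforms are fitted (canonically six steps: order-3
targets with 13 mm averaging three times, order-4 with 7 mm twice, then
every vertex as its own target). Because connectivity profiles do not
require time-locked stimuli, source and target connectomes may come from
*different movies* (cross-movie CHA). The time-locked baseline, response
hyperalignment (RHA), uses movie response patterns
(timepoints × vertices) in place of profiles and requires identical
stimuli.

Predictions are scored against each subject's own localizer topography
(mean across runs of unthresholded GLM t maps, target category vs. all
others) with whole-map and searchlight Pearson correlations, with
Cronbach's alpha across runs as the noise ceiling, and with Fisher-z
paired comparisons between methods. A synthetic multi-subject cohort
generator (shared latent movie signals, smooth spatial loadings, planted
block-orthogonal misalignments, two movies sharing connectivity structure,
block-design localizers) makes the whole pipeline testable without any
downloads.

## Worked example

```r
library(chalign)

cohort <- make_cohort(n_subjects = 4, master_seed = 7)
cohort
#> <cohort_bundle> 4 subjects, order-3 meshes (1284 vertices, 1210 cortical), 2 movies x 300 tp, 4 localizer runs

fit_all <- function(method) {
  chains <- lapply(cohort$subject_ids, fit_chains_to_target,
                   cohort = cohort, method = method)
  names(chains) <- cohort$subject_ids
  score_predictions(cohort, chains, method = toupper(method))
}
records <- dplyr::bind_rows(fit_all("cha"), fit_all("aa"))
report <- evaluation_report(records)
report
#> <evaluation_report> 40 records, 10 method x category cells
#> # A tibble: 10 × 6
#>    method category      n mean_r    se_r mean_alpha
#>    <chr>  <chr>     <int>  <dbl>   <dbl>      <dbl>
#>  1 AA     bodies        4  0.635 0.00799      0.995
#>  2 AA     faces         4  0.632 0.0150       0.993
#>  3 AA     objects       4  0.621 0.0215       0.996
#>  4 AA     scenes        4  0.597 0.0250       0.995
#>  5 AA     scrambled     4  0.658 0.00329      0.995
#>  6 CHA    bodies        4  0.865 0.00234      0.995
#>  7 CHA    faces         4  0.865 0.00506      0.993
#>  8 CHA    objects       4  0.855 0.00734      0.996
#>  9 CHA    scenes        4  0.839 0.00241      0.995
#> 10 CHA    scrambled     4  0.851 0.00324      0.995
```

Each record is one target subject × category: `map_r` is the correlation
between the topography predicted from the *other* subjects' localizer
data and the subject's own-localizer topography; `mean_alpha` is the
across-run reliability (noise ceiling). CHA markedly beats the
anatomical-alignment (AA) baseline in every category, and the Fisher-z
paired comparisons in `report$comparisons` are significant after
Bonferroni correction:

```r
report$comparisons[, c("method_a", "method_b", "category", "mean_z_diff", "p_adjusted")]
#>   method_a method_b  category mean_z_diff   p_adjusted
#> 1      CHA       AA     faces   0.5679559 0.0004951981
#> 2      CHA       AA    bodies   0.5625512 0.0001941858
#> 3      CHA       AA    scenes   0.5266519 0.0027073383
#> 4      CHA       AA   objects   0.5470546 0.0004873606
#> 5      CHA       AA scrambled   0.4718361 0.0003861746
```

Cross-movie prediction only changes the target connectome:
`fit_chains_to_target(cohort, id, method = "cha", source_movie = "A",
target_movie = "B")`. `autoplot(report)` draws the method × category bar
chart with alpha ticks; `plot_contrast_map()` renders any per-vertex map.

## Command line

A thin `exec/chalign` Rscript chains the pipeline:

```sh
chalign simulate --out-dir run1 --seed 9
chalign align    --out-dir run1 --method cha --steps 1
chalign predict  --out-dir run1 --baseline-aa
chalign evaluate --out-dir run1     # writes report.tsv + summary.json
```

Exit codes: 0 success, 2 configuration error (e.g. `--method rha
--cross-movie A:B`, which violates RHA's same-stimulus requirement),
1 runtime error.

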