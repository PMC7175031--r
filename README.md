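# cicaemd

Group-level resting-state fMRI analysis with constrained ICA and
data-driven references from bidimensional ensemble empirical mode
decomposition.

## The problem

Spatial ICA is the workhorse for extracting resting-state networks (RSNs)
from fMRI, but its permutation and sign indeterminacies make single-subject
decompositions incomparable across a cohort: the "same" network appears in
a different row, with arbitrary polarity, for every subject. `cicaemd`
implements a hybrid workflow that solves this without any external atlas or
stimulus model:

1. **Preprocess & reduce.** Per subject, mask, linearly detrend and
   standardize voxel time series, and project onto the `M` leading PCs:
   `X_M = U_M' X`.
2. **Decompose.** Slice the `M` reduced component images transversely and
   decompose each slice into bidimensional intrinsic mode functions (BIMFs)
   `I(x,y) = Σ_j b_j(x,y)` with a noise-assisted ensemble sifting scheme
   whose envelopes are Green's-function-in-tension interpolants
   (`g(r) = K0(pr) + log(pr)`, `p = sqrt(T/(1−T))`; tension decreasing by
   `1/J` per mode from `T₁ = 0.9`).
3. **Match & average.** Stack a low-frequency mode combination into an
   `M × L` matrix per subject, match rows across subjects with the
   Hungarian algorithm on the `1 − ρ` cost, and merge them with an
   incremental mean into `M` standardized group reference maps.
4. **Constrain.** Estimate each subject's demixing matrix `W` (`Y = W X_M`)
   by a constrained, decoupled extended-Infomax ICA: maximize
   `E{log p(w_m' x)} + log|d_m' w_m|` subject to
   `ς − ϵ(y_m, r_m) ≤ 0`, handled by an augmented Lagrangian
   `(max{0, γh_m + μ_m}² − μ_m²)/2γ` with `μ_m ← max{0, μ_m + γ h_m}`
   (defaults `η = 0.5`, `γ = 3`).
5. **Evaluate.** Cross-subject consistency per component,
   `K_per(y_m) = (1/S) Σ_s ρ(y_m^(s), ⟨y⟩_m)`, one-sample t-maps
   (`p < 0.001`, one-tailed, `t = 4.30` at `df = 9`), and display
   thresholding.

The similarity threshold `ς` is the user-facing dial: raising it trades
subject-specific detail for cross-subject consistency, and `K_per` rises
monotonically along the sweep `ς ∈ {0.4, 0.5, 0.6, 0.7}`.

## Worked example

A synthetic three-subject cohort with two planted networks, run through
the complete pipeline at two thresholds:

```r
library(cicaemd)

ds  <- generate_group_dataset(grid = c(16L, 16L, 4L), n_subjects = 3,
                              n_timepoints = 40, n_sources = 2, seed = 42)
res <- run_pipeline(ds$subjects,
                    config = synthetic_study_config(seed = 42, n_components = 2,
                                                    thresholds = c(0.4, 0.6)))
print(res)
#> <pipeline_result> 3 subject(s), M = 2 components, thresholds: 0.4, 0.6
#>   threshold 0.4: mean K_per = 0.911
#>   threshold 0.6: mean K_per = 0.911

print(res$consistency[["0.6"]])
#> <consistency_report> threshold = 0.6
#>   K_per: 0.942 0.879
```

`K_per` close to 1 means every subject's component map is nearly a copy of
the group mean network. Because the data are synthetic, recovery of the
planted truth can be measured directly — each entry is the matched absolute
correlation between one subject's extracted component and that subject's
ground-truth network:

```r
rec <- source_recovery(res, ds$truth)
round(rec[["0.6"]]$rho, 2)
#>      [,1] [,2]
#> [1,] 0.95 0.85
#> [2,] 0.93 0.93
#> [3,] 0.87 0.74

round(critical_t(0.001, 9), 2)
#> [1] 4.3
```

For real data, pass NIfTI paths instead of simulated series and keep the
defaults (`M = 20`, 5 discarded frames, 5 mm smoothing, reference
combination `b5 + b6`):

```r
res <- run_pipeline(c("sub01.nii.gz", "sub02.nii.gz"),
                    config = list(thresholds = 0.5),
                    out_dir = "run01")   # writes references, CSVs, manifest
```

A thin command-line front end lives in `inst/cli/cicaemd.R`
(`simulate` and `run` subcommands, YAML config).

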