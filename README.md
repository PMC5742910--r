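# brainentropy

Image-based brain entropy (BEN) quantifies the complexity of rendered brain
activation maps. Resting-state fMRI studies of attention deficit
hyperactivity disorder (ADHD) have reported that patients show *lower*
entropy — more regular, less complex activity — in visual (occipital) areas
than healthy controls. `brainentropy` implements that analysis end to end
for anyone working with exported ICA component overlays: it segments each
overlay image into five colour classes, discards background and red artifact
signals, computes the Shannon entropy of the retained pixel intensities, and
runs the standard two-group statistical battery. A seeded synthetic-image
generator makes the whole pipeline testable and demonstrable without any
imaging data.

## The measure

For one component image, pixels are classified by nearest reference colour
(Euclidean distance in RGB) into **background, white, grey, blue
(activation), red (artifact)**. White/grey/blue pixels are retained, red and
background are excluded, and the retained pixels are mapped to 8-bit
grayscale (BT.601 luminance). With `p_i` the fraction of retained pixels at
intensity `i` (256 bins),

```
BEN_bits = − Σ_{i=1}^{256} p_i · log2(p_i)          ∈ [0, 8] bits
BEN      = BEN_bits / log2(256)                     ∈ [0, 1]
```

BEN is 0 when all retained pixels share one intensity and 1 for a perfectly
uniform intensity distribution. A subject's BEN is the mean over their two
closely matched sequential component images. Groups are then compared with a
pooled two-sample t-test (BEN), Mann–Whitney U with tie-corrected normal
approximation (age), Pearson chi-squared without continuity correction and
the phi coefficient (gender × group), and the point-biserial BEN–group
correlation.

## Worked example

```r
library(brainentropy)

# one synthetic component map and its entropy
img <- generate_component_map(map_gen_config(seed = 42))
image_ben(img)
#> <ben_result> 5.3660 bits, BEN = 0.6708 (2556 pixels)

# a full synthetic study: 25 ADHD (BEN target 0.56 ± 0.14) vs 19 controls
# (0.64 ± 0.11), two images per subject
cohort <- generate_cohort(cohort_gen_config(seed = 1))
res <- analyze_cohort(cohort)
build_table1(res)
#> Comparison of group characteristics
#>                              ADHD (n = 25)    Control (n = 19)     Z/chi2        p
#> Age                          35.216 ± 6.330  31.326 ± 7.339       1.931    0.053
#> Gender (male/female)         20/5             8/11                  6.699    0.010
#> Brain entropy (BEN)          0.581 ± 0.137   0.645 ± 0.103       -1.647    0.099
#> BEN-group correlation r = -0.252 (p = 0.099); gender-group phi = -0.390 (p = 0.009)
```

The first line says the seeded map's 2556 retained pixels carry 5.37 bits of
intensity entropy, i.e. BEN ≈ 0.67 of the 8-bit maximum. In the group table,
the gender × group chi-squared (6.699) and phi (−0.390) are exact because the
generator reproduces the configured 20/5 vs 8/11 gender counts; the BEN means
scatter around their 0.56 / 0.64 targets with the configured between-subject
spread, so the t-test p-value varies from seed to seed — at these group sizes
the test's power is only ≈ 0.52.

Real data can be analysed the same way from a directory containing
`subjects.csv` (`subject_id,group,age,gender,image_1,image_2`) and the
referenced PNG overlays:

```r
run_pipeline(run_config(mode = "from-images", input = "my_study/",
                        outdir = "my_study_results/"))
```

or from the shell via the driver script:

```sh
Rscript inst/cli/ben-pipeline.R generate --outdir demo --seed 7
Rscript inst/cli/ben-pipeline.R analyze --mode from-images --input demo --outdir demo_results
```

Every run writes per-image and per-subject BEN tables, the group-comparison
report (CSV, JSON and plain text), label-map audit images on request, and its
fully resolved configuration for reproducibility.

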