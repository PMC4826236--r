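# chromtex

Quantifying chemotherapy-induced chromatin remodelling from
fluorescence microscopy.

DNA-damaging treatment (platinum drugs, irradiation) condenses
chromatin: DAPI-stained nuclei shift from a smooth, homogeneous
interior to a clumped, heterogeneous one. `chromtex` measures that
shift for cell-biology and translational labs working with nuclear
texture, DNA-damage foci and tissue-microarray (TMA)
immunofluorescence:

* **Nuclear texture** — per-nucleus grey-level co-occurrence matrices
  (GLCM) and the five Haralick statistics
  ASM $= \sum p(i,j)^2$,
  contrast $= \sum (i-j)^2 p(i,j)$,
  correlation $= \sum (i-\mu_x)(j-\mu_y)p(i,j)/(\sigma_x\sigma_y)$,
  IDM $= \sum p(i,j)/(1+(i-j)^2)$, and
  entropy $= -\sum p \log_2 p$ (bits), with per-sample averaging,
  treated-vs-control percent change and a chromatin-pattern call
  (homogeneity / heterogeneity / contrast).
* **Foci counting** — Laplacian-of-Gaussian detection of punctate
  nuclear foci (e.g. γH2AX) per segmented nucleus, with the
  "more than five foci per cell" positivity cut-point.
* **Compartment scoring** — mean target intensity within
  cytokeratin-defined cytoplasmic and DAPI-defined nuclear
  compartments of TMA cores, excluding cores with < 5% epithelium.
* **Group statistics** — exact (enumeration-equivalent) and
  normal-approximation two-tailed Mann-Whitney U, and pooled-variance
  t-tests, per texture parameter.
* **Synthetic scenes** — a generator for all three image classes with
  complete ground truth (nucleus masks, focus coordinates, compartment
  labels), used to validate every stage.

## Worked example

Simulate a control and a treated sample, segment, profile texture and
interpret the change:

```r
library(chromtex)

control <- generate_texture_scene(scene_spec(texture_regime = "control", seed = 1))
treated <- generate_texture_scene(scene_spec(texture_regime = "treated", seed = 2))

prof_c <- nucleus_texture_profile(control$channels$dapi,
                                  segment_nuclei(control$channels$dapi))
prof_t <- nucleus_texture_profile(treated$channels$dapi,
                                  segment_nuclei(treated$channels$dapi))
prof_c
#> <texture_profile> 12 nuclei (0 with undefined correlation)
#>         asm    contrast correlation         idm     entropy
#>      0.0614      1.0365      0.7333      0.6576      4.3977

pct <- percent_change(prof_t$sample_means, prof_c$sample_means)
round(pct, 1)
#>         asm    contrast correlation         idm     entropy
#>       -63.0       522.6       -10.8       -17.9        38.1

interpret_chromatin_pattern(pct)
#> <pattern_call> homogeneity: decreased, heterogeneity: increased, contrast: increased
```

ASM, correlation and IDM fall while entropy and contrast rise — the
directional signature of damage-induced chromatin condensation: the
treated nucleus is less uniform (lower ASM/IDM), more disordered
(higher entropy) and shows stronger local grey-level contrast. The
pattern call condenses the five changes into the three conventional
chromatin-pattern directions.

Foci counting against ground truth:

```r
sc <- generate_foci_scene(foci_scene_spec(seed = 3, foci_per_nucleus = c(0L, 12L)))
detect_foci(sc$channels$foci, sc$truth_nuclei)
#> <foci_result> 8 nuclei, 52 foci, 62.5% positive (> 5 foci)
```

Cells with more than five foci are scored positive; up to five foci
count as negative background.

An end-to-end run (simulate two arms → segment → texture → compare) is
driven by a YAML config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "chromtex"),
             output_dir = "demo_out")
```

writing per-nucleus and per-sample CSVs, percent-change and
pattern-call JSON, Mann-Whitney comparisons and a provenance manifest.
Reruns with the same config and seed are byte-identical.

## Documentation

The methods vignette
(`vignettes/chromatin-texture-methods.Rmd`) describes the texture
model and its numerical conventions, what the synthetic scenes emulate
(and what they deliberately do not), and the design decisions behind
the defaults.
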