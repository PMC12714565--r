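# eploopr

Annotation of chromatin loops as enhancer–promoter (EP) interactions from
histone-mark and accessibility peak tracks, for regulatory genomics in
zebrafish and other vertebrates.

Distal enhancers regulate genes across tens to hundreds of kilobases through
chromatin loops, but a loop call by itself says nothing about what its two
anchors are. `eploopr` integrates three epigenomic signals to classify
accessible regions and then annotates Hi-C loops against them:

- **promoter**: an accessible region carrying all three signals —
  ATAC-seq ∩ H3K4me3 ∩ H3K27ac;
- **enhancer**: an accessible region carrying ATAC-seq ∩ H3K27ac but
  **lacking** H3K4me3;
- **EP-loop**: a chromatin loop whose anchors connect an enhancer and a
  promoter (one on each anchor).

Peaks enter the classification only if −log10(P) > 5 (strictly). Every loop
receives exactly one category by the precedence EP > PP > EE > PN/EN > NN,
with midpoint-to-midpoint anchor distances, and EP vs non-EP counts are
summarized per chromosome. Typical downstream use is picking candidate
enhancers for CRISPRi perturbation, so the package also implements the
surrounding bookkeeping of such a screen:

- bridge-linker splitting of chimeric Hi-C reads (Hamming search, configurable
  linker, 20-bp fragment floor);
- the CRISPRi sgRNA selection rule: perfect on-target, efficiency strictly
  > 60, then lexicographic minimization of the off-target counts
  (MM0, MM1, MM2, MM3), within the −50 bp … +400 bp TSS window (inclusive);
- quantification formulas: 2^−ΔΔCt relative expression, survival rate,
  hemoglobin index (stain-positive pixels / yolk-sac pixels from thresholded
  RGB masks), and the pairwise Bonferroni threshold P = 2α / (k(k−1));
- a seeded synthetic-data generator that emits every input with planted
  ground truth, so the whole pipeline is testable without downloads.

All user-facing functions take and return tibbles; fitted results support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a toy genome (2 chromosomes × 1 Mb, 10 promoters, 10 enhancers,
decoy sites, 35 loops), then run the filter → classify → call chain:

```r
library(eploopr)

cfg <- sim_config(seed = 42)
sim <- simulate_inputs(cfg)

elements <- classify_elements(
  filter_peaks(sim$tracks$atac),
  filter_peaks(sim$tracks$h3k4me3),
  filter_peaks(sim$tracks$h3k27ac)
)
calls <- call_ep_loops(sim$loops$loops, elements)
calls
#> EP-loop annotation: 35 loops, 10 EP (10 promoters, 10 enhancers)

glance(calls)
#> # A tibble: 1 × 8
#>    n_EP  n_PP  n_EE  n_PN  n_EN  n_NN n_loops median_ep_distance_bp
#> 1    10     5     5     5     0    10      35                170000

summarize_by_chromosome(calls)
#> # A tibble: 2 × 4
#>   chrom  n_ep n_non_ep n_total
#> 1 chr1      5       13      18
#> 2 chr2      5       12      17
```

All 10 planted EP loops are recovered and none of the 25 decoy loops (EE, PP,
PN, NN) is mis-called; the per-chromosome totals sum to the 35 input loops.
`autoplot(calls)` draws the stacked EP/non-EP bar chart per chromosome.
`run_ep_pipeline()` wraps the same chain around files on disk and writes
`elements.bed`, `eploops.bedpe`, `annotation.tsv`, `summary.tsv` and a
provenance manifest.

The quantification formulas behave the same way:

```r
pairwise_alpha(0.05, k = 5)
#> [1] 0.005

ctg <- generate_ct_table(cfg)   # planted knockdowns of 20/50/80%
tidy(relative_expression(ctg$ct, "sgCtrl"))
#> # A tibble: 4 × 6
#>   group      n mean_fold sem_fold mean_delta_delta_ct is_calibrator
#> 1 kd20       9     0.803  0.0147                0.319 FALSE
#> 2 kd50       9     0.501  0.0101                1.000 FALSE
#> 3 kd80       9     0.193  0.00455               2.38  FALSE
#> 4 sgCtrl     9     1.00   0.0236                0     TRUE
```

The recovered mean folds (0.80, 0.50, 0.19) match the planted fold changes
(0.8, 0.5, 0.2) to within the Ct noise, and the calibrator sits at fold 1.

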