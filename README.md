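# contrastPeaks

Unsupervised, replicate-aware peak calling for ATAC-seq coverage data.

ATAC-seq reads pile up where chromatin is open, and "peaks" — intervals of
significantly enriched fragment coverage — are the substrate of most
downstream chromatin analyses. Single-sample statistical callers produce
many false positives, supervised deep learners need labels that rarely
exist, and biological replicates are usually consulted only after calling.
`contrastPeaks` treats replicates as the supervision: the same genomic
segment observed in two replicates is a positive pair for contrastive
learning, any two different segments are negatives. The package is aimed
at epigenomics analysts with multi-replicate ATAC-seq (or similar
coverage-based assays such as ChIP-seq or CUT&RUN) and no usable truth
labels.

## Method at a glance

1. **Candidate selection.** Per-base fragment coverage per replicate
   (`bedtools genomecov -pc` semantics). Positions with coverage `> t` in
   *all* R replicates (default `t`: per chromosome, the minimum across
   replicates of the median coverage over non-zero positions) are merged
   when within 90 bp and kept when longer than 100 bp, giving candidate
   regions. Fixed-length segments (`alpha` = 1000 bp) are centred on
   region midpoints, or on high-coverage clusters (≥ 0.95 within-region
   coverage quantile) for long regions; blacklist-overlapping segments are
   removed.
2. **Representation learning.** Per-base coverage vectors `m_ri`
   (segment *i*, replicate *r*) are embedded by a dilated-convolution
   ResNet encoder, `x_ri = e(m_ri)`, with a 2-class softmax head
   `q_ri = g(x_ri)` and a symmetric decoder. Training jointly minimises
   `L = l1 + l2 + l3`:
   * `l1` — cross-replicate contrastive loss over cosine similarities
     (temperature τ₁ = 0.5): same segment across replicates attracts,
     other segments repel;
   * `l2` — class contrastive loss over per-replicate class-probability
     profiles `p_rk` (τ₂ = 0.5): replicate class assignments agree and
     differ from their complements;
   * `l3` — mean squared reconstruction error (denoised coverage).
   Adam, learning rate 1e-4, 25 epochs, batch 256 segments.
3. **Calling.** ξ_ri = peak-class probability of segment *i* in replicate
   *r*; a candidate region's score is the mean ξ over its segments and
   all replicates, and it is called a peak when the score ≥ 0.5.

Evaluation helpers transfer call scores to labeled regions by
overlap-weighted averaging, compute precision/recall/F1 and PR curves
with trapezoidal PRAUC, and quantify how label noise contaminates
observed recall.

## Worked example

Simulated study conditions: 200 kb toy genome, 2 replicates, 100 planted
peaks (300–800 bp) at 8× enrichment over negative-binomial background.

```r
library(contrastPeaks)

fx   <- simulateFixture(seed = 42)           # tracks + planted truth
segs <- prepareSegments(fx$tracks, t = "median")
segs
#> PeakSegments object
#>   candidate regions: 96
#>   segments:          96 (alpha = 1000 bp)
#>   replicates:        2 (rep1, rep2)
#>   thresholds:        chr1=2, chr2=2

fit   <- trainModel(contrastModel(seed = 42), segs, epochs = 25, seed = 42)
#> peak class resolved to softmax column 1 (no substantial class split; ...)
peaks <- callPeaks(fit, segs, cutoff = 0.5, outBed = "peaks.bed")
sum(peaks$isPeak)
#> [1] 96
fixtureTruthMetrics(peaks[peaks$isPeak], fx$truth)
#> $precision [1] 1     $recall [1] 1     $f1 [1] 1
head(lossHistory(fit), 3)
#>   epoch       l1          l2       l3    total
#> 1     1 3.372487 -0.04810604 9.942489 13.26687
#> 2     2 3.367590 -0.04709802 6.933265 10.25376
#> 3     3 3.363531 -0.04651607 6.690877 10.00789
```

The resolved per-chromosome thresholds (here 2, the minimum replicate
median over non-zero positions) define the candidate search; all 96
candidates coincide with planted peaks and every one is called, so
region-level precision, recall and F1 against the planted truth are all 1.
The loss table shows the joint objective falling as training proceeds,
with the reconstruction term `l3` doing most of the early work.

A thin command-line front end with `prep`, `train`, `predict`, `eval` and
`simulate` subcommands is installed at `inst/scripts/contrast-peaks`.

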