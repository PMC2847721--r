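---
title: "Methods: EAR and reference-gene normalization of RT-qPCR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EAR and reference-gene normalization of RT-qPCR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earnorm)
```

## The problem

Relative quantification by RT-qPCR measures a quantification cycle (Cq) per
well: the cycle at which amplification fluorescence crosses threshold, one
cycle fewer for every doubling of starting template. Between-sample
differences in RNA input, reverse-transcription yield and pipetting
("loading") shift every gene's Cq together, so a target's signal is only
interpretable relative to a reference that experiences the same loading.
Two reference strategies are implemented here side by side:

* **Reference-gene panels (GeNorm).** Screen candidate housekeeping genes,
  score each by the stability measure M, and normalize by the geometric
  mean of the most stable few.
* **Expressed Alu repeats (EAR).** Amplify transcribed Alu elements
  collectively. Because Alu repeats sit in the UTRs and introns of
  thousands of human transcripts, the pooled signal approximates the total
  mRNA fraction; dysregulation of any modest subset of genes barely moves
  it. One assay then serves any human tissue, at the price of a
  heterogeneous amplicon that needs melt-curve quality control.

## Models and procedures

### Calibration

A serial dilution is fitted by OLS, $Cq = b_0 + b_1\,\log_{10}(\text{amount})$.
The per-cycle amplification factor is $A = 10^{-1/b_1}$ and percent
efficiency $E = (A-1)\times100$. Replicate wells at a dilution enter as
separate points — pre-averaging would understate the residual variance.
$r^2$ is the squared Pearson correlation of observed and fitted Cq, the
standard univariate-OLS definition. There is no weighting and no outlier
rejection: a dilution series is short, and silent down-weighting hides
pipetting faults that should be seen and rerun.

### Relative quantities

Replicates are averaged on the Cq scale (technical noise is approximately
additive in cycles), with the $n-1$ standard deviation and the non-missing
count reported. Missing Cq stays missing end to end; sentinel values such
as 40 or 0 would silently bias means. The mean Cq is then transformed per
gene as $Q_s = A^{(Cq_{\min} - Cq_s)}$, placing the highest-expressing
sample at $Q = 1$. The scale is arbitrary and cancels from every downstream
ratio; translation invariance of $Q$ under a constant Cq shift is tested
explicitly. When an assay has no standard curve its factor defaults to
$A = 2$ (100 % efficiency), overridable per gene — efficiencies are
typically only measured for the non-standard assays, EAR above all.

### Stability analysis

For genes $j,k$ the pairwise variation is
$V_{jk} = \mathrm{sd}_s\!\left(\log_2 Q_{js} - \log_2 Q_{ks}\right)$ with the
$n-1$ denominator, and $M_j = \mathrm{mean}_{k \ne j} V_{jk}$. The stepwise
procedure removes the largest-M gene and recomputes until two genes remain.
Log base 2 is the field convention; any fixed base scales all M equally, so
the base is recorded in the report. Numerical choices worth stating:

* **Ties at the exclusion step** are broken lexicographically, and treated
  as ties whenever the maxima agree to within $10^{-12}$ — exactly
  proportional genes produce M values equal only up to floating-point
  rounding, and the tolerance makes the tie-break reproducible. Tie-broken
  rounds are flagged in the report.
* **The final pair is rank-tied.** With two genes M collapses to the single
  shared $V_{jk}$, so no ordering between them is defensible; they are
  displayed lexicographically and marked as tied. Published stability
  figures often print an order for the final pair anyway; we treat that as
  presentation, not inference.
* **Selection.** The reference set is the `n_references` (default 3) most
  stable genes of the ranking — the field's standard practice of taking the
  final pair plus the last-excluded gene. Each selected gene's M from the
  round where it was last evaluated is then checked against the
  conventional instability threshold (default 0.5), with a warning when a
  selected gene fails it. We deliberately do not define the selected set as
  "all genes with M below threshold": in realistic noise configurations,
  mid-noise genes are excluded in early rounds while their last-evaluated M
  is still below 0.5, so a pure threshold rule inflates the set and defeats
  the purpose of the ranking. The threshold is a QC flag on the chosen
  references, not the selector.
* The normalization factor is the per-sample geometric mean of the selected
  genes' $Q$; scaling one reference by $c$ scales NF by $c^{1/n}$ and no
  M at all (tested).

### Normalization and comparison

`normalize_to_single()` divides target by reference per sample — EAR is
deliberately just a reference "gene" on this code path —
and `normalize_to_nf()` divides by the factor. No calibrator rescaling is
applied by default: published comparisons plot unitless values with medians
near 1 without stating a calibrator, so the package leaves the scale alone
and lets the user median-centre explicitly if wanted. Strategy agreement is
summarised by the Pearson correlation of the paired per-sample values, the
two medians, and per-sample ratios.

### Melt-curve QC

The dissociation transform is the central finite difference of
$-F$ with respect to $T$ on the interior grid points, with no smoothing by
default (an optional odd-width moving average is available for noisy
traces) — the transform stays transparent and testable. Peaks are local
maxima with topographic prominence at least a fraction (default 0.2) of the
well's own global maximum; measuring prominence relative to the well
tolerates plate-level fluorescence scale differences. Multiple peaks are a
legal outcome: the pooled Alu amplicon melts as a mixture of subfamily and
polymorphism variants. The replicate-concordance rule — same peak count and
greedily matched peak temperatures within 0.5 °C (configurable) — encodes
the QC expectation that different samples may legitimately melt
differently, but replicates of one sample must agree. A single replicate is
"indeterminate", not a pass. The expected EAR peak default is carried as
88.69 °C; the alternative reading of the printed token ("88, 69") as two
peaks is plausible, so the value is an editable configuration default, not
an assertion.

### In-silico PCR

The forward primer is matched on the plus strand and the reverse primer as
its reverse complement downstream; coordinates are reported 1-based
inclusive (GenBank convention) and the product length is
`end − start + 1`, verified against the extracted substring. IUPAC codes in
primers match their degenerate sets. Mismatch tolerance, when enabled,
never applies to either primer's 3'-terminal three bases, since polymerase
extension requires a matched 3' end. Transcript templates are searched on
the plus strand only by default; both-strand search is an explicit flag for
genomic sequence. Panel validation passes only on exactly one hit of the
expected length — multiple hits are "ambiguous", never a pass.

### Statistics

Pearson r carries the usual two-sided t-based p. The Mann-Whitney U test
uses the exact null distribution (equivalent to enumerating all rank
assignments) when $n_1 + n_2 \le 16$ and the data are tie-free, and the
normal approximation with tie and continuity corrections otherwise; the
switch point balances enumeration cost against approximation quality at
the sample sizes typical of tissue studies, and the output records which
path ran. Completely tied inputs carry no evidence and return $p = 1$.
Box summaries follow the convention for skewed expression data: quartile
box, median line, and 10th/90th-percentile whiskers only when $n \ge 10$.
Percentiles use linear interpolation between order statistics (type 7) —
no convention was mandated, so the default is the most widespread one and
is recorded in the output.

## The simulator

`simulate_experiment()` generates Cq tables with known ground truth:

* **Loading** is log2-normal per sample (default sd 0.5 log2 units, a
  realistic spread for independently extracted and reverse-transcribed
  clinical samples) and multiplies every gene identically.
* **Biology** is log2-normal per (sample, gene). The default panel names
  the six blood housekeeping candidates with sds 0.05 (GNB2L1, HPRT1,
  YWHAZ) and 0.3/0.4/0.5 (B2M, GAPDH, ACTB), so the simulated stability
  ordering reproduces the ordering reported for human blood; plus a
  BDNF-like target with sd 0.8 — real targets vary between donors, and that
  inter-individual variance is what any two valid normalization strategies
  must agree on. A "constant" target in the concordance sense means no
  dysregulation effect, not zero biological variance: a target with
  literally zero variance would leave nothing but reference noise to
  correlate, and the comparison would be meaningless by construction.
* **Dysregulation** adds a log2 effect to flagged genes in the leading
  `n_cases` samples, for case-control designs.
* **EAR** is the sum of `ear_components` (default 500) independent
  transcript quantities, each with its own mean abundance (spread 1 log2
  unit) and per-sample biological noise (sd 0.3) — the pooling argument
  made quantitative: summing hundreds of independent transcripts shrinks
  the log-scale spread of the total by roughly the square root of the
  effective component count, and the truth object reports the realised sd.
* **Technical noise** is additive on the Cq scale (default sd 0.15 cycles)
  per well, with the 2 RT × 3 PCR design (six measurements per sample and
  gene) as default. The baseline anchor (Cq 24 at unit quantity) only
  places values in the realistic 18–35 window; translation invariance
  makes it irrelevant downstream.

Everything is a pure function of (config, seed), leaving the caller's RNG
untouched.

What the simulator does **not** emulate: sequence-level Alu subfamily
structure (the pooled-quantity model stands in for it), inter-plate
calibration, probe chemistry differences, RNA degradation gradients,
amplification inhibitors, or correlated technical error within an RT
replicate. Passing tests therefore demonstrate the algorithms' correctness
and the internal consistency of the two normalization strategies under
this noise model — not that EAR normalization is valid for any particular
real tissue, which remains an experimental question.

Default problem sizes used throughout the test suite — ten samples, six to
eight genes, six replicate wells, 100-seed property loops, 500 pooled EAR
transcripts — were chosen as the typical scale of a single-plate tissue
study, and keep the whole suite fast enough to run habitually.

## Known limitations

* Single-plate model: no inter-plate calibrators or batch correction.
* Efficiency is per-gene constant; no per-well efficiency estimation from
  amplification curves.
* The exact Mann-Whitney path requires tie-free data; heavily tied small
  samples fall back to the corrected approximation.
* Melt peak calling has no model of amplicon identity; it reports
  temperatures, not products.
* In-silico PCR assumes perfect specificity outside the reported
  mismatches; it does not model primer dimers or thermodynamics.
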