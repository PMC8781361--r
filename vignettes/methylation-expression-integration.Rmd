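---
title: "Methods: relative-difference methylation and enhancer-driven expression change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative-difference methylation and enhancer-driven expression change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rdmeth` integrates array methylation (HM450K-style beta values) with
RNA-seq counts in cohorts that contain matched tumor/adjacent-normal pairs.
This vignette is the package's own account of the statistics it computes,
the conventions it fixes where the underlying definitions leave room, and
what its synthetic-data tests do and do not demonstrate.

## Differential expression

Counts are normalized with median-of-log-ratios size factors. For sample
$j$, $d_{kj} = \ln\!\big(C_{kj} / (\prod_j C_{kj})^{1/n}\big)$ over
*reference genes* — genes with positive counts in every sample, the only
genes for which the log geometric mean is defined — and
$s_j = \exp(\mathrm{median}_k\, d_{kj})$. Normalized counts are
$NC_{kj} = R(C_{kj}/s_j)$ where $R$ is round-half-to-even (the default
rounding of R; the choice only matters at exact .5 ties). A per-sample
multiplicative effect of any origin — sequencing depth, but equally a
patient-wide expression shift — is absorbed entirely by $s_j$.

Fold change is the ratio of group means of $NC$. A zero paracancer mean
yields $FC = +\infty$, which is flagged, excluded from correlation-based
steps, and can still be called *up* on the adjusted-p criterion. All
thresholds are strict as stated: $FC > 1.25$ with $p_{adj} < 0.05$ is up,
$FC < 0.8$ with $p_{adj} < 0.05$ is down; $FC = 1.25$ exactly is not up.

The significance test is a negative-binomial Wald test on the log ratio of
group means, with a per-gene method-of-moments dispersion pooled across the
two conditions and floored at $10^{-8}$; $p$-values are BH-adjusted over
tested genes (genes with all-zero counts are *untested*). This transparent
test is deliberately simple and pluggable; with 9 matched pairs plus the
default unmatched extras (20 cancer vs 12 paracancer samples) it is mildly
anticonservative — the package's own null simulations place the raw
$p<0.05$ fraction near 0.06 rather than 0.05 — which the acceptance tests
treat as the calibrated operating point, not as nominal uniformity.

## Methylation: beta, QC, and the RD statistic

From intensity pairs, $\beta = \max(y_m,0)\,/\,(\max(y_m,0) + \max(y_u,0)
+ \alpha)$ with $\alpha = 100$ (units: fluorescence intensity; the offset
keeps dim probes defined and shrunk toward 0). Probe QC removes non-CpG
probes first, then every probe with at least one missing value across
samples — missing cells on this platform typically mark SNP-affected
probes, so the whole probe is distrusted rather than imputed. Because
NA-carrying probes are removed globally, no per-cell NA logic exists
downstream; that is a deliberate simplification and both filter counts are
logged in order.

Gene promoter methylation pools probes in $[\mathrm{TSS}-1500,
\mathrm{TSS}+1500]$ (inclusive at both ends; probe strand is ignored since
the window is symmetric) in two stages: per-probe condition mean first,
then the mean over the gene's $m_r$ probes. The differential statistic is
the relative difference

$$RD_k = \frac{\beta_{k,t} - \beta_{k,p}}{\beta_{k,p} + \Delta},
\qquad \Delta = 10^{-9},$$

with strict thresholds: $RD > 0.2$ hyper, $RD < -0.2$ hypo. Two numerical
properties are documented rather than "fixed": $RD$ is asymmetric (a 0.2
gain on a low baseline is a larger $RD$ than on a high baseline), and a
near-zero paracancer level produces an enormous $RD$ through $\Delta$.
Pooled RD uses all cancer vs all paracancer samples, unmatched; per-patient
RD appears only in the enhancer model.

## Bin profiles and the key bins

The promoter is divided into 30 bins of 100 bp in transcription
orientation; every other region (5'UTR, exon, intron, 3'UTR, enhancer) into
10 bins over its concatenated length in transcription order, the last bin
absorbing the remainder and multi-interval regions (e.g. split exons)
concatenated before binning. Bin numbering is fixed by the identity that
bins 14–17 span TSS ± 200 bp: bin $\mu$ covers transcription offsets
$[100(\mu-16),\ 100(\mu-15))$, so bin 16 begins at the TSS and bin 15 ends
just upstream of it. Bins are half-open at their upstream edge: a probe on
a boundary belongs to the downstream-numbered bin. Two edge consequences
follow and are asserted in tests rather than patched: (i) the bin partition
covers offsets $[-1500, 1500)$ while the gene-promoter mean uses the
inclusive window, so a probe exactly at the $+1500$ edge contributes to the
gene mean but to no bin; (ii) the strand-mirror property ($\mu \mapsto
31-\mu$ when the strand flips) holds for all probes except those exactly on
a 100-bp boundary, where half-openness maps offset 0 to bin 16 on both
strands.

Bins without probes are absent from the profile, never zero-filled, and are
excluded from the denominator of per-bin abnormal-gene densities. The
key-bin filter keeps genes with $|RD| > 0.2$ in *at least one* of bins
14–17; requiring one bin (not all four) reflects that probe coverage per
100-bp bin is sparse.

## Enhancer → target assignment and DME calling

Each enhancer's target is the gene minimizing $|\mathrm{TSS} -
\mathrm{center}|$ on the same chromosome within 1 Mb (inclusive), center
being the floor midpoint of the BED interval. Ties break to the smaller
TSS, then lexicographic gene id — assignment is deterministic and invariant
to input order.

A DME–gene pair passes three screens in order: pooled enhancer
$|RD| > 0.2$ (all probes inside the enhancer, unbinned); Spearman
$r < -0.4$ between per-patient enhancer RD and per-patient target fold
change $(NC_t + 1)/(NC_p + 1)$ across matched pairs (the pseudocount keeps
single-patient ratios defined at zero counts); and pooled promoter
$|RD| \le 0.2$, so the expression change is attributable to the enhancer.
Genes with no promoter probes pass the third screen by default — there is
no evidence of promoter involvement — and this is logged via the
`no_probes` status. The rank correlation uses the classical
$1 - 6\sum d^2 / (n(n^2-1))$ shortcut for tie-free vectors and falls back
to the Pearson correlation of midranks under ties, where the shortcut's
distinct-rank assumption fails; constant vectors return `NA` with a
warning. Because rank correlation is invariant under strictly monotone
transforms, whether fold change enters as a ratio or its log is
immaterial — only tie handling matters.

## The synthetic-study generator

`simulate_study()` is first-class, tested code: the study conditions the
whole test battery runs under. Defaults: 300 genes on one toy chromosome
tiled every 50 kb, 9 matched pairs plus 11 unmatched cancer and 3 unmatched
paracancer samples (keeping cancer samples in excess, as in tumor
cohorts), 10% each of planted D-Hyper, U-Hypo and DME genes.

* **Counts** are negative binomial (dispersion 0.05) around log-normal
  baselines (log-mean $\ln 300$, log-sd 0.8) with per-sample log-normal
  depth factors (sd 0.2). Planted genes get $|\log_2 FC| = 1.5$ plus
  jitter. Patient-shared expression effects are represented within the
  per-sample depth factor: a sample-wide multiplier is exactly what size
  factors absorb, so a separate pair random effect would be
  indistinguishable downstream.
* **Methylation** is Beta-distributed around a target mean with
  concentration 30 (bounded, heteroskedastic, sd ≈ 0.08 at β = 0.5).
  Planted promoter shifts are $\Delta\beta = 0.25$ by default, confined to
  the key bins (`key_bin_only = TRUE`). Baselines differ by class —
  D-Hyper promoters start low (0.20–0.35) and U-Hypo promoters high
  (0.45–0.60) — because a hypermethylation gain is detectable by RD only
  against a low baseline and a loss only against a high one. About 0.5% of
  cells are set to `NA` (dropping ≈15% of probes through the all-sample NA
  filter, comparable to real 450K QC losses) and 1% of probes are non-CpG.
* **Probe placement** concentrates 70% of promoter probes within TSS ± 200
  bp, the CpG-island-like geography of real arrays. This is load-bearing:
  with uniform probes, a key-bin-only effect touches at most 4/30 of
  promoter probes and can never move the whole-promoter RD past ±0.2, so
  gene-level recovery of key-bin effects would be impossible for any
  effect size.
* **DME genes** get one causal enhancer 5–20 kb from their TSS (genes are
  50 kb apart, so the nearest-gene rule recovers the causal pairing
  unambiguously), plus decoy enhancers near 20% of non-DME genes.
  Per-patient enhancer shifts span $[0.05, 0.05 + \Delta\beta]$, assigned
  anti-monotone (by rank, with jitter) to the patient's planted expression
  multiplier. The shifts are all positive by design: a zero-mean shift
  pattern would cancel in the pooled enhancer RD and be removed by the
  first DME screen, which operates on pooled, not per-patient, methylation.
  Unmatched cancer samples receive the mean shift for the same reason.

**What passing tests show — and don't.** On these studies the pipeline
recovers planted D-Hyper and U-Hypo genes with sensitivity ~1.0, DME pairs
with sensitivity ≥ 0.95 and precision ~1.0 at $\Delta\beta = 0.4$, and
null-study false calls are near zero. The generator does not emulate
Illumina type I/II probe chemistry, SNP-driven artifacts beyond random NA
dropout, copy-number confounding, correlated probe noise within CpG
islands, or multi-enhancer regulation; real-data performance will be worse
than these clean-room numbers, and the null calibration in particular
reflects NB-distributed counts, not real RNA-seq quirks.

**Problem sizes.** Tests and the acceptance script use 300-gene studies
and 10–20 seed replicates per claim; these sizes give stable Monte-Carlo
estimates (the 20-seed mean of the null $p<0.05$ fraction has sd ≈ 0.003)
while a full run stays in seconds.

## Known limitations

* The DE test is a stand-in with documented calibration, not a reproduction
  of any published tool's numerics; swap in another per-gene test if exact
  parity with a specific pipeline matters.
* One TSS per gene is assumed; multi-transcript genes must be collapsed
  upstream, and the annotation reader rejects duplicate gene ids rather
  than guessing.
* The promoter-exclusion screen for DME genes uses the pooled gene-level
  RD; a promoter abnormal only within a sub-bin but not in aggregate will
  not disqualify a pair.
* Candidate selection stops at the reproducible list (class ∩ cancer-gene
  set ∩ key-bin abnormality, with role/direction concordance reported, not
  enforced); any further biological curation is out of scope by design.
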