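---
title: "Models and methods behind waverate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind waverate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
conventions of waverate, in the spirit of the methods sections of
mature omics packages: what is assumed, what is tunable and why, and
what the synthetic validation does and does not demonstrate.

## The wave model of DRB-release transcription

DRB reversibly blocks the transition from transcription initiation to
elongation. While the drug is on, RNAPII accumulates at promoters;
after washout all polymerases of a gene are released near-synchronously
and advance at the gene's elongation rate $v$ (kb/min). The nascent-RNA
coverage of a gene at $t$ minutes after release is therefore a *wave*
occupying $[\mathrm{TSS}, \mathrm{TSS} + vt)$. A 4sU pulse of length
$w$ minutes immediately before harvest labels only RNA polymerized in
the last $w$ minutes, i.e. the trailing segment
$[\mathrm{TSS} + v\,\max(0, t-w),\ \mathrm{TSS} + vt)$.

waverate assumes:

* a **sharp front with uniform occupancy behind it** — release is
  treated as perfectly synchronous and within-gene speed as constant.
  Real waves have dispersed fronts (initiation is not instantaneous and
  speeds vary along genes); the changepoint detector absorbs moderate
  dispersion because it estimates the location of the mean shift, not
  a corner;
* **mature-RNA contamination is exon-restricted** — the background that
  survives nascent enrichment is spliced mRNA, so it concentrates on
  exons. This motivates both the 0-min subtraction and the exon-mask
  imputation;
* the **default 0/5-min design with a 10-min pulse**: when the pulse is
  at least as long as the release time, the labeled signal covers the
  entire wave and the front position is simply $vt$. Later time points
  (15, 45 min) are supported by the same machinery (the label then
  covers only the trailing window), but rates are fitted from the
  boundaries, which are front positions in either case.

## The rate chain and its parameters

**Binning** (`bin_coverage()`). A fragment is assigned to the bin of
its 5′-most base in transcription direction, so bins are comparable
between strands; values are divided by the library's total aligned
reads. The default bin is **200 bp**: at $t = 5$ min this quantizes
rates in steps of $0.04$ kb/min, an order of magnitude below the
between-gene variation of interest, while keeping per-bin counts high
enough for stable means. (20-bp bins are used only for metagene
profiles, where averaging over genes supplies the statistics.)

**Control normalization** (`wave_signal()`). The 0-min track is
*subtracted* (signal $=\max(0, s_t - s_0)$ per bin). A ratio variant
(`mode = "ratio"`) is provided; subtraction is the default because the
0-min control measures an additive contamination floor, and ratios are
unstable in bins where the control is near zero.

**Exon masking.** Bins overlapping annotated exons are replaced by the
mean of their non-masked neighbors within 5 bins (0 if none), then the
signal is smoothed by a centered running mean over **5 bins** (partial
windows at the edges). Masking protects boundary detection from exonic
mRNA spikes the subtraction missed. Its cost: if an exon happens to
straddle the true front, imputation can displace the boundary by up to
the exon width even in noiseless data. The pipeline therefore exposes
`mask_exons`; the test suite checks exact noiseless recovery (boundary
within one bin of truth for every gene) with masking off — the setting
in which masking has nothing to do — and checks noisy recovery (median
absolute error ≤ 0.25 kb/min at 500 signal + 50 background fragments
per gene) with the full default chain.

**Boundary detection** (`detect_boundary()`). The front is the
changepoint $c^\*$ minimizing the two-segment squared error
$\sum_{i<c}(s_i-\mu_L)^2 + \sum_{i\ge c}(s_i-\mu_R)^2$ subject to
$\mu_L > \mu_R$, ties broken towards the largest $c$ (the most distal
equally-good front). Detection is gated on contrast: if the optimal
split does not satisfy $\mu_L > 2\mu_R$, the signal is declared flat
and no boundary is returned. This is a deliberately transparent
changepoint formulation of the wave-front observable: it is $O(n)$ via
cumulative sums, has no tuning beyond the contrast gate, and is
verified against an independent exhaustive-search implementation on
1,000 random signals in the test suite. Published wave analyses have
used Matlab protocols whose exact boundary criterion is not printed;
per-gene numerical identity with those scripts is not claimed.

**Rate fit** (`estimate_rate()`). Boundary versus time is fitted
through the origin, $v = \sum_j t_j b_j / \sum_j t_j^2$, because DRB
synchronization pins the wave at the TSS at $t=0$; an intercept fit is
available (`intercept = TRUE`) for designs where a release lag is
suspected, but it is off by default (with a single positive time point
it would be unidentifiable).

**QC filters** (`apply_rate_filters()`), applied independently so a
gene can carry several flags:

| flag | rule | default |
|---|---|---|
| `too_short` | gene length below threshold | 20 kb |
| `low_coverage` | summed release-time coverage over the first 20 kb, in reads per million | 0.7 |
| `too_slow` | rate ≤ threshold (a rate *exactly at* the cutoff is excluded) | 0.5 kb/min |
| `no_boundary` | flat signal, no front detected | — |
| `missing_in_other_condition` | no rate in the companion cell type | optional |

The coverage rule's published phrasing ("0.7 reads per gene at the
first 20 kb") does not state units; waverate interprets it as
depth-normalized coverage in reads per million summed over the first
20 kb, with the threshold configurable so other readings can be
applied.

**Speed classes** (`assign_speed_groups()`). Retained genes are split
at the empirical 1/3 and 2/3 quantiles (type 7, R's default); values
tied with a boundary go to the lower class. The tie rule is a
convention — any consistent rule preserves the three-class analysis —
and all-equal rates are rejected as degenerate rather than silently
producing empty classes (the pipeline then reports every gene as
`unassigned`).

## Occupancy, pausing and m6A quantification

**Spike-in correction** (`spike_in_factor()`). With human chromatin
spiked into mouse samples before immunoprecipitation, global occupancy
changes that read-count normalization would hide are recoverable from
the mouse/human aligned-read ratio. The corrected knockout signal is
the read-normalized signal times
$(\text{mouse}_{WT}/\text{human}_{WT}) /
(\text{mouse}_{TKO}/\text{human}_{TKO})$, computed per replicate.
Whether a pooled factor would be preferable is unknowable from the
published description; per-replicate factors keep replicate provenance
intact.

**Occupancy and pausing** (`pausing_table()`). Promoter (TSS±500 bp)
and body (TSS+500 → TTS) occupancies are RPKM-style
($\text{count}/(\text{len}/10^3)/(\text{total}/10^6)$, times the spike
factor), averaged across replicates, and the pausing index is the
ratio of the replicate-mean signals. Mean-then-ratio was chosen over
ratio-then-mean for stability (a single low-body replicate would
otherwise dominate); genes with zero body signal get an undefined index
and are excluded from rank tests rather than carrying infinities. The
spike factor cancels in the index up to replicate weighting.

**m6A level** (`m6a_level()`). Per replicate, IP and input counts over
the extended transcript (TSS−2 kb → TTS+2 kb; m6A concentrates near
stop codons/TTS, hence the extension) are divided by their library
totals; the level is the replicate mean of the IP/input ratio. Genes
with no data in any replicate of a condition, or zero input, are
excluded. Cross-condition change is $\log_2$ of the level ratio;
quartile analyses split genes by promoter-proximal H1 occupancy
(TSS±2 kb, the window used for the promoter profiles) with type-7
quartiles and report one-sample Wilcoxon signed-rank tests of the
log-ratios against 0 — the standard one-sample form of the rank test.
An all-zero quartile is degenerate and reported with $p = 1$ by
convention. Peak classification uses the peak *midpoint* against
TSS±2 kb / TTS±2 kb windows; midpoint rather than any-overlap avoids a
long peak counting in several windows, and short genes can
legitimately yield `both`.

**Statistics layer.** All tests are two-sided (the conservative choice
when sidedness is unstated); `wilcox.test()` supplies exact small-$n$
p-values where feasible and the tie-corrected normal approximation
otherwise. Fully degenerate comparisons (all values identical, or all
paired differences zero) return $p = 1$ by convention. No
multiple-testing correction is applied by default, matching the
raw-p-value reporting style of the analyses this package mirrors;
`p.adjust()` composes naturally with the tidy outputs when wanted.

## What the generator emulates — and what it does not

`simulate_annotation()` places non-overlapping genes (50 per synthetic
chromosome, 10-kb gaps — arbitrary but documented), lengths uniform in
30–60 kb by default, 2–10 exons whose first and last blocks touch the
gene ends. `simulate_wave()` draws Poisson fragment counts (default
2,000 labeled + 100 exonic background per gene) with uniform positions
on the labeled wave segment. `simulate_count_tables()` draws Poisson
counts around true occupancies, expressions and enrichments; knockout
mouse totals are scaled by the inverse of the true spike factor so the
ledger encodes a recoverable global shift; MeRIP IP libraries are
generated at the calibrated depth recorded in the totals table, so
depth-normalized IP/input ratios estimate the true per-gene enrichment
directly. Default true rates follow a two-component log-normal mixture
with modes 2.0 and 3.5 kb/min (weights 1/3 and 2/3, sdlog 0.2),
emulating a slow and a fast transcription class.

The generator does **not** model: read-level sequencing (no FASTQ/BAM,
no error or mappability structure), overdispersion beyond Poisson,
within-gene speed changes, dispersed release, intergenic background,
or overlapping/nested genes. Passing tests therefore demonstrate the
*correctness of the computational chain under its stated model*, not
performance on real libraries, where front dispersion and
overdispersion will widen error bands.

Noise choice: no noise model for nascent coverage is published;
Poisson is the minimal choice for count data and the validation
tolerances absorb it.

## Problem sizes and determinism

The validation suite runs cohorts of 150–300 genes (200–2,000
fragments per gene), 1,000-signal detector/oracle comparisons, and
1,000-replication null calibrations of the Mann–Whitney layer — sizes
chosen so the whole suite completes in well under a minute per file on
one CPU while keeping Monte-Carlo error comfortably inside the asserted
tolerances. Every stochastic step is seeded; `simulate_*()` functions
derive their streams from `cfg$seed` plus the time point, replicate and
condition, so outputs are byte-identical for a fixed configuration and
distinct across samples.

## Known limitations

* Boundary quantization: rates are multiples of
  `bin_size / (t · 1000)` kb/min; medians over cohorts inherit a
  half-bin granularity.
* Genes shorter than $vt$ clip the wave at the TTS; their boundary
  reflects the gene end, not the rate. The 20-kb length filter removes
  the worst cases at the default design but very fast short genes can
  still saturate.
* The exon-mask/front interaction described above biases individual
  boundaries inward by up to one exon width; it does not move cohort
  medians appreciably but matters for single-gene claims.
* `cherna_output()` normalizes by gene length as the printed
  description does; exonic-length normalization would differ for
  genes with little exonic sequence.
* Real-data RefSeq curation (which transcript set, how alternative
  TSSs were merged) is not recoverable from published descriptions;
  `keep_longest_transcript()` guarantees only the longest-transcript
  rule with a deterministic lexicographic tie-break.
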