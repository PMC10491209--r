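---
title: "Testing per-transcript RNA length changes in nanopore direct RNA-Seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing per-transcript RNA length changes in nanopore direct RNA-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drnalen)
```

## The problem

Nanopore direct RNA sequencing threads native RNA molecules through the pore
3′ to 5′, so each read ends where the molecule ends: a transcript that has
been nibbled back from its 5′ end produces a shorter aligned span. Comparing
the distribution of read lengths for a transcript between two conditions is
therefore a direct, single-molecule assay for 5′ decay. The statistical
difficulty is that read lengths within a sequencing library are correlated —
library preparation and pore behaviour shift whole libraries up or down — so
pooling reads across replicates and running a plain two-sample test
overstates the evidence, and deeper libraries dominate the effect estimate.

## The model

For one transcript, let $Y_{ij}$ be the length of read $i$ in library $j$,
$c_j \in \{0, 1\}$ the condition of library $j$ (0 = control), and optionally
$\log_2$-transform the response. The package fits

$$Y_{ij} = \beta_0 + \beta_{\mathrm{cond}} c_j + b_j + \varepsilon_{ij},
  \qquad b_j \sim N(0, \sigma_b^2), \quad
  \varepsilon_{ij} \sim N(0, \sigma^2),$$

by REML (`fit_lmm()`), where $b_j$ is a random intercept per library. On the
$\log_2$ scale $\beta_{\mathrm{cond}}$ is the log2 fold-change of read
length, condition over control. Alternatives are the fixed-effects linear
model without $b_j$ (`fit_linear()`, equivalent to a pooled two-sample
t-test when there are no covariates) and the Wilcoxon rank-sum test
(`fit_wilcoxon()`, condition only, no covariates). `run_differential_length()`
applies one of these per transcript and adjusts p-values across transcripts
with the Benjamini–Hochberg step-up procedure; significance is reported both
on raw and on adjusted p-values.

### Why the Wald statistic uses a Satterthwaite t reference

The condition effect is tested with the Wald statistic
$\beta_{\mathrm{cond}}/\mathrm{SE}$. With three libraries per condition the
effective degrees of freedom for this contrast are close to 4 — the
information about $\beta_{\mathrm{cond}}$ comes from 6 library means, not
from thousands of reads — so referring the statistic to a standard normal
is sharply anticonservative: $P(|t_4| > 1.96) \approx 0.12$, more than
double the nominal 0.05. Referring the same statistic to a t distribution
with Satterthwaite degrees of freedom (via lmerTest) restores calibration;
the packaged null simulations (1000 genes per cell, re-run by
`scripts/acceptance.R`) give empirical false-positive rates within the 99%
binomial interval of the nominal 0.05 at every read depth. The package
therefore always uses the Satterthwaite t reference for the mixed model:
a plain-normal Wald test cannot control the type-I error at these library
counts.

### Degenerate and unidentifiable fits

* Zero residual variance (all reads identical within groups) is not an
  error: the estimate is reported, the p-value is 1 when the estimate is
  also zero and NA otherwise, and the `degenerate` flag is set.
* A design with fewer than two libraries in some condition cannot identify
  $\sigma_b^2$; `fit_lmm()` falls back to the linear model and sets
  `fallback_flag`, as it does for singular or non-converging fits.
  Transcripts are never silently dropped.
* Wilcoxon p-values are exact (enumeration) for untied samples with both
  groups under 50 reads, and use the normal approximation with tie
  correction otherwise. Fully tied inputs give p = 1.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_reads_per_condition` | 10 | a transcript is tested only with at least this many reads in *both* conditions; below ~10 reads the mixed model is unstable |
| `logscale` | TRUE | model $\log_2$(length); estimates become log2 fold-changes and the test is scale-free |
| `alpha` | 0.05 | level for the `sig_raw` / `sig_adj` call columns |
| `adaptor_only`, `polya_only` | FALSE | restrict to reads whose 5′ adaptor / poly(A) flag is TRUE; an NA flag means "unknown" and is never treated as TRUE |
| reference level | lexicographically smallest | override with `load_design(..., reference = )`; estimates are always condition minus control |

## The simulator

`simulate_scenario()` generates data from exactly the model the mixed model
assumes. For gene $g$ and library $j$ the group mean is $\mu_j = L$
(control) or $pL$ (condition), with $L$ the true length and $p$ the
shortening proportion; a library effect $b_{gj} \sim N(0, (0.10\,L)^2)$ is
drawn independently per gene and library; each of the `reads_per_library`
reads adds $\varepsilon \sim N(0, (0.20\,\mu_j)^2)$. Lengths are rounded to
whole nucleotides and clamped at 1 nt (clamping is counted and warned above
0.1% frequency — it is negligible at the default noise levels).

Choices worth recording:

* **Defaults are the study conditions**: 3 control + 3 condition libraries,
  library SD 10% of the true length, residual SD 20% of the group mean,
  1000 genes per scenario, read counts 10–200, proportions 0.5–1.0 (1.0 is
  the null).
* **True length 1000 nt.** Both noise terms are proportional to the true
  length, so on the log scale results are insensitive to its value; 1000
  keeps fixtures hand-checkable.
* **Residual SD scales with the group mean**, so shortened reads are less
  noisy in absolute nucleotides. The alternative (scaling with the true
  length in both groups) changes the absolute noise of condition reads by
  the factor $p$; the group-mean reading is used throughout.
* **The library effect is drawn per gene × library**, matching the per-gene
  mixed model. Sharing one library effect across genes within a library
  would induce cross-gene correlation that a per-gene test neither assumes
  nor exploits; both readings are defensible, this one is the default.
* **Reproducibility**: one master seed; per-gene substreams are derived from
  it, so any gene can be regenerated in isolation and two runs with the
  same scenario are byte-identical.

`run_simulation_grid()` sweeps (proportion × count) cells, reporting the
mean estimate and the fraction of genes significant at `alpha`: type-I error
at proportion 1.0, power elsewhere.

### The library variance caps power

Because the library effect is the replicated unit, the standard error of
$\beta_{\mathrm{cond}}$ is floored at roughly
$\sqrt{(\sigma_{b,\mathrm{ctrl}}^2 + \sigma_{b,\mathrm{cond}}^2)/3}$ on the
modelling scale no matter how many reads each library contributes: once
$\sigma^2/n \ll \sigma_b^2$, additional read depth buys almost nothing. On
the log2 scale a 10%-of-true-length library SD is ~0.14 in the control
group and, under shortening to proportion $p$, ~$0.14/p$ in the condition
group. Two consequences, both visible in the numbers the acceptance script
computes: at proportion 0.9 the power of the calibrated test plateaus
around 0.15 from count ~25 onward (the curve is monotone in expectation,
but its increments beyond count 50 are smaller than the Monte-Carlo noise
of a 1000-gene cell, so sample power estimates can wiggle downward); and at
proportion 0.5 with 200 reads per library power reaches ~0.96, not 1 —
pushing past that would require more libraries, not more reads, or an
anticonservative reference distribution. Mean-estimate recovery is
unaffected: the estimator is unbiased and its cell means land within a few
hundredths of $\log_2 p$.

What the simulator deliberately does **not** emulate: basecalling error,
alignment artifacts and soft-clipping noise, poly(A)-tail length variation,
3′ truncation, transcript-to-transcript expression differences within a
scenario, and non-normal length distributions (real per-transcript length
distributions are often multimodal mixtures of intact and decayed
molecules). Passing the simulation checks therefore demonstrates that the
inference machinery is calibrated and recovers effects *under its own
assumptions*; it does not by itself validate the normality assumption on
real data — the Wilcoxon option exists for exactly that concern.

## Read geometry

* **Coordinates** are 0-based half-open everywhere in memory; 1-based only
  at the SAM boundary. `extract_read_coords()` takes the leftmost aligned
  reference position and the CIGAR reference span (M/=/X/D/N), so soft and
  hard clips — adaptors, poly(A) — never count. Reverse-strand alignments
  are skipped with a counter (direct RNA reads align sense to a
  transcriptome).
* **Read length for testing** is the aligned reference span, not the query
  length, so untemplated bases do not inflate lengths; `coords_to_length_table()`
  makes the conversion explicit.
* **Meta-length** divides each annotated transcript into 20 equal bins
  indexed 0–19, bins both read ends (`bin(x) = floor(x / (L/20))`, using the
  last covered base for the 3′ end), and reports the *inclusive* bin span as
  a percentage: $(b_3 - b_5 + 1)/20 \times 100$. The inclusive convention is
  chosen so that a full-length read scores exactly 100% (a bare bin
  difference would cap at 95%); the scale is discrete, multiples of 5 in
  (0, 100].
* **TSS calling** pools reads across libraries, counts 5′ ends at each
  position within the annotated 5′ UTR, and calls the modal position when
  its own support (not the UTR total) reaches `min_support = 5` reads. Ties
  are broken towards the smallest (most 5′) coordinate and flagged.
* **Composition** tallies transcript bases at offsets −flank…+flank around
  each read's 5′ end; per-read positions outside the transcript are
  skipped, and each offset's A/C/G/T fractions are computed over the reads
  actually counted there.

## Problem sizes used by the test suite

The packaged checks run the simulation study at 1000 genes per grid cell
(null cells at counts 10/100/200; recovery at proportions 0.5/0.7/0.9 with
count 200; a power curve at proportion 0.9 over counts 10–200), which gives
a 99% binomial interval of ±0.018 around a nominal 0.05 false-positive
rate — tight enough to detect the ~2× inflation a misreferenced Wald test
produces, while keeping a full run in the minutes range on one CPU. Unit
tests use much smaller scenarios; geometry checks run against a hand-written
8-record SAM whose expected outputs are hand-computed.

## Known limitations

* Exactly two condition levels; no continuous exposure or >2-group
  contrasts.
* The Wald/Satterthwaite p-value is asymptotic in the residual dimension;
  with extreme imbalance between libraries it can still be mildly
  miscalibrated.
* The Wilcoxon option cannot adjust for covariates.
* `adjust_bh()` assumes independent or positively dependent tests, as BH
  does.
* TSS calls depend entirely on the annotated 5′ UTR interval; an
  unannotated or wrong UTR silently shifts the search window.
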