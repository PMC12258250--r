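---
title: "Multiomic TFBS scoring: model, calibration and design notes"
author: "tfscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiomic TFBS scoring: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfscan)
```

## The scoring model

A putative TFBS is a window of a promoter sequence that matches a TF's
motif. `tfscan` scores it as a sum of independent log-likelihood terms,
one per evidence type, on a common scale (bits). The modelling premise
is that each evidence type contributes an approximately independent
likelihood ratio for "this window is a functional site", so log terms
add; the sum is the *combined affinity score*.

**PWM term.** From a position frequency matrix with counts $a_i$ per
nucleotide and position, sequence count $S$, and pseudocount $b$
(default 0.8), the weight of nucleotide $a$ at position $i$ is
$$w(a, i) = \log_2 \frac{(a_i + b/4)\,/\,(S + b)}{p_{bg}(a)},$$
and a window's PWM score is $\sum_i w(x_i, i)$. The background defaults
to human genome composition ($p_A = p_T = 0.295$, $p_C = p_G = 0.205$)
and is configurable; when background *counts* are supplied instead of
frequencies, the same pseudocount is applied to them
($(n_{nuc} + b)/(l_{bg} + b)$). Both paths are exposed because the
pseudocount treatment of the background is a genuine modelling choice;
the default applies it only when counts are given, which reduces to the
standard log-odds PWM with published frequencies.

**Empirical feature terms.** Each evidence track is summarised once,
genome-wide, into an empirical score table: the distribution of an
observable over every nucleotide position (or every catalogued value),
with a direction fixed per feature:

| feature | observable | tail |
|---|---|---|
| CAGE | distance to nearest peak | $P(x \le d)$ |
| ATAC | distance to nearest peak | $P(x \le d)$ |
| conservation | distance to nearest element | $P(x \le d)$ |
| metaclusters | overlap count | $P(x \ge n)$ |
| eQTL | effect magnitude | $P(x \ge m)$ |
| CpG | observed/expected ratio in 200 nt | $P(x \ge r)$ |
| correlation | TF–gene correlation magnitude | $P(x \ge c)$ |

The score of an observed value is $-\log_2$ of its tail probability,
which is non-negative and, with the probability floor below, finite.
Summed features (CAGE, ATAC, eQTL) accumulate one term per relevant
element; the CAGE term weights each peak's term by its expression share
$p_i / p_{total}$ *inside* the logarithm, i.e.
$-\log_2\!\big(P(x \le d_i)\, p_i/p_{total}\big)$. Read literally this
makes a low-usage peak contribute *more* bits, which is biologically
surprising; the form is retained deliberately (it is the published
formulation) and a `cage_weighting`-style alternative was considered
and rejected to keep a single code path — the benchmarking sweep can
simply exclude the CAGE feature where it hurts.

**Distance convention.** Distances are nearest-edge distances between
closest base positions: 0 on overlap, 1 when bookended, gap + 1 in
general. This makes a width-1 query interval at position $p$ score
identically to position $p$ in the genome-wide per-position table, so
hit-level lookups and table construction share one convention. The hit
centre is never used.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| pseudocount `b` | 0.8 | counts | standard smoothing; keeps zero counts finite |
| PWM p-value cutoff `pval` | 0.01 | probability | retains ~1% of background windows |
| combined p-value cutoff `pvalc` | 0.01 | probability | same, on the combined scale |
| promoter window | −900..+100 | nt vs TSS | 1,000 bp window; negative values flip a boundary across the TSS |
| CpG window | 200 | nt | island-scale ratio |
| probability floor $\varepsilon$ | $1/(n+1)$ | — | values beyond observed support stay finite, at most $\log_2(n+1)$ bits |
| p-value score grid | $10^{-3}$ | bits | discretisation of the PWM score distribution |
| correlation cutoff | 0.3 | magnitude | pairs below it are absent and score 0 |
| CAGE-like caller | signal > 5, merge ≤ 10 nt, width > 10 nt | — | strict inequalities, filter → merge → width |
| TN sampling | n = 50, window 2,000 bp, ≥ 25 bp | — | matched-negative defaults |
| ChIP protocol | top 500 peaks, min 100, 200 bp regions | — | per-TF inclusion rule |

## Numerical choices

**Exact PWM p-values on a grid.** The null distribution of the PWM
score is computed by per-position convolution of the four cell weights
under the background, discretised on a fixed grid (default $10^{-3}$
bits). Naively rounding a window's floating-point score onto the grid
can land one cell away from the window's own convolution atom (the
roundings accumulate per position), so the scanner addresses each
window's atom directly through the same per-position integer offsets
the convolution uses — scan p-values are therefore exact with respect
to the discretised distribution, and for motifs of length ≤ 5 they
reproduce brute-force enumeration of all $4^L$ windows. Reported
*scores* remain exact floating-point bits; only the p-value lookup is
gridded. Windows containing `N` are skipped rather than scored.

**Empirical p-values.** Combined scores are calibrated per TF, not
pooled: PWM score ranges differ strongly with motif length, so pooling
would let long motifs dominate. The p-value is $(r+1)/(n+1)$ with $r$
the count of background scores at or above the observation — never 0,
monotone, and exact under ties. The original tool calibrates against
tens of thousands of real promoters; here the corpus is pluggable and
the packaged default is 200 synthetic 1,000 bp promoters, a size chosen
so the whole suite runs in minutes on one CPU while leaving the
calibration check statistically meaningful. Uniformity of the null is
verified on *per-promoter top scores* with leave-one-out p-values:
maxima compared against the pooled all-hit background are of course not
uniform, so the calibration property is stated — and tested — at the
level at which exchangeability actually holds.

**Degenerate inputs.** Empty PFMs, empty background corpora and empty
element lists for distance tables are errors (a distance table without
elements has no defined support); missing *tracks* are not — a feature
with no data scores 0 and raises a per-feature `absent` flag, because
the tool legitimately runs with feature subsets (non-human species have
only CAGE-like, CpG and conservation data). A paired t-test with
zero-variance differences reports p = 1 with a `degenerate` flag so
combination sweeps stay total. Ties in the best-combination search are
broken toward the smaller feature set, then enumeration order.

## The synthetic data generator

Fixtures emulate the statistical structure the method exploits, not
real genomes. A genome is i.i.d. nucleotides at a configurable GC
fraction (default 0.41) with evenly spaced `+`-strand transcripts;
motif instances are sampled from the PFM (default: an 8-position motif
with 85% dominant-base columns, ≈ 1.1 bits/position, typical of a
well-characterised motif) and written at chosen positions. Each
feature track places a fraction $e$ (the enrichment) of its elements
within 25 bp of a random implant and the rest uniformly; eQTL
magnitudes are $|N(0,1)|$, correlations Uniform(−1, 1) filtered at
magnitude 0.3 with implanted genes upweighted. Default scale — 100 kb,
20 transcripts, 200 background promoters; the benchmark fixture uses a
40 kb genome with 12 true positives × 50 matched negatives — was sized
so the suite completes in minutes on one CPU.

What passing on fixtures does **not** show: real promoters are not
i.i.d. (repeats, isochores, CpG islands with internal structure), real
evidence tracks are correlated with each other and with GC content,
and real negatives are not guaranteed non-functional. Fixture results
validate the machinery — score arithmetic, calibration, protocol
constants, monotonicity — not biological accuracy.

## Benchmarking protocol notes

True negatives are drawn uniformly over centres that satisfy *both*
stated constraints — inside the anchor transcript's promoter *and*
within the 2,000 bp window around the true positive, at least 25 bp
from its centre (both read inclusively) — since the intersection is the
only reading satisfying each. TNs may overlap one another but never a
TP region of the same TF; overlap with other TFs' sites is not
excluded (not stated by the protocol, configurable via `all_tp`).
Region scores are the maximum over all windows at scan threshold 1;
a region with no scorable window receives $-\infty$ and ranks last.
AUROC is the tie-aware rank statistic, identical to all-pairs counting,
and is cross-checked in the tests against an independent ROC
implementation. The 128-combination sweep recombines cached per-window
component scores, so combinations never rescan. In the ChIP-Seq
protocol, each true negative reuses its true positive's TSS-relative
offset on a seeded-random peak-free transcript, so the matched pair
sits at the same distance from a TSS.

## CAGE-like peak calling

The caller takes threshold → merge → width order: contiguous runs of
coverage with signal strictly above 5 are candidates, candidates within
10 nt merge, and only then is the strict width filter (> 10 nt)
applied. Filtering width first would delete the sub-peaks the merge
step exists to join. "Within" is read inclusively both for the merge
gap (≤ 10 nt) and for TSS association (≤ 50 nt, distance 0 when the
TSS falls inside a peak); both boundaries are pinned by tests. A merged
peak's signal is the max over members (sum available as an option).
Peaks with no transcript within 50 nt are dropped from the CAGE track.

## Known limitations

- Correlation tables are tissue-agnostic; the per-pair Bonferroni
  filter is applied at build time only when per-pair p-values are
  supplied.
- The Ensembl REST retrieval path is out of scope; all inputs are local
  files behind the reader contracts.
- The track figure is a faithful schematic (panel set and semantics),
  not a pixel-accurate reproduction of any particular styling; the CpG
  panel draws the per-hit CpG score rather than a base-resolution ratio
  curve.
- Strand handling assumes single-chromosome, `+`-oriented fixtures for
  generation; analysis itself is strand-aware (minus-strand transcripts
  get mirrored windows and TSS-relative coordinates, verified by a
  reverse-complement symmetry test).
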