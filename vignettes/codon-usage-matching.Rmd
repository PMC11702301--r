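---
title: "Measuring virus-host codon usage match: models, indices and design choices"
author: "codonMatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring virus-host codon usage match}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonMatch)
```

## The question the package answers

Most viruses do not encode their own tRNAs, so translation of viral proteins
runs on the host tRNA pool. If translational selection matters, a virus whose
synonymous codon preferences match those of a candidate host should translate
efficiently there, and codon usage similarity becomes a host-range predictor.
For giant viruses (*Nucleocytoviricota*) infecting amoebae this logic turns
out to be surprisingly unreliable — some virus families use codons *opposite*
to their best-known laboratory hosts — which is exactly the kind of claim that
needs careful, reproducible measurement. This package implements the full
measurement chain: per-gene codon usage statistics, virus-versus-host
similarity indices, robust comparison of their distributions, and supporting
scans of host genomes for integrated viral regions whose composition betrays
past infections.

Everything runs on plain CDS FASTA files, and a synthetic CDS generator
reproduces the statistical structure the analysis assumes, so the whole
pipeline is testable without downloading any genome.

## Codon usage statistics

**Codon usage tables.** All statistics derive from counts of the 61 sense
codons (`codonUsageTable()`), either per gene or pooled over a CDS set
(species, genus or family pools). Counting rules, applied once at load time
(`readCdsFasta()` / `cdsSet()`): sequences are upper-cased; ambiguity codes
other than N are collapsed to N; a trailing incomplete codon (1-2 nt) is
trimmed with a warning, since annotation exports often carry broken terminal
codons; codons containing N are excluded; and counting stops before the first
in-frame stop codon. The stop rule serves two purposes at once — terminal
stops never enter any index (all indices here are defined over
amino-acid-coding codons), and pseudogenized genes with premature stops, which
genuinely occur among integrated viral genes, are scored on their intact
prefix instead of crashing or contaminating counts. Each load records a
report of how many sequences each rule touched.

**GC3.** The fraction of counted codons whose third base is G or C. All
counted codons enter, including the invariant Met (ATG) and Trp (TGG) codons:
the alternative convention (GC3s, degenerate families only) exists, but since
the plotted quantity is simply "GC content at the third codon position" we
keep the literal definition; the choice shifts every gene of a genome by a
comparable small amount and does not affect within-plot structure.

**ENC.** The effective number of codons runs from 20 (each amino acid uses a
single codon) to 61 (uniform synonymous usage). Per degenerate family $a$
with codon count $n_a$ and relative synonymous frequencies $f_c$, the
homozygosity is either the plug-in $F_a = \sum_c f_c^2$ or the bias-corrected
$F_a = (n_a \sum_c f_c^2 - 1)/(n_a - 1)$ (defined for $n_a \ge 2$; the
default, since per-gene samples are small). Averaging $F$ within each
degeneracy class $k \in \{2, 3, 4, 6\}$ over the *observed* families gives

$$\mathrm{ENC} = n_1 + \sum_k N_k / \bar F_k,$$

with $n_1$ the number of observed single-codon amino acids and $N_k$ the
number of observed families of class $k$. For a gene containing all 20 amino
acids this is the classical estimator (and reproduces the anchors 20 and 61
exactly); for short genes missing whole families it degrades gracefully
instead of extrapolating to unobserved families. Two numerical conventions:
if the lone 3-fold family (Ile) is observed but its $F$ is inestimable,
$\bar F_3$ is interpolated as $(\bar F_2 + \bar F_4)/2$ when both neighbours
exist, the standard recommendation; and sampling noise occasionally pushes
the estimate above 61, so values are capped at 61 to keep the documented
scale. A class whose $\bar F$ is undefined or non-positive (possible for the
bias-corrected form on two-codon observations) is omitted from the sum.

**The no-selection null curve.** On an ENC-GC3 plot, the expectation under
mutational bias alone is

$$\mathrm{ENC}_0(s) = 2 + s + \frac{29}{s^2 + (1-s)^2},$$

implemented literally in `encNull()`. Genes far below the curve are
candidates for translational selection; `flagTopExpressed()` marks the top
5% of genes by expression (FPKM proxy) so this prediction — highly expressed
genes should sit lower — can be read off the plot. The flag count is exactly
$\lceil 0.05\,N \rceil$; ties at the cutoff are broken lexicographically by
gene id so runs are deterministic, and genes missing from the expression
table are never flagged but counted in a report.

**CAI.** Relative adaptiveness $w_c = f_{\mathrm{ref}}(c) / \max_{c' \in a}
f_{\mathrm{ref}}(c')$, and CAI is the geometric mean of $w$ over the gene's
counted codons excluding Met, Trp and stops. Reference codons with zero count
get the standard pseudo-count $w = 0.5/\max$-count, which keeps the geometric
mean finite without distorting observed preferences; a family wholly absent
from the reference is uninformative and scores $w = 1$. CAI is invariant to
rescaling reference counts.

**COUSIN.** CAI compresses everything into $[0,1]$; the COUSIN index instead
normalizes against the null of equal synonymous usage, which makes the value
interpretable as a similarity *direction and magnitude*: 1 means the query
shares the reference preferences, 0 means equal usage, values in $(0,1)$
the same direction at smaller magnitude, above 1 exaggerated, below 0
opposite. Per degenerate family present in the query whose reference usage is
non-uniform,

$$\mathrm{num}_a = \sum_c f_q(c)\,(f_r(c) - e_a), \qquad
  \mathrm{den}_a = \sum_c f_r(c)\,(f_r(c) - e_a), \qquad e_a = 1/k_a .$$

The family-weighted variant (`cousin18`) averages $\mathrm{num}_a /
\mathrm{den}_a$ over families; the amino-acid-weighted variant (`cousin59`)
is $\sum_a n_a \mathrm{num}_a / \sum_a n_a \mathrm{den}_a$ with $n_a$ the
query's amino-acid counts. The 59-variant is implemented as a ratio of
weighted sums rather than a weighted mean of ratios: that form both matches
"each family contributes proportionally to the frequency of the corresponding
amino acid in the query" and preserves the anchors exactly (query = reference
gives 1, uniform query gives 0, identically, for any reference). These five
anchor behaviours (1, 0, below 0, between 0 and 1, above 1) are the binding
contract of the implementation; degenerate-family edge cases (uniform
reference families, families unseen in the reference) are excluded from both
variants symmetrically.

## Robust comparison of score distributions

Per-CDS score distributions are heavy-tailed — a handful of genes in any
genome have extreme composition — so group centres are compared robustly:

* **Huber M-estimator of location** (`huberLocation()`): iterated winsorized
  mean, scale fixed at the MAD, tuning constant $k = 1.5$ (the conventional
  default of robust-location routines, cross-checked in the tests against an
  independent implementation). Zero MAD falls back to the median.
* **MAD** (`madScale()`): normal-consistent constant 1.4826.
* **Wilcoxon rank-sum with continuity correction** (`wilcoxonRankSum()`):
  mid-ranks for ties, tie-corrected variance, two-sided normal approximation.
  For group sizes of roughly 5 and above the approximation agrees with exact
  rank enumeration to within 0.02; below that, and exactly at the
  distribution centre under heavy ties, the discrepancy can reach a few
  hundredths — an inherent property of the approximation worth remembering
  when groups are tiny. Identical constant samples are flagged and given
  $p = 1$ by convention.
* **Hodges-Lehmann location difference** (`locationDifference()`): median of
  all pairwise differences, oriented **host − virus** so that an
  opposite-preference virus against a self-similar host yields a positive
  shift and an exaggerated virus a negative one. Beyond $10^7$ pairs a seeded
  uniform subsample is used; on 500 x 500 inputs the subsampled estimate
  agrees with full enumeration to well under 0.01.

`compareDistributions()` assembles all of this plus empirical 2.5/50/97.5
percentiles per group. Density-curve figures in this literature draw three
lines inside each curve for a "95% confidence interval" without defining
them; we interpret and implement them as those empirical percentiles of the
score distribution (rather than a bootstrap interval of the centre), and
label them as such in exports. Text rendering follows the conventional
report style, printing vanishingly small p-values as "< 2.2e-16" while the
stored value keeps full precision. No multiple-testing correction is applied
across virus families, matching how such panels are conventionally reported.

## The synthetic data generator

`makeHostCut()` builds a host-like codon usage table from two interpretable
dials: a GC3 target and a bias strength. Within each family, preference
weights are softmax-tilted toward (or away from) G/C-ending codons; the tilt
is calibrated by root-finding so that at bias strength 1 the realized table
GC3 lands on the target (within 0.05; the code's floor is about 0.1 because
ATG and TGG are invariant and G-ending). A seeded perturbation, centred
within each family's third-base classes so it does not move expected GC3,
gives families distinct top codons the way real genomes have them. Bias
strength 0 yields the exactly uniform table (plug-in ENC 61). The defaults
used throughout the tests emulate the empirical spread of amoeba genomes:
GC-rich hosts around GC3 0.8 (the *Acanthamoeba* pattern) and AT-rich hosts
around 0.25 (the *Naegleria*/*Willaertia* pattern).

`deriveRegimeCut()` turns a host table into the four virus regimes that span
the COUSIN quadrants: *matched* (copy; COUSIN 1), *equal_usage* (uniform
families; COUSIN 0), *opposite* (frequencies reflected about equal usage,
$f' \propto \max(2e_a - f, \varepsilon)$ with floor $\varepsilon = 0.01$ so
no codon becomes impossible and CAI stays defined), and *exaggerated*
($f' \propto f^\gamma$, $\gamma = 2$ by default). Amino-acid totals are
preserved so only within-family preferences change.

`simulateCdsSet()` draws, per gene, a length (normal in codons, mean 300, sd
80, floored at 10 — a typical protein-length scale), amino acids (uniform
over the 20 by default; the field lacks a canonical amoeba proteome
composition, and the frequencies are configurable), and codons from the
regime table's synonymous frequencies. Expression is log-normal, and the
expression-bias link raises the sampling frequencies to
$1 + \text{biasLink} \cdot \max(0, (q - 0.8)/0.2)^2$ at expression quantile
$q$: only the upper expression tail sharpens its codon usage (lower ENC),
which is the empirical ENC-plot pattern, while the bulk of genes keep the
table's preferences so regime centres stay on their anchors. One global seed
drives a per-gene seed sequence, so rerunning is byte-identical and a
10-gene run is a prefix of a 500-gene run.

What the generator deliberately does **not** emulate: amino-acid composition
differences between genes, codon autocorrelation along a gene, isochore /
regional mutational-bias variation within a genome (the *V. vermiformis*
pattern), annotation errors other than length trimming, and any realistic
read-level FPKM noise. Passing tests therefore demonstrate that the
statistics and their comparisons behave correctly under the stated model —
not that any particular biological dataset will reproduce a given number.

`plantEveRegion()` provides the analogous ground truth for the genome
scanners: a background contig at one GC content with an embedded region at
another, optionally flanked by exact reverse-complement arms.

## Scanning for integrated viral regions

`gcProfile()` computes windowed GC% and AT% over counted (non-N) bases,
0-based half-open coordinates, trailing partial window included and marked.
With step = window the windows partition the contig and the base-weighted
mean of window GC reconstructs whole-sequence GC exactly. There is no
canonical window size for such figures; the defaults (window 1000, step 500)
resolve multi-kb insertions well and are configurable.
`regionGcContrast()` reports mean windowed GC inside versus outside a
candidate region (windows assigned by midpoint) and their difference; a
"notable" difference is not a defined quantity in this literature, so the
tool reports the delta and only the CLI summary applies a configurable flag
threshold (default 5 points).

`findTerminalInvertedRepeats()` locally aligns the start of a candidate
region against the reverse complement of its end (match +1, mismatch −1,
gap −2) and reports arms of at least `minArm` bases whose mismatch-plus-indel
fraction is at most `maxMismatchFrac`. The scan runs at several terminal
window sizes (down from `maxSearch` to a few arm lengths): a genuine terminal
arm sits at the region boundary and survives every window, whereas in a wide
window a long, noisy internal alignment can outscore a short genuine arm and
would otherwise mask it. Candidate regions themselves are accepted as BED
input — identifying them by homology (protein searches against viral capsid
databases) is a separate, heavier problem this package deliberately leaves to
dedicated tools.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make Monte-Carlo checks stable yet quick: 500-gene CDS sets
for regime-recovery checks (per-gene COUSIN centres are then stable to a few
hundredths), 200 random small genes for brute-force oracle equivalence at
$10^{-9}$, and 30 kb contigs with 8 kb planted regions for the scanners. All
randomness flows from explicit seeds; CLI runs write provenance records
(inputs, parameters, seed, version) and atomic outputs so any table can be
regenerated byte-identically.

## Known limitations

* Set-level (pooled) scores weight genes by length; per-CDS distributions
  weight them equally. Both are exposed (`pooledScores()`, `scoreSet()`)
  because they answer different questions.
* The ENC observed-family convention makes very short genes comparable, but
  ENC for genes under ~100 codons remains noisy; the bias-corrected estimator
  mitigates, not removes, this.
* COUSIN values for genes that share only one or two informative families
  with the reference are effectively single-family ratios and can be extreme;
  they are reported as computed, never clipped.
* The Wilcoxon p-value is a large-sample approximation; see above for its
  small-n behaviour.
* tRNA inventories, codon-pair bias and RSCU heat maps are out of scope; the
  indices here summarize single-codon usage only.
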