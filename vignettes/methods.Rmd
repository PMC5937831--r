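---
title: "Methods: screening small RNA libraries for heat- and spermidine-responsive miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening small RNA libraries for heat- and spermidine-responsive miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The design

`spidmir` implements a classic single-library small RNA-seq screen over a
2 × 2 condition design: control temperature vs heat stress, crossed with a
water spray vs a foliar spermidine (Spd) spray. The four libraries are
labelled CW (control/water), CS (control/Spd), HW (heat/water) and HS
(heat/Spd). The screen asks which miRNAs respond to heat, which to Spd, and
— the headline set — which respond to both, as candidates for mediating
Spd-dependent heat tolerance. With one pooled library per condition there
are no biological replicates; inference rests on exact count statistics and
on the intersection structure of four comparison pairs, and an auxiliary
two-way ANOVA (on replicated expression measurements) checks the
temperature × Spd interaction for the selected set.

# Read filtering

Reads are filtered by seven rules applied in a fixed order, each read
attributed to the first rule it fails:

1. low quality: at least 4 bases with quality < 10 (phred64 decoding, i.e.
   ASCII − 64, valid range 0–41; phred33 selectable);
2. too many undetermined bases: proportion of N above 10%. The source
   convention says only "greater than 10"; we read it as 10 *percent*,
   since a proportion is dimensionless;
3. 5′ primer contaminant: the read starts with the 5′ adapter (8 nt seed);
4. no insert: the 3′ adapter starts at position 1;
5. no 3′ adapter: neither a full-adapter match nor a terminal adapter
   prefix of ≥ 6 nt. Matching is exact; the terminal-prefix fallback
   handles adapters truncated by the read end;
6. poly(A): the trimmed insert is ≥ 80% adenine (threshold configurable;
   no published value exists);
7. short: the trimmed insert is below 18 nt. Inserts longer than 30 nt are
   retained — the 18–30 nt range is enforced at the gel-excision stage of
   the protocol, not computationally.

Accounting closes by construction: `high_quality = total − (1) − (2)` and
`clean = high_quality − (3) − (4) − (5) − (6) − (7)`; percentages are
reported against the high-quality count, rounded half-up to two decimals,
which is the convention that reproduces published cleaning-summary tables.
Identical inserts are collapsed into unique tags with per-library counts —
the unit all downstream stages operate on.

# Annotation hierarchy

Tags are mapped to the genome exactly (no mismatches, both strands) and
classified by priority:

rRNA > snRNA > snoRNA > tRNA > repeat > exon (sense, antisense) >
intron (sense, antisense) > known miRNA > unannotated.

The priority mirrors the sequential removal order of the original pipeline
(structural RNA and degradation fragments are removed before miRBase-style
matching). The published procedure does not state how multi-category
overlaps were resolved; the fixed priority is our documented convention. A
tag is accepted as a known miRNA iff it matches a reference precursor
perfectly and overlaps the annotated mature sequence by at least 16 nt;
ties go to the longest mature overlap, then the lexicographically smallest
name. Each read counts once, toward its single category.

# Novel miRNA candidates

Unannotated tags with genome hits seed a hairpin search in ±100 nt flanking
windows. True thermodynamic folding (the MFE criterion of Mireap-style
tools) is deliberately replaced by a self-contained pairing model: over
every antiparallel ungapped stem placement we maximize
`WC + 0.5·G:U − 2·mismatch` (a contiguous run along an anti-diagonal, loop
≥ 3 nt), and report `score = −(WC + 0.5·G:U)` of the chosen stem as the
stability proxy. The mismatch penalty of 2 sets the detector's operating
point: at the default score threshold of −14, over 95% of random 100-mers
are rejected. A candidate requires ≥ 14 paired bases inside the mature tag,
a score ≤ −14, and the tag ends within 3 nt of a stem end (a Dicer-cut
proxy). Overlapping loci merge (a hairpin seen from both strands is one
locus), and candidates expressed in fewer than two libraries are dropped,
mirroring the published one-library rule. All thresholds are conventions
exposed in `novel_params()`, not literature facts, and an external folding
engine can substitute scores.

On planted-hairpin-only input the detector attains perfect recall and
precision (tested); on full synthetic genomes occasional chance stems in
random intergenic windows pass, as they do for real predictors — these
candidates are flat across libraries and never reach the responsive sets.

# Differential expression

Counts per miRNA (summed over its tags) are normalized to transcripts per
million of clean reads: `TPM = count / clean_total × 10⁶`. Zeros are
imputed to 0.01 *only* for ratio computation; miRNAs expressed in a single
library are excluded entirely. For each ordered pair (CS/CW, HW/CW, HS/CW,
HS/HW; the second library is the control) the fold change is
`log2(TPM_treat / TPM_ctrl)` and significance requires `|log2FC| > 1`
(strict) and `p < 0.05`, with `**` marking `p < 0.01`. No multiple-testing
correction is applied by default, for fidelity to the original screen; a
BH option exists.

The p-value is an exact tag-count test: conditional on the total
`t = x + y`, the count in library 1 is `Binomial(t, N1/(N1+N2))` under the
null of equal concentrations, and the two-sided p-value is
`min(1, 2·min(P(X ≤ x), P(X ≥ x)))`. We chose the conditional-binomial form
of the classic Audic–Claverie-type test rather than the negative-binomial
posterior-predictive form because only the former satisfies the exact
symmetry `p(x, y, N1, N2) = p(y, x, N2, N1)` and gives `p = 1` at
`x = y = 0` for unequal depths — properties the screen's swap-invariance
relies on. The method is recorded in the output metadata and pluggable.

# Four-pair screening

Significant sets from the four pairs are intersected Venn-style. Rules:
heat-responsive = significant in HW/CW and HS/CW; Spd-responsive =
significant in CS/CW, HS/CW and HS/HW; both-responsive = significant in
all four pairs (taking precedence). Direction patterns record the sign of
the fold change in the member pairs only and are summarized as all-down /
all-up / inconsistent; the characteristic sign-flip pattern (down in three
pairs, up in HS/HW) marks miRNAs whose Spd response differs between
temperatures. Known and novel miRNAs are screened separately and reported
jointly.

# Targets and enrichment

Mature sequences of the both-responsive miRNAs are scanned ungapped against
every transcript window of equal length. The penalty is
mismatch = 1, G:U = 0.5, doubled at miRNA positions 2–13. Two presets stand
in for the two external engines whose intersection defined the published
call: strict (penalty ≤ 4.0, no mismatch at positions 10–11) and relaxed
(penalty ≤ 5.0). The cited alignment criteria are not reproduced in the
source, so the presets are honest conventions — named as such, not claimed
identical to TargetFinder or psRobot — and the relaxed preset stays ungapped
(no bulge model) to keep the scoring exact and enumerable. A gene is a
target only if found under both presets.

Term enrichment is the upper-tail hypergeometric probability of seeing ≥ k
term genes among the n targets given K of N background genes, corrected per
term class (Benjamini–Hochberg by default; the published "corrected
p-value" does not name a method, so the choice is recorded in output
metadata and switchable to Bonferroni). The background is the whole bundled
transcriptome.

# Growth contrasts

Trait tables (means ± SD over 8 replicate seedlings) are summarized with
sample statistics, and treatment contrasts are percent changes rounded
half-up to two decimals — the convention that reproduces the published
growth percentages from the printed means, with one exception: the printed
plant-height response to Spd under heat (17.10%) is 17.1053% from the
printed means, so it was evidently computed from unrounded data; the test
suite asserts agreement at printed precision there. Post-hoc grouping
letters are preserved as opaque annotations (the replicate-level data
needed to recompute them is unpublished).

# The synthetic world

`simulation_config()` states the world the tests assume; its defaults are
not tuned to outcomes:

* four libraries of 100,000 reads (depth is configuration, as published
  totals describe multi-million-read libraries the desk-scale tests do not
  need); read length 36 nt, inserts 18–30 nt plus 3′ adapter, phred64
  qualities drawn from 30–41 for clean reads;
* contaminant classes injected at rates echoing the published cleaning
  summaries (≈ 0.09% quality/N removals, ≈ 2.8% short inserts, ≈ 0.4%
  missing 3′ adapter, ≈ 0.1% 5′ contaminants, ≈ 0.01% each no-insert and
  poly(A)); each contaminant is constructed to fail exactly its intended
  rule, so filter accounting is exactly recoverable;
* a ~100 kb two-contig genome carrying disjoint structural-RNA, repeat,
  exon and intron loci; 48 known miRNAs in 20 families (echoing the
  published family diversity at reduced scale) planted as
  mature–loop–star precursors; six novel hairpins (perfect 20–22 nt
  inverted repeats around an 8–40 nt loop, with two interior star
  mutations so arm tags map uniquely);
* clean-read composition echoing the published classification table:
  ≈ 18% rRNA, ≈ 1.7% tRNA, ≈ 20% known miRNA, ≈ 55% unannotated, the rest
  spread over the minor categories;
* planted effects: eight both-responsive miRNAs (five all-down, two with
  the published sign-flip pattern, one inverse), four heat-only and three
  Spd-only, every planted pairwise ratio ≥ 4×; baselines (2,500 expected
  CW reads per 100,000 for the main set) chosen so the weakest planted
  signal still sits several sampling standard deviations from the
  fold-change threshold;
* a 60-gene transcriptome in which five of the eight both-responsive
  miRNAs carry planted perfect-complement sites (1–12 genes each; three
  carry none), and a term map with one deliberately concentrated pathway
  term as enrichment ground truth.

The generator emulates sampling noise (multinomial reads over true
proportions) but not sequencing errors, isomiR heterogeneity, adapter
dimers or ligation bias; a green recovery test therefore establishes the
correctness of the statistical machinery on the stated world, not
robustness to artefacts the world omits. True expression recorded in the
manifest is the exact post-renormalization sampling proportion, so
recovery tests compare against the actual truth rather than the nominal
effect.

# Numerical and degenerate-input choices

* Percentages use half-up decimal rounding (base R rounds halves to even).
* All randomness flows from the single configuration seed through scoped
  RNG (caller state restored); a fixed seed reproduces FASTQ and manifest
  byte for byte.
* Quality decoding rejects out-of-range characters with a hint naming the
  other encoding.
* `twoway_anova()` refuses unbalanced or under-replicated designs and
  returns a degeneracy flag (rather than NaN F statistics) on
  zero-variance input.
* Stem-search ties: when several stems attain the same pairing objective,
  the first in diagonal order is reported deterministically; tests
  therefore compare the objective value against exhaustive enumeration,
  and exact layouts only where the optimum is unique.
* Venn regions, screening classes and DE tables are sorted
  deterministically so repeated runs are byte-identical.

# Known limitations

Single-library screens cannot separate biological variability from
condition effects; the exact tag-count test treats each library as one
sample and its p-values are anti-conservative relative to replicated
designs — the published protocol is reproduced as stated, not endorsed.
The hairpin detector is a pairing-score stand-in for thermodynamic
folding; the target presets approximate, but are not, the external
engines; and the enrichment background is the bundled transcriptome rather
than a genome-wide annotation.
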