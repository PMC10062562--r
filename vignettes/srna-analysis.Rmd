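---
title: "Methods: small RNA classification, dependency calling and signature tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA classification, dependency calling and signature tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapipe)
```

## The analysis model

srnapipe implements the standard desk workflow for dissecting small-RNA
biogenesis in a knockdown panel. The input is a set of *collapsed*
libraries — each unique read sequence paired with its copy count — one per
condition: a dsGFP control plus dsRNA knockdowns of candidate biogenesis
factors (Argonautes, PIWI proteins, RdRPs). Five analysis stages sit on
top of the classification core.

### Sequential hierarchical classification

Reads are matched *exactly* (no mismatches) against every reference
sequence on both strands, mirroring the `bowtie -v 0` convention for
small-RNA annotation. Assignment is sequential: a read belongs to the
first category in the hierarchy order (default miRNA, RNAPIII, rRNA,
snoRNA_mRNA, repeat) with at least one hit; reads hitting only the genome
background fall in the `genome` sink; the rest are unmapped. This
winner-takes-first rule makes category totals conserve: summed category
counts plus the genome sink equal the total of mapped copies, and category
percentages sum to 100%.

Two counting conventions coexist deliberately. A read contributes its
copies exactly once to its category total, but within the assigned
category its profile rows are added at *every* locus it hits. Per-locus
remapping double-counts multi-mapping reads in exactly this way, and
per-locus size profiles would otherwise be biased against repeat families.
A fractional split across loci is a conceivable alternative; we kept full
counting because the downstream dependency rule operates on ratios, which
uniform multi-counting leaves untouched.

Coordinates are 0-based half-open. The 5′ end of an antisense read lies at
reference position `start + length − 1`; recording 5′ ends in reference
coordinates on both strands makes the ping-pong geometry below a pure
difference of positions.

Abundances are normalised to reads per million genome-mapping reads (RPM):
`count / total_mapped × 1e6`, with `total_mapped` the summed copies
hitting any reference or background sequence in that library. RPM is
depth-invariant by construction, which the dependency tests exercise
directly.

### Dependency calling

For each locus, the fold change in a knockdown library is
`RPM_kd / RPM_control`. A locus is *dependent* on a factor when the fold
change is strictly below `1 − reduction` (default reduction 0.4, i.e.
reduced by more than 40%) in any library targeting that factor. Three
conventions matter and are all read literally from the field's practice:

* **Strict inequalities.** Fold change exactly 0.600 is *not* dependent;
  mean RPM exactly at the expression threshold is *not* retained; Z
  exactly at the critical value is *not* significant. Boundary tests pin
  each of these.
* **Expression filters** retain loci with mean RPM strictly above a
  threshold across all libraries of the panel — 35 RPM for coding loci,
  800 RPM for repeat families in the reference analysis. The threshold is
  a tunable argument.
* **AGO3 merging.** Two independent dsRNA constructs targeting the same
  AGO3 gene are merged into one factor: dependency if *either* library
  shows the reduction. `merge_ago3 = FALSE` keeps them separate for
  construct-level comparisons.

One ambiguity deserves a note: descriptions of PIWI-dependent repeats
sometimes phrase the same rule as "reduced (<60%)". We implement fold
change < 0.6, consistent with the >40%-reduction reading; the two agree on
every example we could construct.

Loci with zero control RPM have undefined ratios; they are flagged and
excluded from calls rather than given a pseudo-count, because a dependency
call on an unexpressed locus is meaningless. The separate
`fold_change_table()` (for scatter displays) *does* use a symmetric
pseudo-count, default 0.5 RPM, so zero-count loci stay plottable:
`log2((kd + 0.5)/(control + 0.5))`.

No variance model is attempted: the design has one library per factor
(n = 1), so the deterministic threshold rule is the honest analysis;
replicate-aware extensions are out of scope.

### Ping-pong overlap signature

PIWI slicing cuts the target opposite nucleotides 10 and 11 of the guide,
so ping-pong pairs show a 10-nt 5′-5′ overlap. With sense 5′-position
counts c₊(p) and antisense counts c₋(q) at one locus, every position pair
contributes `c₊(p)·c₋(q)` to the score at distance `d = q − p + 1`
(complete 10-nt overlap ⇒ d = 10), summed over loci for d = 1…25 within
the piRNA length window (default 25–30 nt).

Numerical choices, each exposed as an option:

* **Product weighting** of collapsed counts (not `min`), matching the
  additive position-count formulation; a `weight = min`-style sensitivity
  analysis can be run by collapsing counts to 1.
* **Z-scores over all 25 distances**, `z(d) = (s(d) − mean s)/sd s`, with
  the *population* sd (divisor 25): the scanned distances are the entire
  population of interest, and the focal distance is not excluded from the
  background (an `exclude_d0` option exists).
* **Degenerate signatures** (zero variance, e.g. empty windows) get all-zero
  Z-scores, a raised flag, and are never significant.
* **Critical value 2.58**, the two-sided standard-normal quantile at
  p = 0.01, with a strict `>` comparison.

The background of 25 scores is not i.i.d. normal, so the nominal 1% level
is not asserted anywhere; the specificity test instead checks empirically
that unpaired panels rarely cross the threshold.

### Terminal chemical structure

Periodate oxidation destroys 3′ ends carrying vicinal 2′,3′-OH groups
(they can no longer be ligated), so a class *enriched* in the oxidised
library is 2′-O-methylated and a *depleted* class has free 2′,3′-OH.
Terminator exonuclease removes 5′-monoP species, so enrichment in that
library indicates 5′ di/tri-phosphates, while an abundant class showing no
enrichment is 5′-monophosphorylated. The comparison statistic is the
pseudo-counted RPM ratio `(rpm_treated + 1)/(rpm_standard + 1)` with
symmetric 2-fold calls (enriched ≥ 2, depleted ≤ 0.5). The underlying
laboratory readout is qualitative; the symmetric 2-fold default is this
package's documented operating point, not a published cutoff. A
`min_standard_rpm` guard (default 10 RPM) makes the monoP call
*indeterminate* for scarce classes, where absence of enrichment carries no
information — single species would be confirmed by Northern blotting,
which has no computational counterpart.

### PolyA status and sRNA production

mRNAs lacking polyA tails are enriched in rRNA-depleted (total) RNA-seq
relative to polyA-selected RNA-seq. In (x, y) = (log2 polyA TPM+1,
log2 total TPM+1) space, spliceosomal RNAs — non-polyadenylated by
construction — define an OLS baseline (all points used, no outlier
trimming); coding genes strictly above the line (zero margin by default,
with a `margin` option) are polyA(−). To match expression levels, the
minimum y among polyA(−) genes is the cutoff below which polyA(+) genes
are excluded from comparisons. sRNA production (log2 RPM+1) between the
groups is compared by a two-sided Wilcoxon rank-sum test via
`stats::wilcox.test`, which uses the exact distribution for group sizes
below 50 without ties and the tie-corrected normal approximation
otherwise — on the canonical fully separated 3-vs-3 configuration the
exact two-sided p is 0.1.

## The synthetic generator

The generator is first-class, tested code: it is the oracle for every
stage. `generate_references()` draws random locus sequences (default
200 nt, background 5 kb) and *screens at construction time* so no 18-mer —
on either strand — is shared between any two sequences. Every generated
read of ≥ 18 nt therefore maps to exactly one locus, keeping planted truth
crisp. `generate_libraries()` plants:

* **The ten-condition design** (dsGFP control plus dsAgo-16, dsAgo-30,
  dsAgo-78, dsAgo-96, dsAub, dsAGO3-1, dsAGO3-2, dsRdRP1, dsRdRP3), with
  knockdown modelled as a pure multiplicative reduction (default
  efficiency 0.8) of dependent classes and Poisson-realised per-locus
  counts. No off-target effects are simulated.
* **The default class panel** mirrors the endogenous populations: a 5′U
  22-nt miRNA class (Ago-78-dependent), a double-stranded 22-nt class from
  RNAP III loci (RdRP1 + Ago-30; 2′-OH, 5′-monoP), a repeat 22-nt siRNA
  class (RdRP3 + Ago-16), a repeat 25–30 nt piRNA class (Aub + AGO3,
  2′-O-me, ping-pong fraction 0.3, 5′U) and a factor-independent viral
  22-nt class. Together they reproduce the bimodal 22 / 26–29 nt length
  profile.
* **5′-nucleotide bias** is realised by weighting candidate start
  positions by the bias of the base they would expose, so reads remain
  exact substrings of their locus — a vectorised equivalent of rejection
  sampling over starts.
* **Ping-pong pairs**: a fraction ρ of a class's reads is emitted as
  guide/partner pairs with the antisense 5′ end placed opposite the
  guide's 10th nucleotide (d = 10 exactly).
* **Chemical treatments** are binomial thinnings of copy counts with
  per-state retention probabilities (oxidised: 0.95 for 2′-O-me, 0.05 for
  2′-OH; 5′-polyP enrichment: 0.9 for polyP, 0.05 for monoP). The real 5′
  protocol involves re-phosphorylation steps of unquantified efficiency;
  these retention values are engineering choices, flagged as such.

Default abundances are a few hundred to a few thousand expected copies per
locus, giving libraries of roughly 10⁴–10⁵ copies — two to three orders of
magnitude below real sequencing depth. This is the scale at which the full
panel (10 libraries × 20 seeds in the recovery tests) runs in a couple of
minutes; the planted effects (5-fold knockdown at ≥ 500 copies/locus)
dominate Poisson noise by a wide margin at this scale, so recovery rates
are informative about the rules, not about depth. What the generator does
*not* emulate: sequencing error, PCR duplication, adapter artifacts,
mismatch-tolerant mapping, shared sequence between references
(multi-mapping is screened away by construction), and any transcriptional
response to the knockdowns. Passing tests therefore validate the
*inference rules*, not robustness to real-library noise sources.

## Degenerate inputs and edge behaviour

* Reads with ambiguous bases (N) are rejected at parse time — whether the
  original pipelines discarded them pre-mapping is unstated, so rejection
  is this package's explicit choice. Reads outside 15–35 nt are dropped at
  parse with a logged count; the analysis window (default 18–30 nt) is a
  separate, downstream filter.
* Duplicate sequences in one FASTA merge by summing counts, with a
  warning. Writing an empty library is refused.
* Empty profiles give all-zero overlap scores (not an error); zero-variance
  score vectors are degenerate, never significant.
* A locus absent from one library contributes an RPM of 0 there; a control
  RPM of 0 voids the locus's dependency call.
* With no gene above the polyA baseline, the expression cutoff is
  undefined and exclusion is skipped with a warning.

## Interface note

All functionality is exposed as documented R functions; the worked example
in the README and `scripts/acceptance.R` show the intended composition.
Tabular outputs are written with `write_table()` (TSV, full numeric
precision), references round-trip through YAML manifests plus per-category
FASTA, and collapsed libraries through `">name_count"` FASTA headers (a
whitespace dialect is supported on input).
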