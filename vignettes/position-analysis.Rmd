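---
title: "Conserved and family-specific positions in superfamily alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved and family-specific positions in superfamily alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fspscan)
```

## The problem

A functionally diverse enzyme superfamily — the motivating system is the
fold-type I, PLP-dependent aspartate aminotransferase superfamily, which
spans aminotransferases, aldolases, decarboxylases and more on one
structural scaffold — carries two complementary layers of sequence signal.
Positions conserved across the whole superfamily support the shared
catalytic machinery (in the motivating system, the Schiff-base lysine, the
aspartate that protonates the cofactor's pyridine nitrogen, and the
arginine that docks the substrate α-carboxylate). Family-specific
positions (FSPs) are conserved *within* each functional family but
occupied by *different* residues in different families; they shape the
active-site microenvironment and are candidate determinants of reaction
and substrate specificity, hence natural hotspots for specificity
engineering.

`fspscan` implements the sequence-analysis side of that programme as a
reusable, fully testable pipeline: set cleaning, core-guided merging of
family sub-alignments, specificity-group inference, column statistics,
and reference-numbered reporting. The structural steps that produce the
core alignment in the original protocol (structure searches, 3D
superposition, loop rebuilding) are out of scope: the core alignment is
consumed as an input.

## The model and its statistics

For an alignment of $n$ sequences partitioned into $K$ families, each
column $j$ yields a profile of residue counts, overall and per family.
Gaps and the ambiguity codes B/Z/X are treated as missing: excluded from
counts, but accumulated into the column's gap fraction.

**Conservation** is the frequency of the most common residue among the
column's effective observations. A column is called `conserved` when this
reaches `conserved_min_freq` (default 0.98). We deliberately do not
require literal invariance: in a superfamily set of thousands of
database-derived sequences, even a functionally invariant site shows
sporadic deviations, and the motivating analysis itself reports an
"invariant" arginine that an entire family replaces by valine. A column
falling below the threshold is still called `conserved_with_exceptions`
when the overall consensus is the within-family consensus residue (at
frequency at least `fsp_min_within_family_consensus`, default 0.9) in all
but at most `exception_max_families` families (default 1); the deviating
families are reported.

**Family specificity** is measured by the plug-in mutual information (in
bits) between residue identity $a$ and family label $f$ over the column's
effective observations,

$$\mathrm{MI}_j \;=\; \sum_{a,f} p(a,f)\,
  \log_2 \frac{p(a,f)}{p(a)\,p(f)},$$

computed as $H(A)+H(F)-H(A,F)$ and normalised, when wanted, by
$\min\{H(A), H(F)\}$. This statistic is this package's own choice — the
original analysis delegated FSP scoring to a web service whose internal
statistic is not published, so no numerical equivalence with any server
is claimed, and every output table is labelled with the statistic name.

**Significance** comes from a label-permutation null: for each of $B$
iterations one permutation of the family labels is drawn and applied to
*all* columns, preserving the inter-column dependence structure of the
null; $p_j = (1 + \#\{b: \mathrm{MI}_{j,b} \ge \mathrm{MI}_j\})/(B+1)$,
with a z-score from the permutation mean and standard deviation.
Benjamini–Hochberg FDR control is applied across all non-masked columns.
A column is called `fsp` when $q \le$ `fdr_q` (default 0.05), at least
`fsp_min_distinct_consensi` (default 2) distinct within-family consensus
residues occur, and at least two families are conserved at the column.
Columns gappier than `gap_mask_threshold` (default 0.5) are `masked`;
everything else is `variable`. Every column receives exactly one class,
in the fixed precedence masked → conserved → conserved-with-exceptions →
fsp → variable.

### Numerical choices

Ties for a consensus residue (overall or within a family) are broken
alphabetically. Permutation MI values are compared with the observed
value with a $10^{-12}$-bit tolerance so that permutations reproducing
the observed MI exactly (e.g. label swaps of a symmetric column) count as
ties rather than falling on one side of floating-point noise. With all
permuted MIs equal (an invariant column), the z-score is defined as 0 and
$p = 1$. The smallest attainable p-value is $1/(B+1)$; with $m$ tested
columns, BH can therefore only reject when the tied floor rank reaches
$m/((B+1)\,q)$, which is why the default is $B = 1000$ — at $q = 0.05$
and a few hundred columns, a handful of genuinely diagnostic columns at
the floor is then sufficient.

## Set cleaning and merging

Family sequence sets assembled from database searches are cleaned per
family, relative to the family representative: sequences scoring under
`min_bits_per_column` (default 0.5 bits; BLOSUM62 half-bit scores halved
and averaged over mutually non-gap columns, no gap penalties) or
differing from the representative by more than `max_length_diff` (default
20%, strictly greater, measured on ungapped lengths) are outliers; then a
greedy keep-first sweep removes any sequence at or above
`identity_threshold` (default 0.95) identity with an already-retained
one, the representative always first; finally at most
`max_seqs_per_family` (default 1000) are kept. Identity is computed on
the induced pair from the sub-alignment, over columns where both
sequences carry standard residues — the standard convention for
intra-alignment redundancy filtering and insensitive to terminal gaps.
Outliers are removed before redundancy because redundancy among discarded
outliers is irrelevant. Both filters are deterministic and idempotent.

Merging threads each family's sub-alignment onto the core alignment of
representatives. Sub-columns holding a representative residue land in
that residue's core column; sub-columns where the representative is
gapped become family-private insert columns, attached immediately after
the preceding representative residue's core column (leading insertions
anchor before the first core column), with same-anchor blocks from
different families in family input order. Insertions from different
families are never aligned to each other: without structural information
such columns are not comparable, so they occupy disjoint columns and
every other family carries gaps there. This preserves, exactly, all
within-family residue correspondences of each sub-alignment and all
between-representative correspondences of the core — the property the
test suite checks against a brute-force correspondence extractor on
randomized fixtures.

## Specificity-group inference

When no family annotation is available, sequences are clustered by
average-linkage hierarchical clustering on the distance
$1 - \text{identity}$, and the group count $k$ is chosen from a scanned
range by maximizing $Q(k) = W(k) - B(k)$, where $W$ is the mean (over
groups and non-masked columns) within-group top-residue frequency and
$B$ the mean (over non-masked columns) fraction of group pairs whose
group consensus residues agree — within-group conservation traded
against between-group agreement. The original analysis states this
objective only verbally ("maximizing sequence conservation within the
groups and sequence variability between the groups"); $W - B$ over
average-linkage candidate partitions is this package's concrete,
deterministic instantiation, recorded in the output metadata. Ties go to
the smaller $k$; groups below `min_group_size` (default 2 — singletons
cannot exhibit conservation) are merged into the group at smallest mean
distance before scoring. Identity-based clustering presupposes families
coherent across much of the alignment (the regime of the original data,
roughly 85% within- and 25% between-family identity); it is not expected
to work when families differ only at a handful of diagnostic columns.
When an annotation is supplied, this stage is bypassed entirely.

## The synthetic generator

`generate_alignment()` draws alignments with planted column roles:
conserved columns (planted residue, per-sequence deviation rate),
exception columns (majority residue everywhere except one family),
FSP columns (per-family residue map, deviation rate) and background
columns (i.i.d. from a configurable distribution, uniform by default —
uniform maximizes null entropy and is the hardest case for false
conservation calls). Gaps are overlaid per cell; by default planted
columns are gap-protected so recovery tests isolate the statistics from
gap masking, and an unprotected mode exercises masking. The ground truth
is recorded by the generator itself, never inferred post hoc.

The default validation conditions used by the acceptance checks are 5
families × 50 sequences × 300 columns, with 5 conserved columns at 1%
deviation, one exception column, 10 FSP columns at 5% deviation, 2%
protected gaps, 500 permutations and $q \le 0.05$; the null-calibration
check uses the same dimensions with no planted columns over 20 replicate
seeds at $B = 499$ (odd $B$ centres the attainable p-grid so that
$P(p < 0.05) = 24/500$ under the null), and clustering recovery uses 3
families × 12 sequences × 120 columns in the 85%/25% identity regime.
These sizes are the package's chosen study conditions; they keep the full
validation suite to a couple of minutes on one CPU.

What the generator does *not* model matters for interpretation: families
are i.i.d. within family, with no phylogeny. Real families are
tree-correlated, which inflates apparent within-family conservation and
mutual information relative to the i.i.d. null; recovery rates measured
here therefore bound the statistical machinery, not the field behaviour
of the method on real superfamilies. Indel structure is likewise a
per-cell gap rate, not an evolutionary indel model, and family-correlated
gaps are deliberately excluded from the MI observations (gap masking) —
indel signal is a recorded limitation, not a feature the statistic
claims to capture.

## Reference numbering and reporting

Reported positions are labelled in the residue numbering of each family's
representative (e.g. `K199` style), via the count of non-gap characters
up to the column plus a configurable starting number, so outputs can
match PDB numbering; a gap in the representative renders `N/A`. The
family × position table puts conserved-type positions first (in column
order) and FSPs after, ordered by descending permutation z-score. The
table is a pure function of the classification result — re-rendering
never recomputes statistics — and the provenance block (config echo,
statistic name, package version) suffices to reproduce a run.

## A worked run

```{r example, eval = FALSE}
cfg <- sample_synth_config(
  n_families = 5, seqs_per_family = 50, n_columns = 300,
  n_conserved = 5, n_fsp = 10, n_exception = 1,
  conserved_deviation = 0.01, fsp_deviation = 0.05,
  gap_rate = 0.02, seed = 20260101)
sim <- generate_alignment(cfg)
numberings <- setNames(
  lapply(families(sim$annotation), function(f)
    ref_numbering(paste0(f, "_s001"))),
  families(sim$annotation))
bundle <- run_scan(sim$alignment, sim$annotation,
                   scan_config(n_permutations = 1000, seed = 20260104),
                   numberings = numberings, out_dir = "results")
bundle
table(bundle$classifications$class)
```

The numbered scripts under `analysis/` run this end to end — simulation,
filtering and merging, clustering, scanning and reporting — and print
the recovery of the planted signal against the generator's ground truth.

## Known limitations

* The FSP statistic is not the one used by any published web server;
  residue lists from analyses run elsewhere are not a numerical oracle
  for it.
* Phylogenetic correlation is neither modelled in the generator nor
  corrected for in the statistic (no tree weighting); on real data the
  permutation null is anti-conservative to an extent that grows with
  within-family relatedness.
* Gap-dominated columns are masked rather than tested; family-specific
  indels are invisible to the scan.
* Cross-family insertions are left unaligned by design; downstream
  consumers should treat insert columns as family-private.
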