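---
title: "Methods: positional analysis of dispersed repetitive DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positional analysis of dispersed repetitive DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disperscan)
library(dplyr)
```

## The problem

Satellite DNAs are tandem repeats concentrated in pericentromeric
heterochromatin, which is largely absent from chromosome-level assemblies.
What the assembly does contain is the euchromatic fraction: single repeats
and short multimers of these families scattered among genes. Whether those
dispersed copies sit preferentially inside introns, how close they lie to
genes, whether different families co-occur in the same chromosomal
regions, and how diverged their sequences are — these are the positional
questions this package answers, for inputs of the kind produced for the
ten TCAST repeat families of the red flour beetle (ten assembled
chromosomes, 294–1771 bp monomers, a few dozen to a few hundred dispersed
elements per family).

Everything downstream operates on three tabular inputs: a chromosome size
table with assembly-gap intervals and a list of excluded (unplaced or
unlocalized) scaffolds; a gene annotation with exon structure; and either
a ready element table or a similarity-search hit table to be filtered and
merged into elements. Internally all coordinates are 0-based, half-open
(the BED convention); GFF3 is converted at the boundary. Strand is
recorded but ignored by all positional statistics — it matters only for
multimer orientation.

## Element calling

Hits are retained when they cover at least 40% of the family consensus
length **and** exceed 80% identity. The identity bound is strict and the
coverage bound inclusive, mirroring the asymmetric wording of the
screening rule the thresholds come from; both are arguments of
`filter_hits()`. Same-family hits on one chromosome are merged into one
element when separated by at most `max_gap_factor = 2` monomer lengths.
No merge distance is published for this analysis; two monomer lengths is
chosen so that inverted dimers with short internal spacers (tens of bp,
the observed geometry) group into one element while independent
insertions do not, and the factor is exposed as an argument. A group of
one hit is a `single`; two opposite-strand hits are an `inverted_dimer`
with the inter-hit gap recorded as the spacer; anything else is a
`direct_multimer` whose order counts grouped hits, including partial
monomers — consistent with census tables that count partial dimers as
multimers. The census counts multimeric *elements*, not their constituent
monomers; the published "number of multimers" is ambiguous on this point
and we document our reading rather than guessing the other.

## Genome partition and categorization

Exonic space is the union of all exons (all transcripts merged per gene).
Gene-body space is the union of gene spans; intronic space is gene body
minus exonic, so an exon of one gene overlapping an intron of another
wins, and nested genes never create intergenic islands; intergenic space
is the complement of the gene body. Genes with no exon records are
treated as single-exon genes — the alternative (a whole-gene "intron")
would manufacture intronic space out of annotation incompleteness.

Elements are assigned a single category with exon > intron > intergenic
precedence: any exon overlap, even 1 bp, makes an element exonic;
otherwise any intron overlap makes it intronic. All of an element's base
pairs count toward its one category. Assembly gaps inherit the category
of their surroundings in the partition; they constrain only null-model
placement. Percent-in-introns is reported both by base pairs
(intronic bp / total bp) and by element count.

Two internal inconsistencies of the published reference tables surface
when they are recomputed, and the package reproduces the per-family
arithmetic rather than the printed aggregates: the all-family intergenic
base-pair total differs from the sum of its own column (450,656 printed
vs 451,726 summed), and the per-chromosome all-family counts for two
chromosomes are each one less than their row sums. Similarly, the
regression of the TCAST3 family's counts on chromosome size yields
R² = 0.416 from the printed counts themselves, not the printed 0.414;
`tcast_chromosome_table()` carries the printed values and our tests
anchor on what those values actually imply.

## Permutation nulls

The enrichment null re-places every nonexonic element uniformly over all
genome-wide start positions at which the whole element fits between
exclusions (assembly gaps and exons; excluded scaffolds are absent from
the genome model entirely). Placement is genome-wide with probability
proportional to eligible space — chromosome identity is not conserved,
matching the referenced shuffling tool's default — and placements may
overlap one another, since observed elements do. The empirical
probability is `#(simulated ≥ observed) / n_reps`, exactly the "met or
surpassed" counting rule of the original analysis, computed separately
for element counts and base-pair totals, for introns and intergenic
regions, per family and pooled; the conservative `(k+1)/(n+1)` variant
and Benjamini–Hochberg columns are available behind flags but are not
defaults, because the published probabilities are raw.

One estimator property worth knowing: with "met or surpassed" counting,
ties between the observed and simulated statistic push the empirical
probability upward. Element *counts* on small genomes tie often, so
count-based probabilities are visibly conservative (super-uniform) at
moderate `n_reps`; base-pair totals over elements of distinct lengths are
effectively tie-free and calibrate cleanly. Our null-uniformity test
therefore checks the base-pair probability; this is a property of the
published estimator, not an implementation artifact.

The distance null re-places intergenic elements excluding gaps and gene
bodies, pools the nearest-gene distances of all `n_reps = 100` replicates
into one null sample (the pooled comparison uses the larger null; a
single matched-size draw is available with `pool = FALSE`), and compares
observed against null with the two-sample Kolmogorov–Smirnov test on raw
distances. Distances are edge-to-edge from element boundary to gene-span
boundary, 0 when bookended, undefined (and excluded, with a logged count)
on chromosomes without genes. The `log10(d + 1)` transform appears only
on plotting axes. The K–S statistic is the supremum of the ECDF
difference over the sorted unique pooled values, which handles ties; the
p-value uses the asymptotic Kolmogorov distribution at effective size
`n₁n₂/(n₁+n₂)`, evaluated by its alternating series to well below 1e-9 —
slightly more accurate than the common reference implementation, whose
series truncates at a 1e-6 term tolerance.

## Chromosome-scale statistics

Counts per chromosome are regressed on chromosome size and on gene count
with ordinary least squares (`lm`); R² and the two-tailed slope p-value
(t, n−2 df) are reported raw, with no multiple-testing correction, as in
the source tables. Along-chromosome profiles bin features by start
coordinate — elements are tiny relative to bins, and a single convention
conserves counts; midpoint binning is an option — into either ten
equal-width bins with integer boundaries `floor(i·L/10)` (half-open, the
last bin absorbing the remainder) or fixed 1 Mb bins with a partial last
bin. Colocalization is the Pearson correlation of bin-count vectors per
chromosome and pooled, flagged significant at r > 0.700 and p < 0.05;
Spearman is available alongside. Whether the original analysis correlated
counts or percentages per bin is unstated; we use counts and expose
`use_percent` — per chromosome the two differ only by a scale factor that
Pearson absorbs, pooled they do not.

## Divergence and group statistics

The uncorrected p-distance is mismatches over comparable sites, a site
being comparable when neither row has a gap or N (pairwise deletion, the
default of the software the published divergences came from; complete
deletion amounts to dropping columns beforehand). Family divergence is
the mean over all unordered row pairs, in percent. The origin-group
comparison is the equal-variance (Student's) two-sample t test, as named
in the source; Welch is a flag. Recomputing the published group means
from the element counts reproduces the transposon-origin group exactly
(208.20 ± 138.36) but gives 268.20 for the other group where 267.80 is
printed — the counts behind the printed value cannot be reconstructed, so
the first group anchors our tests and the discrepancy is surfaced rather
than matched. Copy numbers are `fraction × genome size / monomer length`
at full precision, rounded to two significant figures only in the report
column.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not sequence realism (no GC skew, no transposition process). Defaults are
the study regime: ten chromosomes at the assembled sizes (137.7 Mb
total), one assembly gap per Mb averaging 2 kb, 12,119 genes allocated to
chromosomes by length, `1 + Poisson(3)` exons per gene with exon lengths
`50 + Exp(300)` bp and intron lengths `60 + Exp(1200)` bp, and the ten
families at their observed element counts and monomer lengths, with
element lengths uniform between 40% and 100% of the monomer (mirroring
the coverage rule), a 3% multimer fraction, and a per-site substitution
rate of 0.07 for sequence blocks (pairwise divergences near the observed
10–20%). Genes never overlap in the generator so that per-element truth
is unambiguous; overlapping-gene handling in the partition module is
exercised by hand-built fixtures instead.

Placement draws each element's location from a per-bp weight field —
baseline 1, × `intron_bias` in introns, × `boost` in hotspot windows
shared across families, 0 in gaps and (by default) exons — restricted to
positions where the whole element fits inside one weight run, so the
planted category is exact and truth/re-analysis agreement is 100% by
construction. Under a bias *b* on intron fraction *f* of eligible space,
the expected planted intron fraction is `bf / (bf + (1 − f))`; at
*b* = 2, *f* = 0.3 that is 0.4615, which both the test suite and the
acceptance script recover within binomial tolerance (fitting whole
elements into runs shaves the eligible starts of short runs, a sub-1%
effect at the 50 bp element lengths used there). When a proximity
mixture is configured, intergenic-routed elements are instead placed at
an exponential distance from a random gene edge — near scale with the
mixture fraction's probability, far scale otherwise — with bounded
retries and fallback to the uniform draw; this produces the bimodal
log-distance profiles (two element populations with different gene
proximity) that the distance test is designed to detect. Mutated
alignment blocks substitute each site independently at rate μ, uniform
over the three alternatives, giving expected pairwise p-distance
`2μ(1 − 2μ/3)`.

## Calibration, problem sizes and what passing shows

The test suite pins every primitive to an independent oracle (IRanges for
interval algebra, per-bp labeling for categorization, normal equations
for regression, per-site loops for p-distance, brute-force pooled ECDFs
and long-series evaluation for K–S) and calibrates the permutation engine
end to end on a fixed 1 Mb fixture whose nonexonic space is exactly 30%
intronic: with observed sets drawn by the shuffler itself, base-pair
empirical probabilities over 500 replicates at 200 placements each are
uniform (K–S vs uniform, discreteness at 1/200 granularity); with a 2×
intron bias and 300 elements at 1000 placements, the pooled intron
probability falls at or below 0.05 in ≥ 95% of 100 replicates; occupancy
over allowed space at 10⁵ single-bp placements passes a chi-square
uniformity check. These sizes keep the whole suite under a minute of
permutation work while leaving the binomial tolerances meaningful.

Passing these tests shows the machinery is correctly calibrated under the
generator's assumptions — independent placements, annotation-faithful
exclusions, unambiguous truth. It does not certify behavior on real
assemblies, where annotation errors, collapsed repeats and assembly gaps
correlate with the features being tested; the genome-scale published
probabilities (e.g. the pooled intron enrichment P = 0.005) additionally
require the original assembly and element coordinates, which have no
deposited machine-readable form, and are therefore reproduced in
*property* (calibration and power) rather than in value.

## Known limitations

No GC- or chromatin-matched nulls, no circular permutation, no
per-chromosome-conserved shuffling by default (available as a flag on the
placement layer), no transcript-isoform or UTR/CDS distinction within
exonic space, no alignment construction or model-corrected distances, and
no handling of genome sequence itself — positional statistics need only
coordinates.
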