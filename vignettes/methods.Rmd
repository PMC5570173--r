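---
title: "Methods: detecting and prioritizing plant biosynthetic gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and prioritizing plant biosynthetic gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantbgc)
```

`plantbgc` identifies candidate biosynthetic gene clusters (BGCs) in
annotated plant genomes and ranks them with transcriptome data. This
vignette is the package's own account of the underlying method: the model,
its assumptions, the tunable parameters, the numerical choices, and what
the synthetic-data tests do and do not demonstrate.

## The detection model

Plant BGCs are genomic loci encoding several functionally different enzyme
(sub)classes of one metabolic pathway. Detection operationalizes this in
four steps.

**Domain annotation.** Genes are scored against a library of 62 profile
HMMs (57 Pfam families, 5 custom models) covering enzyme families
recurrently involved in plant specialized metabolism: terpene synthases
and cyclases, cytochrome P450s, glycosyltransferases, type III polyketide
synthases, methyltransferases, BAHD and SCPL acyltransferases,
2-oxoglutarate dioxygenases, Bet v1-fold enzymes, berberine bridge
enzymes, and others. The shipped library
(`inst/extdata/domain_library.tsv`) is a reconstruction curated for this
package: the class labels, signature flags and per-profile cutoffs are
data, not code, and can be revised without touching the implementation.
Hits are filtered at E ≤ 1e-5 per domain row unless a profile configures
its own cutoff; the equality boundary is kept. HMMER itself is an optional
external adapter (`run_hmmscan()`); every downstream step consumes plain
hit tables, so analyses are reproducible from a saved table alone.

**Dynamic density cutoff.** Gene density varies enormously within plant
genomes, so a fixed kilobase cutoff either fragments clusters in sparse
regions or bridges unrelated genes in dense ones, and a pure
gene-count cutoff lets clusters cross repeat-rich deserts. The chaining
cutoff is therefore a linear function of local gene density: for the 10
genes nearest a hit (midpoint distance, ties to the lower coordinate),

```
cutoff_kb = multiplier × window_span_kb / window_gene_count
```

clamped to [`min_kb`, `max_kb`] = [10, 100] kb, with `multiplier = 5` by
default. The multiplier and clamp are calibration constants, exposed in
`detection_config()`; the defaults here were chosen so that, under
plant-like spacing (mean ~5 kb), neighboring pathway genes chain while
genes more than a few average intergenic distances apart do not, and they
are validated against planted-locus fixtures rather than against any
genome survey. Two fallback modes exist for poorly annotated genomes:
fixed-kilobase and maximum-intervening-gene-count. Consecutive hit genes
merge when the gap between gene bodies (end-to-start, not midpoints) is at
most the larger of their two cutoffs; chaining is transitive.

**The minimum rule.** A locus is accepted when it contains at least 3
distinct enzyme *subclasses* from at least 2 enzyme *classes*. Subclasses
are computed per class by greedy identity clustering with CD-HIT
semantics: sequences sorted by length (ties broken lexicographically by
gene id, for determinism), each sequence joining the first group whose
representative it exceeds 50% identity with. Identity is the number of
identical aligned positions divided by the length of the shorter sequence,
from a semi-global alignment (free end gaps; match +1, mismatch 0, gap −1
for path choice only). CD-HIT's word-filter heuristics are an
optimization, not a semantic, and are deliberately not reproduced — exact
alignment is affordable at the locus scale the rule operates on. The
shorter-sequence denominator means a fragment contained in a longer
homolog counts as identical, which is the behavior wanted for collapsing
tandem arrays with partial duplicates. Genes lacking a protein sequence
cannot be aligned and each count as their own subclass — a deliberate
permissive choice for annotation-only inputs.

**Extension and classification.** Accepted loci absorb every gene between
their outermost hits plus flanking genes whose nearest edge falls within
the outermost hit's cutoff; when two accepted loci's extensions collide,
the boundary is drawn at the gene-index midpoint between their hit spans
so reported clusters never overlap. Clusters are classified from their
signature enzymes via a rule table (terpene synthase → Terpene, type III
PKS → Polyketide, glycosyltransferase → Saccharide, Bet v1/strictosidine
synthase/decarboxylase/berberine bridge → Alkaloid, dirigent → Lignan);
two or more distinct products add "Hybrid", none yields "Putative".

## Coordinates

Internal coordinates are 1-based inclusive, GFF3-native. The R ecosystem
this package builds on (IRanges, GenomicRanges, rtracklayer, Biostrings)
uses that convention throughout, so converting to a 0-based internal form
would add translation layers at every boundary for no arithmetic benefit;
BED export converts at the writing boundary. All gap, span and density
arithmetic is explicit in the code and covered by round-trip tests.
When one gene has several transcripts, the mRNA with the longest summed
CDS is kept — the method needs one protein per gene for identity grouping,
and the longest CDS is the least lossy single choice.

## Coexpression

Pearson correlation r between two genes' expression profiles maps to a
distance d = 100 × (1 − r) ∈ [0, 200] (0 at r = +1, 200 at r = −1).
Heatmap ordering uses complete-linkage agglomeration on d. Heatmap colors
are min–max normalized per row by default (or per column); constant rows
map to 0.5. Min–max was chosen over z-scoring because it is
scale-preserving within a gene and puts every row on the same [0, 1]
color range; it is configurable.

The cluster network joins genes at d < 50 (r > 0.5). The ego network
extends it with outside genes that either (i) belong to another candidate
cluster and correlate above r = 0.9 with ≥1 focal gene, or (ii) carry a
biosynthetic domain and correlate above the threshold with ≥2 focal genes
of which ≥1 is biosynthetic. The threshold in clause (ii) is read as the
same 0.9 as clause (i).

Inter-cluster links are declared on the full network over all candidate
clusters' genes. The edge rule for that network is not uniquely
determined by the linkage criteria themselves; this package uses r > 0.9,
consistent with the ego-network threshold, and exposes it as a parameter.
The network is partitioned by Louvain (resolution 1, fixed seed — the
default 42 — so community assignment is reproducible), and a cluster pair
is linked when some subnetwork satisfies: same community; positive local
transitivity at every node; ≥2 genes per cluster; ≥1 biosynthetic gene
per cluster; ≥3 biosynthetic genes total. Candidate subnetworks are the
connected components of the pair's genes within a community; a component
that fails only the transitivity criterion is pruned of zero-transitivity
nodes to a fixed point and its components re-tested. This prune-to-fixed-
point search is a design choice (the criteria define what a witness is,
not how to find one); it cannot invent witnesses, and for the clique-like
structures coexpressed pathways produce it finds them directly.

Genes with zero variance are excluded from all correlation computations
(r undefined); with missing values, pairwise-complete correlations require
≥3 shared samples. One experiment is analyzed at a time.

## The prioritization statistic

For a candidate cluster of x genes, the within-cluster distribution holds
the PCC of every unordered pair of *eligible* cluster genes — eligible
meaning observed in all experiments and with unscaled median absolute
deviation > 0 in each (a flat gene carries no coexpression signal and its
correlations are numerically fragile). The background distribution is
distance-matched: all PCCs of eligible pairs separated by 0…x−2
intervening genes (exactly the separations that occur inside an x-gene
cluster; adjacent = 0), collected across the genome but excluding any pair
touching a predicted cluster. Matching on gene-order distance controls for
the neighborhood coexpression plants show regardless of clustering.
Multiple experiments are pooled by concatenating samples after
per-experiment row standardization, so differing scales cannot dominate;
pooling-then-correlating (rather than averaging per-experiment PCCs) is a
documented, switchable choice.

The test is the one-sided Mann–Whitney U (within stochastically greater),
with midrank ties. When both samples have ≤12 values the p-value is exact,
computed by dynamic programming over the permutation distribution of the
midrank sum — valid under ties, where the classic no-tie tables are not;
otherwise the normal approximation with tie and continuity correction is
used. The two paths agree to within 0.01 in the transition region. Raw
p-values at α = 0.05 are the primary output, as the procedure prescribes;
a Benjamini–Hochberg column is reported alongside for transparency, not
used for the flag. The variant run discards within- and background pairs
whose genes share a proteome-wide identity group (0.5 threshold), so
significance cannot be driven by coexpressed tandem duplicates.

## Comparative search

The locus database is built by re-running detection with inclusive
thresholds — ≥2 distinct identity groups, no class-count requirement,
identity 0.9 — so loci homologous to a real cluster are not excluded
merely for failing the strict rule. Query proteins are aligned to database
proteins with exact local BLOSUM62 alignment (gap open 11, extend 1) and a
standard gapped Karlin–Altschul bitscore (λ = 0.267, K = 0.041); per query
gene the best hit per locus above 30% identity and 30 bits is kept. Loci
rank lexicographically by number of query genes hit, then conserved
synteny — the longest common ordered run of hit positions, computed
forward and reversed so inversions of a whole locus score identically —
then cumulative bitscore, with the locus id as the final deterministic
tie-break. Lexicographic ordering (rather than a weighted sum) was chosen
because the three keys are on incomparable scales. An external aligner can
be swapped in behind the same hit-table contract for large databases.

## The synthetic-data generator

`make_toy_genome()` emulates the features detection must discriminate:
log-normal intergenic spacing (plant-like: large and variable; default
mean 5 kb, log-sd 0.6), planted loci whose same-class enzymes descend
from a shared ancestor mutated to a requested mutual identity (per-copy
substitution rate 1 − √target, so two independently mutated copies meet
the target in expectation), tandem arrays (identity 0.95 by default), and
truth tables recording each planted element's span, genes and expected
outcome. Domain hits are emitted directly in the hit-table format with
scores far above the cutoffs; a "borderline" mode instead places planted
hits exactly at the E = 1e-5 boundary and adds decoys just above it, to
exercise the filter.

`make_expression()` plants coexpression blocks with a latent-factor
construction: block genes are √ρ × shared standard-normal factor +
√(1 − ρ) × independent residual, so the expected pairwise PCC equals the
target ρ; all other genes are independent noise. The generator does **not**
model read-count noise distributions, batch effects, dosage compensation,
codon usage, introns beyond simple gene models, or sequence-level
evolution. Passing tests therefore demonstrate that the algorithms
implement their definitions and recover planted structure under calibrated
noise — not that any particular real genome will yield a particular
cluster count.

## Problem sizes and calibration checks

The test suite's statistical checks use sizes chosen to make the
properties sharp at desk scale: Mann–Whitney exactness is verified against
full permutation enumeration for all sample-size pairs up to 6×6 (ties
included); type-I error is estimated on 1000 independent null clusters of
5 genes over 30 samples against an 800-gene background (observed rejection
rate at α = 0.05 falls within [0.03, 0.07]); power uses 200 planted ρ = 0.8
clusters over 30 samples; planted-locus recovery runs 50 seeded genomes of
~35 genes; oracle equivalences (complete linkage, network edges, greedy
identity clustering, interval chaining) run on instances of up to 40
elements against brute-force reimplementations.

## Known limitations

- The domain library is a curated reconstruction; sensitivity and class
  assignments inherit its coverage. It is shipped as data precisely so it
  can be replaced.
- The density multiplier and clamp defaults are fixture-validated
  conventions, not genome-calibrated constants; for unusual genomes they
  should be tuned, or the gene-count mode used.
- Within-cluster PCC pairs are not independent (they share genes); the
  Mann–Whitney test inherits this mild dependence, as the underlying
  procedure does. The null calibration above shows the practical size is
  close to nominal at realistic cluster sizes.
- De novo gene finding, interactive visualization, and precomputed
  public-genome databases are out of scope; inputs must be annotated
  genomes, and outputs are machine-readable tables and graphs.
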