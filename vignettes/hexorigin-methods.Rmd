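---
title: "Methods: phasing, Ks dating and allele-specific expression in a synthetic hexaploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasing, Ks dating and allele-specific expression in a synthetic hexaploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexorigin)
library(dplyr)
```

## The problem

Hexaploid genomes such as that of the kiwifruit relative *Actinidia
valvata* carry six haploid complements whose history mixes hybridization
and whole-genome duplication (WGD). hexorigin implements the
computational core of reconstructing such a history from a
haplotype-resolved assembly: (i) phasing assembly unitigs into haplotype
groups from Hi-C contacts, (ii) pairing allelic gene copies across
haplotypes and classifying loci by allele multiplicity, (iii) dating the
polyploidy events from the synonymous-substitution (Ks) distribution via
the molecular clock `T = Ks / (2 r)`, and (iv) quantifying
allele-specific expression (ASE) and subgenome dominance from RNA-seq
counts. A truth-annotated synthetic generator ties the stages together
into an end-to-end recovery benchmark.

The model organism for the synthetic data is an allohexaploid formed by
hybridization between a diploid lineage (subgenome A, haplotypes 1–2)
and an autotetraploid lineage (subgenome B, haplotypes 3–6): the two
ancestors diverged `t_div` years ago (default 7.9 Myr), the
tetraploid-forming duplication WGDt happened `t_wgdt` (0.88 Myr) and the
hexaploid-forming doubling WGDh `t_wgdh` (0.44 Myr) years ago.

## The coding-sequence simulator

`simulate_haplotype_cds()` evolves each ancestral gene along the event
tree `((hap1, hap2), ((hap3, hap4), (hap5, hap6)))` with branch lengths
set by the three event times. The substitution process is deliberately
the *same* model the downstream estimator assumes: mutation proposals
arrive at rate `r_syn` per nucleotide site (default
3.39 × 10⁻⁹/site/year, an angiosperm neutral-rate calibration), pick one
of the three alternative bases uniformly (Jukes–Cantor), fix with
probability 1 when synonymous and `omega` (default 0.2, moderate
purifying selection) when non-synonymous. Proposals that would create a
stop codon are discarded — the event simply produces no change. This
keeps the coding sequence translatable and keeps the realized synonymous
rate exactly consistent with NG86 site counting, in which alternatives
leading to stops are counted as non-synonymous; re-drawing the proposal
elsewhere would instead inflate every other rate by the stop-proposal
mass (~1–2%). Under this process the expected Ks between two copies
separated for `T` years is `2 r_syn T`, which the tests verify by Monte
Carlo at 2000 genes.

The branching order inside subgenome B (which haplotype pairs coalesce
at WGDh versus WGDt) is not something the Ks data of a real assembly pins
down *a priori*, so it is an explicit parameter (`b_topology`) rather
than a fixed choice; the default pairs (3,4) and (5,6).

### Why 500 codons per gene

The default `codons_per_gene = 500` (a 1.5 kb CDS, at the upper end of
typical plant gene lengths) is a resolution requirement, decided from
the statistics of the youngest event before any end-to-end run. At
`Ks ≈ 0.003` the number of synonymous differences per gene pair is
Poisson with mean `Ks × S`, where `S ≈ 0.75 × codons` is the synonymous
site count. The empirical Ks distribution is therefore concentrated on
the discrete atoms `k / S`, and a kernel-density peak can only sit near
the true value when the mean count is at least about one and the Poisson
mode/mean ratio is within the dating tolerance. At 500 codons
(`S ≈ 375`) the expected counts at WGDh/WGDt/divergence are ≈1.1, 2.2
and 20, which a Monte-Carlo probe showed recovers all three event times
stably across seeds; materially shorter genes push the WGDh peak onto
the zero-difference atom. The same discreteness is visible in real
Ks plots of very recent WGDs, where the youngest peak sits at roughly
one synonymous difference per average gene.

## NG86 Ks and the molecular clock

`ng86_ks()` implements Nei–Gojobori (1986) counting with the
Jukes–Cantor correction `Ks = -(3/4) ln(1 - (4/3) pS)`:

* synonymous site counts per codon are the fraction of the three
  single-base changes at each position that preserve the amino acid
  (changes to stops count as non-synonymous), averaged over the two
  sequences;
* codons differing at 2–3 positions are resolved by averaging the
  synonymous/non-synonymous step counts over all minimal mutational
  pathways, excluding pathways that pass through a stop codon; codon
  pairs whose every pathway is blocked are skipped and counted;
* gap or ambiguous codons are skipped pairwise;
* pairs with `pS ≥ 3/4` are flagged saturated and excluded from
  distributions rather than clamped.

The implementation precomputes a 64 × 64 pathway-averaged difference
table once per session, so bulk scoring of tens of thousands of pairs is
a vectorized lookup. Its correctness is established against a separate
naive recursive pathway-enumeration oracle (agreement to 1 × 10⁻¹²
on random pairs). Plain NG86 was chosen over gamma-corrected or
maximum-likelihood codon models because it is closed-form,
oracle-verifiable, and matches the simulator's model exactly; at the
shallow divergences of interest (Ks ≤ 0.06) multiple-hit behaviour is
negligible anyway.

Ks distributions use a Gaussian KDE with Silverman's rule-of-thumb
bandwidth on a 512-point grid over `[0, 1.05 max]`; `find_peaks()` takes
local maxima of the grid, merges peaks closer than `min_separation`
(default 0.001, about one atom spacing at the default gene length) and
ranks them by density. `ks_to_time()` applies `T = Ks / (2 r)` exactly
and reports Mya rounded to two decimals, the precision at which such
estimates are conventionally quoted. `assign_subgenomes()` searches all
15 two-versus-four splits of the six haplotypes for the one minimizing
mean within-subgenome median Ks and warns when the between/within
contrast is below a margin (default 0.005), i.e. when there is no clear
subgenome structure.

## Hi-C phasing

The phasing stage mirrors an allele-aware Hi-C clustering pipeline with
overlap-based rescue, operating on one chromosome group at a time (the
chromosome pre-partition is taken as given input):

1. **Prune** (`prune_allelic()`): all Hi-C contacts between unitigs
   carrying copies of the same reference gene are zeroed, so that the
   dominant remaining signal is intra-haplotype.
2. **Partition** (`partition_groups()`): greedy agglomerative
   clustering; singleton clusters merge by the highest inter-cluster
   link density (summed counts divided by the product of total lengths)
   until K groups remain, with lexicographic tie-breaking for
   determinism. Any density-maximizing clusterer satisfies the contract;
   the greedy one is verified against exhaustive search on small planted
   maps.
3. **Dedup** (`dedup_overlaps()`): within a group, unitig pairs whose
   alignment overlap covers at least `large_frac` (default 0.5) of the
   shorter unitig at identity ≥ `min_identity` (default 0.9) are treated
   as redundant haplotype duplicates; the member with the lower Hi-C
   link density to the rest of the group is moved out. Pairs are
   processed in descending overlap length and densities recomputed after
   every removal, making the outcome reproducible.
4. **Rescue** (`rescue_ungrouped()`): ungrouped unitigs are tried in
   descending order of their best group link density, each joining the
   first candidate group (again in descending density order) where it
   has no large overlap with any member. The pass is single and ordered:
   earlier placements are visible to later tests, and previously
   rejected unitigs are not revisited — re-testing after later
   placements could only move unitigs between near-tied groups and would
   make the result order-dependent in a less transparent way.

"Hi-C link density" is defined as summed link counts to the reference
set divided by the unitig's length (links/bp); length normalization
makes short and long unitigs comparable, and the same quantity is used
for dedup decisions and rescue ordering. Unitigs without gene evidence
are assigned to chromosomes by `assign_by_alignment()` (argmax alignment
score, ties to the lowest chromosome id), and `detect_collapse()` flags
windows whose mapping depth reaches `fold` (default 1.75) times the
genome median — the signature of collapsed multi-copy sequence.

`phasing_accuracy()` scores a grouping against simulation truth as the
length-weighted fraction of grouped unitigs whose group maps to their
true haplotype under the best label permutation.

## Allelic loci

`cscore_pairs()` applies three filters in sequence: a c-score filter
(`score ≥ cscore × max(best outgoing of a, best incoming of b)`, with
bests computed over the whole hits table), collinear block chaining
(consecutive retained hits within `dist` gene ranks on both haplotypes;
blocks under `min_size` dropped), and greedy one-to-one matching by
descending score. The defaults (0.7, 20, 4) are the conventional
synteny-pairing settings for this analysis. `dist` is interpreted as
gene-rank distance — genes apart along the chromosome — which avoids
base-pair ambiguity; positions are supplied as rank indices. At
`cscore = 1` the first filter reduces to reciprocal best hits, which the
tests assert.

`build_loci()` forms loci as connected components of the pair graph
over all 15 haplotype pairs. A component containing two genes on the
same haplotype is contradictory; it is repaired by iteratively deleting
its lowest-score edge until every haplotype is represented at most once
— the weakest link is the most likely spurious pairing. Genes in no
pair are singletons. The census classes (sextuple … double, singleton)
partition the gene universe by construction.

The synthetic similarity scores are `1 − p-distance` of the CDS pair, so
the pairing stage needs no aligner; scores are abstract similarities as
far as the filters are concerned.

## Allele-specific expression

Expression is compared on TPM (`compute_tpm()`, exact 10⁶ column sums
over included genes). For each within-locus allele pair and timepoint,
`test_allele_pair()` reports `log2((mean TPM_a + ε)/(mean TPM_b + ε))`
over replicates (ε = 0.01 TPM, below biological resolution, to avoid
infinities) and a two-sided exact binomial p-value on the
replicate-summed raw counts. Because both alleles of a pair are counted
in the same libraries, the null allele share is the effective-length
share `len_a / (len_a + len_b)` — 0.5 for equal lengths. The exact test
was chosen because it is self-contained and exactly computable with no
fitting machinery; counts are summed within timepoint for the test while
TPM is averaged for the fold change, following the TPM-based
significance criterion (`|log2FC| > 1`, `p < 0.05`). No multiple-testing
correction is applied by default, mirroring a raw-p criterion; `adjust =
TRUE` enables BH-FDR.

A locus is ASE when any of its allele pairs is significant at any
timepoint; testing is per-timepoint with any-timepoint aggregation,
which matches treating each stress timepoint as a condition of interest.
A pair is an *inconsistent* ASE pair when it is significant at two or
more timepoints with different dominant alleles. `dominance_summary()`
contrasts mean TPM of subgenome-A copies (haplotypes 1–2) against
subgenome-B copies (3–6) per sextuple locus and classifies loci biased
beyond |log2| > 1.

## What the generator does and does not emulate

The generator reproduces the features the methods actually consume:
clock-like sequence divergence structured by the event tree,
block-structured Hi-C contact counts (intra-haplotype ≫ allelic ≫
background, Poisson), allelic unitig overlaps emitted as PAF records,
gene-free unitigs as rescue fodder, and negative-binomial expression
with subgenome dominance and planted allele-specific effects over a
4-timepoint × 3-replicate design (12 samples).

It deliberately does not emulate: read-level data, assembly graphs,
indels or structural variants, chromatin contact-distance decay, gene
loss/fractionation (so a clean run yields only sextuple loci),
gene-length variation, or expression changes over time (planted ASE
effects are constant across timepoints, so inconsistent-ASE calls on
synthetic data arise only from noise). Passing recovery tests therefore
demonstrates correctness of the inference machinery under the stated
model, not robustness to the full messiness of real assemblies — e.g.
chimeric unitigs, collapsed repeats or mapping bias.

## Numerical and scale choices

All coordinates are 0-based half-open; haplotypes are labelled 1–6 with
1–2 subgenome A by convention. Every stochastic function takes an
explicit integer seed and is bit-reproducible under it. Degenerate
inputs error early with named causes (empty categories, zero-median
depth, zero-count samples, fewer unitigs than groups).

The shipped tests and the acceptance script run the recovery analyses at
sizes chosen to make their statistics decisive while staying desk-scale:
2000 loci × 500 codons for event dating (30 000 gene pairs), six
haplotypes × 8 unitigs over five seeds for phasing, and 150–200 loci for
ASE calibration/recovery. The end-to-end `run_pipeline()` default uses
500 loci.

## Known limitations

* Peak dating inherits the count-discreteness bias discussed above:
  the KDE mode underestimates very recent event times by up to
  ~`0.5 / (Ks × S)` relative, which is visible as recovered WGD ages a
  few percent young.
* The greedy clusterer is only verified optimal on small instances;
  pathological contact maps could in principle defeat it.
* The exact binomial ASE test ignores replicate-level overdispersion
  (it pools counts); with few, deep replicates it is anti-conservative
  relative to a count-model test, which is why the fold-change
  criterion is applied jointly.
* Component repair in `build_loci()` is greedy weakest-edge removal;
  it does not revisit alternative splits.
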