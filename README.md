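# hexorigin

Reconstructing the origin of a hexaploid genome from a
haplotype-resolved assembly: Hi-C haplotype phasing of unitigs, allelic
gene pairing, Ks-based molecular-clock dating of polyploidy events, and
allele-specific expression / subgenome dominance analysis — with a fully
truth-annotated synthetic hexaploid generator for end-to-end validation.

## Who this is for

Genome-assembly and polyploid-evolution researchers working with
haplotype-resolved assemblies of complex polyploids — the motivating
case is the hexaploid kiwifruit relative *Actinidia valvata*, an
allopolyploid whose six haplotypes split into a diploid-derived
subgenome A (haplotypes 1–2) and an autotetraploid-derived subgenome B
(haplotypes 3–6). The package implements the analysis core of that kind
of study as tested, reusable functions: every stage takes plain tibbles
and returns tibbles, so results chain with the pipe and feed directly
into dplyr/ggplot2.

## What it computes

* **Phasing** (`prune_allelic()`, `partition_groups()`,
  `dedup_overlaps()`, `rescue_ungrouped()`, `assign_by_alignment()`,
  `detect_collapse()`): allele-aware pruning of Hi-C contacts between
  unitigs carrying copies of the same gene, link-density clustering into
  K haplotype groups, removal of redundant overlapping unitigs inside
  groups (the member with less Hi-C link density loses), ordered rescue
  of ungrouped unitigs into the strongest conflict-free group,
  alignment-based chromosome assignment and depth-based collapse QC.
* **Allelic loci** (`cscore_pairs()`, `build_loci()`): one-to-one
  allelic gene pairs per haplotype pair via the c-score filter
  (`score ≥ c · max(best(a), best(b))`), collinear block chaining and
  best-score matching; loci as connected components classified
  sextuple … double plus singletons.
* **Ks clock** (`ng86_ks()`, `ks_distribution()`, `find_peaks()`,
  `ks_to_time()`, `assign_subgenomes()`): Nei–Gojobori (1986) synonymous
  distance with Jukes–Cantor correction
  `Ks = -(3/4) ln(1 - (4/3) pS)`, per-category kernel density peaks, and
  event dating via `T = Ks / (2r)` with `r = 3.39 × 10⁻⁹`
  substitutions/site/year by default.
* **ASE** (`compute_tpm()`, `ase_test()`, `classify_asegs()`,
  `inconsistent_asegs()`, `dominance_summary()`): per-allele-pair,
  per-timepoint exact binomial tests with a TPM fold-change criterion
  (`|log2FC| > 1`, `p < 0.05`), ASE locus census, dominance switching,
  and subgenome expression bias.
* **Synthetic data** (`history_params()`, `simulate_haplotype_cds()`,
  `fragment_and_contacts()`, `simulate_expression()`): six haplotype CDS
  sets evolved along the hybridization/WGD event tree, unitigs with
  block-structured Poisson Hi-C contacts and PAF overlaps, and
  negative-binomial expression with planted dominance and ASE effects —
  all with ground truth for recovery scoring.

`run_pipeline()` composes everything into one benchmark run;
`tidy()`/`glance()` and `autoplot()` methods summarize and plot results.

## Worked example

Simulate a hexaploid with the default history (ancestor divergence
7.9 Mya, tetraploidization 0.88 Mya, hexaploidization 0.44 Mya), run all
stages, and print the report:

```r
library(hexorigin)

cfg <- hex_config(
  seed = 1,
  history = history_params(n_genes = 2000, seed = 1),
  unitigs_per_hap = 8
)
run <- run_pipeline(cfg)
run
#> Hexaploid origin benchmark run (seed 1)
#>   phasing accuracy (length-weighted): 1.000
#>   locus census: sextuple=2000 quintuple=0 quadruple=0 triple=0 double=0 singleton=0
#>   dated events:
#>     A_wgdh  peak Ks 0.0028 -> 0.41 Mya (truth 0.44)
#>     AxB     peak Ks 0.0539 -> 7.96 Mya (truth 7.90)
#>     B_wgdh  peak Ks 0.0027 -> 0.41 Mya (truth 0.44)
#>     B_wgdt  peak Ks 0.0055 -> 0.81 Mya (truth 0.88)
#>   subgenome A haplotypes: hap1, hap2
#>   ASE: 2000 / 2000 sextuple loci (100.00%)
```

Reading the report: all unitigs were phased into their true haplotype
groups (accuracy 1.0); with no gene loss in the generator every locus is
sextuple; the Ks density peaks of the allelic pair categories date the
hexaploidization (≈0.41 vs true 0.44 Mya), the tetraploidization
(≈0.81 vs 0.88 Mya) and the subgenome divergence (≈7.96 vs 7.9 Mya),
slightly young for the youngest events because peak location sits on
discrete substitution-count atoms (see the methods vignette); the
exhaustive 2-vs-4 split search recovers subgenome A = {hap1, hap2}; and
with the default twofold subgenome-B dominance plus planted
allele-specific effects essentially every locus shows significant allele
imbalance, as expected.

The clock arithmetic alone:

```r
ks_to_time(c(0.003, 0.006, 0.051, 0.056), r = 3.39e-9)$mya
#> [1] 0.44 0.88 7.52 8.26
```

Individual stages run standalone on your own tables — e.g.
`ng86_ks(cds_a, cds_b)` on aligned CDS pairs, or
`phase_unitigs(fragments, k = 6)` on contacts/overlaps/allele tables
read with `read_contacts()`, `read_paf()` and `read_allele_table()`.

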