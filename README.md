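# mgproteo

Composition-based metagenome binning and censored metaproteome statistics
for simple microbial consortia.

Thermophilic consortia adapted to grow on plant biomass are often simple
enough — a handful of dominant populations — that their genomes can be
reconstructed directly from an assembled metagenome, and the proteins each
population secretes can then be quantified by label-free proteomics of the
culture fractions (supernatant, suspended cells, residual biomass).
`mgproteo` implements that full analysis chain, plus seeded synthetic
community and proteome generators with known ground truth so every stage
can be validated end to end.

## What it computes

**Phylogenetic binning.** Each bin is summarised by an order-3 De Bruijn
chain signature — the transition probabilities *P(x₄ | x₁x₂x₃)* of 4-mer
windows, counted on both strands. Contigs are scored against bin models by
the total-variation distance between 4-mer frequency vectors,
*d(p,q) = ½ Σ|p − q|*. Binning is two-round and vetoed: bins are seeded by
contigs with a strict majority of single-copy marker genes from one taxon;
a contig is assigned only if its best score passes the cutoff **and** the
second-best score is at least 1.2× the best (ambiguous contigs "falling
between two bins" stay unassigned); indistinguishable seed bins are merged
and shrinking ones deleted between rounds; a final unvetoed pass
classifies every contig ≥ 1 kbp. Populations sharing a composition
signature are separated afterwards by read coverage
(`extract_coverage_clusters`, a length-weighted kernel density on log2
coverage).

**Genome statistics.** Weighted single-copy marker completeness (each
ribosomal COG counts 1/30 of a non-ribosomal one: with the bundled 54-COG
set all-ribosomal-only scores 4%, non-ribosomal-only 96%); best-hit
average amino acid identity with ≥30% identity over ≥70% query coverage
filters; assembly totals / N50 / GC.

**Protein reference database.** Gene calls are ranked by reliability,
log₁₀(1 + coverage) + log₁₀(length) − [near contig edge (200 bp)], then
greedily dereplicated at 95% global identity so each cluster's
representative is its most reliable member.

**Censored metaproteome statistics.** Peptide-to-protein rollup averages
the top ⌈0.33 n⌉ unique peptides per protein and sample; shared peptides
are excluded. Normalization is two-level fixed-point median-of-ratios
(replicates within fraction, then fractions on the globally complete
proteins) and is exactly idempotent. Replicate variance is pooled through
a power law *σ² = a·μᵇ* fitted on the log-log scale; missing values are
treated as left-censored at the detection floor and imputed just below the
observed range; a hybrid variance rule (sample / averaged / pooled,
depending on how many replicates were observed) feeds a Welch *t* test of
supernatant versus pooled cellular fractions with Satterthwaite degrees of
freedom. Proteins at fold ≥ 2 and p < 0.05 are flagged; category
enrichment uses two-sided Fisher tests with Benjamini–Hochberg control at
FDR 10%.

The package vignette (`vignettes/mgproteo-methods.Rmd`) derives each of
these choices, including why the historical 0.01 score cutoff is not a
total-variation-scale number and what the synthetic generators do and do
not reproduce.

## Worked example

The bundled demo configuration runs a four-population synthetic community
(Thermus / Rhodothermus / Paenibacillus / Gemmatimonas at 70/35/25/10×
coverage) and a censored proteome with 20 planted secreted proteins
through every stage:

```r
library(mgproteo)
cfg <- read_config(system.file("extdata", "demo_config.txt",
                               package = "mgproteo"))
res <- run_pipeline(cfg)
print(res)
```

```
pipeline run report
package mgproteo 0.1.0
config: score_max=0.35 margin=1.2 min_len=1000 order=3 identity=0.95 top_fraction=0.33 floor=auto alpha=0.05 fdr=0.1 seed=1
assembly: 146 contigs, 1210947 bp, N50 11668, GC 61.0%
binning: 4 bins, 146 contigs assigned, 0 unassigned
binning: 100.0% of assigned contigs match ground truth
completeness: Gemmatimonas=79% Paenibacillus=71% Rhodothermus=87% Thermus=63%
refdb: 220 proteins -> 195 representatives at 95% identity
normalization: 319 globally complete proteins; fraction factors supernatant=0.967 cells=1.053 residual=0.983
variance law: var = 0.0144 * mean^2.04
differential: 77/400 proteins >= 2-fold supernatant-overrepresented at alpha 0.05
enrichment: 1/13 categories significant at FDR 0.10
```

Each bin resolves into coverage clusters (the genome reconstructions):

```r
print(res$bin_table, digits = 3)
```

```
            bin coverage_mode cov_lo cov_hi n_contigs total_bp   n50 mean_gc_percent
1  Gemmatimonas          10.1   6.84   12.9        35   300000 13234            60.0
2 Paenibacillus          25.2  19.36   34.4        44   310947  9505            52.1
3  Rhodothermus          34.0  28.61   49.3        25   300000 18418            64.1
4       Thermus          67.8  51.17   83.4        42   300000  9931            68.0
```

The planted secreted pathway is recovered cleanly by the enrichment stage:

```r
head(res$enrichment[, c("category", "k_flagged_in", "n_in", "p", "q", "significant")], 2)
```

```
      category k_flagged_in n_in        p        q significant
1 PWY_secreted           20   20 5.28e-16 6.87e-15        TRUE
7        PWY06            1   25 6.22e-02 3.52e-01       FALSE
```

A rerun with the same config writes byte-identical outputs: all
randomness derives from `config$seed`.

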