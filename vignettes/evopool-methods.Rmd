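---
title: "Methods: simulating and analyzing pooled-isolate resequencing of in situ evolving populations"
author: "evopool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing pooled-isolate resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evopool)
```

## The experimental design being modeled

evopool models a field experimental-evolution design in which an isogenic
bacterial population is incubated in autoclaved "carrier" soil, sealed into
membrane-bounded chambers (adaptation chips), and buried at several farm
sites for months to years. At each retrieval, 100 colonies are recaptured
from a chamber and sequenced together as one pool, so the read fraction
supporting an allele estimates its population frequency — quantized to
multiples of 1/100 and blind below 1%. The analysis questions are: which
mutations are *shared* standing variation that predates burial, whether
their frequencies shift by site after burial, whether multiple mutations
travel together in single isolates (read-backed linkage), and how the
contaminant (non-focal) community inside the chambers behaves.

Because real runs of this design live in sequence archives and depend on
external pipelines, the package carries a first-class synthetic generator
for every layer — genome, population dynamics, pooling, sequencing, and
contaminant community — with machine-readable truth, so the entire analysis
chain is testable offline.

## The synthetic cosm

**Ancestral genome.** `simulate_ancestor()` draws a uniform-random genome
(default 50 kb) and places non-overlapping coding genes (codon-multiple
lengths ~900 bp). Genes are random sequence, not constrained to be
stop-free ORFs: the annotator only needs codon structure, and free
composition keeps paralog construction simple. One gene pair is duplicated
with 10% of positions mutated, giving two co-oriented copies at ~90%
identity — the substrate for paralog best-match checks. A fraction of genes
(default 20%) is flagged *selected*.

**Population dynamics.** `evolve_population()` is a lineage-level
Wright–Fisher simulation: each generation multinomially resamples N
individuals (default N = 10^4) with fitness multiplier (1+s)^k for lineages
carrying k mutations in selected genes (default s = 0.08), then adds
Poisson(μN) new mutations (default μ = 0.01 per genome per generation),
each founding a new lineage at frequency 1/N at a uniform genome position.
Generations are the clock; calendar time maps to generations only through
the configuration, because the field design gives no way to count
generations in soil. Dormancy is modeled as uniformly skipped generations:
a burial phase of g nominal generations realizes only
`ceil((1 - dormancy_fraction) * g)` (default dormancy 0.9, i.e. a
spore-dominated population that sits out 90% of burial time). This is the
simplest mechanism producing the design's signature of very limited
post-burial change; spore physiology itself is out of scope.

**The planted shared set.** All chambers are filled from one carrier-soil
population, so pre-deployment variation is a property of that single
pre-burial state. `plant_shared_mutations()` constructs it directly: n
mutations (default 12) grouped onto a few lineages (default 3), each
lineage's mutations clustered in one selected gene, with lineage
frequencies partitioned inside the 25–50% band. Planting, rather than
re-running the pre-phase sweep each time, gives exact truth labels and
reflects the design reading that mid-frequency shared mutations are the
*outcome* of the lab incubation; the Wright–Fisher engine remains available
(and tested) for explicitly simulating that phase, and drives all
post-burial dynamics.

**Pooling and sequencing.** `sample_isolate_pool()` is a multinomial draw
of 100 isolates by lineage frequency; pool-level mutation frequencies are
therefore multiples of 0.01, which is exactly the default detection
threshold — the package treats the 1% floor as a property of the design,
not a tunable. `generate_reads()` emits pre-aligned, gap-free reads
(default 150 bp at 450× mean depth): uniform starts, lineage-proportional
read origin, lineage mutations installed within the span, then independent
substitution errors at 0.001/base. No aligner, indels, quality model, GC
bias, or wrapping reads (circular genomes are emitted linearized);
alignment is not a contribution of this design and its artifacts are out
of scope.

**Two observation models.** `simulate_experiment()` can observe each
chamber either by generating full reads and running the pileup caller
(`observation = "reads"`), or by drawing, per truth mutation, a
Poisson-depth binomial alt count (`observation = "binomial"`, the
default). The binomial model is the exact marginal distribution of the
read model at a single site, so frequency-level results are
distributionally identical; only read-level analyses (linkage, paralogs)
need reads mode. Multi-chamber layouts use the binomial mode so the
default 60-chamber experiment simulates in seconds.

**Contaminant community.** `simulate_contaminants()` gives each non-focal
taxon a log-normal baseline abundance; the focal species' expected read
share declines log-linearly over burial time (60% → 20% by default);
evenness rises over time (baseline exponents annealed from 2 to 1), so
Shannon diversity of the non-focal community grows; and per-site
perturbation directions with magnitude growing linearly in time separate
sites progressively in Bray–Curtis space. Every resident taxon is given a
minimum relative abundance (0.2% of non-focal mass) in the pre-deployment
sample so that, with the default of zero external taxa, source attribution
is 100% pre-deployment by construction. The generator does not model
taxon–taxon interactions or true immigration dynamics — whether
contaminants compete with the focal species is an open question of the
design, so passing community tests demonstrate the analytics, not ecology.

## The analysis chain

**Pileup and calling.** `build_pileup()` counts A/C/G/T support per
position (gap-free, match-only alignments). `call_variants()` reports one
call per (position, alternate base) with `alt_count >= 2` and
`alt_count/depth >= 0.01`. The frequency is the exact read ratio. The
2-read minimum suppresses singleton errors at 400–500×; both thresholds
are explicit in `detection_rule()` because the design's own floor (1%) is
a consequence of 100-isolate pooling. Only substitutions are handled.

**Effect annotation.** `annotate_effect()` translates the strand-aware
codon containing each call under the standard genetic code;
reverse-strand genes are complement-translated; stop gains count as
non-synonymous (a binary split is used throughout); positions outside
genes are intergenic; genes with non-codon lengths are flagged and their
calls left intergenic rather than guessed.

**Census.** `build_matrix()` unions variant keys across samples
(undetected cells are frequency 0). `classify_shared()` applies the k-of-n
rule — detected in at least k of n chambers — with
`scale_shared_criterion()` preserving the reference prevalence fraction
54/59 when layouts differ (k rounds up, so scaling never loosens the
rule). `venn_partition()` counts a mutation once per site regardless of
how many of the site's chambers carry it. `site_unique_genes()`
operationalizes "most of the chambers" as a strict majority
(`majority_fraction = 0.5`, configurable) plus zero occurrences at every
other site. `ns_ratio()` is a ratio of means (not a mean of ratios) over
the chambers possessing at least one mutation of either class in the
gene, with SE = sd/sqrt(n); the printed ratio uses *half-up* rounding at
two decimals, matching report-table convention (R's default round-half-even
differs at exact .5 boundaries, e.g. 1.46/4).

**Linkage and paralogs.** `pairwise_linkage()` tallies, per variant pair,
the reads spanning both positions and those carrying both alternate
alleles; `linkage_fraction = both/spanning`. Note this equals the carrier
lineage's pool share when wild-type isolates are present: a fully linked
pair on a 30% lineage has fraction ≈ 0.3, and the default grouping
threshold (0.9, with ≥10 spanning reads) targets the high-share regime of
the defining worked case (all reads from one multi-mutant lineage →
fraction 1). Statistical phasing across non-spanned pairs is deliberately
absent — the evidence modeled is strictly single-read co-occurrence, with
transitive closure (`linked_groups()`, union-find) only joining directly
supported pairs. `paralog_best_match()` compares a read, gap-free at
matched within-gene offsets, against each copy of a paralog group and
assigns the unique mismatch minimizer (ties are AMBIGUOUS); copies are
generated without indels, so gap-free comparison is exact here and a
documented limitation on real data.

**Frequency dynamics.** `baseline_shift()` measures percentage-point
changes against the mean over *all* baseline-timepoint samples, pooled
across sites (the first reliable retrieval, default 3 months, is the
baseline; a variant undetected in every baseline sample is flagged, with
baseline 0). `anova_table()` is sequential (Type I) fixed-effects ANOVA
via `stats::aov`, exact for balanced layouts and reported as-is for
unbalanced ones; an all-equal response returns zero SS with F = NaN
rather than a spurious statistic. `tukey_hsd()` uses the studentized
range (`stats::ptukey`, Tukey–Kramer SE for unequal n). No
multiple-testing correction is applied across variants by default
(per-mutation reporting); `site_anova(adjust = "BH")` enables
Benjamini–Hochberg. `abiotic_correlation()` is Pearson r of per-sample
frequency against the sample's site covariate, two-sided t-based p,
flagged (not fabricated) when either vector is constant.

**Community analytics.** Shannon uses natural log and excludes the focal
taxon by default (the index describes the contaminant community);
Bray–Curtis is computed on raw counts via `vegan::vegdist`; PCoA is
classical scaling (`stats::cmdscale`) with negative eigenvalues reported
and excluded from the variance-explained denominator; detection of a
taxon means ≥1 read (configurable). Source attribution is rule-ordered:
pre-deployment beats other-site beats site-exclusive, with read-weighted
percentages per site set (a per-chamber weighting is a possible variant;
read-weighting matches the set-level framing of the design).

## Numerical and testing choices

Internal coordinates are 0-based half-open everywhere; GFF3, VCF and SAM
emission convert to 1-based exactly once at the boundary. Determinism is
guaranteed by explicit seeds threaded through every stochastic call;
`run_pipeline()` writes an md5 manifest so byte-level reproducibility is
checkable. Test problem sizes are deliberately small (6–9 kb genomes, 15–60
chambers, 20 seeds for stochastic claims, 200 datasets for type-I
calibration); at the default depth of 450×, per-pool frequency estimates
carry binomial noise of sd ≈ 2.2 percentage points at mid frequencies, so
accuracy claims are made either against the exact 3·SE binomial band
(per observation) or at ±3 percentage points for per-mutation estimates
aggregated across a layout's chambers.

## Known limitations

Read simulation has no indels, quality scores, or coverage bias; paralog
comparison is gap-free; linkage is frequency-confounded as described;
ANOVA is sequential-SS only; the contaminant generator is phenomenological
(it reproduces the diversity/ordination patterns, not their mechanisms);
and the planted shared set bypasses explicit pre-phase dynamics unless the
Wright–Fisher pre-phase is invoked directly. Passing tests on this
synthetic cosm demonstrate the correctness of the analysis chain under the
stated noise models, not the behavior of real soil populations.
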