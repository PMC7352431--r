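---
title: "Family-based variant prioritization: model, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In a cancer family sequenced by whole-genome sequencing, tens of thousands
of rare variants are shared by chance among relatives. varfunnel implements
the staged prioritization funnel used to nominate a single candidate
predisposition variant from such data, under a rare, high-penetrance,
autosomal dominant model:

1. **Quality** — caller QUAL > 20, read depth > 5x in every genotyped
   member, and all caller-internal filters passed.
2. **Rarity** — minor allele frequency at most 0.1% in each available
   population source (1000 Genomes-style and non-TCGA ExAC-style columns);
   a variant absent from both panels is treated as novel and retained.
3. **Pedigree co-segregation** — every case with a non-missing genotype
   carries the alternate allele, no control carries it. Members with an
   intermediate phenotype (here: benign thyroid nodules) are *potential
   carriers* and impose no constraint in either direction.
4. **CADD** — scaled PHRED-like score > 10, i.e. the top 10% of possible
   variants by the PHRED scale definition $100\cdot10^{-s/10}$.
5. **Conservation** — GERP > 2.0, PhastCons > 0.3, PhyloP >= 3.0.
6. **Consensus deleteriousness** — at least 60% of the available calls from
   ten dbNSFP-style predictors (SIFT, PolyPhen2 HDIV/HVAR, LRT,
   MutationTaster, MutationAssessor, FATHMM, MetaSVM, MetaLR, PROVEAN) are
   deleterious.

Coding variants in known oncogenes, tumor suppressors or dominant familial
syndrome genes can be **rescued**: they bypass stages 4–6 but never the
quality, rarity or segregation stages, which encode the family evidence
itself.

Surviving candidates are *ranked*, never filtered, by gene intolerance
evidence (three intolerance percentiles, pLI for truncating variants,
missense Z for missense variants), and a generic ACMG/AMP 2015 evidence
combiner classifies a candidate from user-supplied evidence codes.

## Boundary semantics and missing data

The gate boundaries follow the threshold wording literally, and the test
suite pins them:

| quantity        | rule      | boundary value | decision |
|-----------------|-----------|----------------|----------|
| QUAL            | `> 20`    | 20.0           | fail     |
| depth           | `> 5`     | 5              | fail     |
| MAF             | `<= 0.001`| 0.001          | **pass** |
| CADD            | `> 10`    | 10.0           | fail     |
| GERP            | `> 2.0`   | 2.0            | fail     |
| PhastCons       | `> 0.3`   | 0.3            | fail     |
| PhyloP          | `>= 3.0`  | 3.0            | **pass** |
| vote            | `>= 60%`  | 6/10, 3/5      | **pass** |

Missing-data policy, where the underlying procedure is silent, is decided
once and documented here:

* **Missing genotypes are unconstrained, not failures.** The motivating
  family's causal allele was inherited from a deceased, untyped founder;
  a segregation filter that punished missingness would delete exactly the
  configuration the method exists for. Missing genotypes are counted in the
  decision (`n_missing`) so the analyst can see how much evidence supports
  a pass. A variant whose cases are *all* untyped is "uninformative" and is
  an error from `classify_segregation()` (a fail inside the cascade).
* **Missing MAF = rare.** Novel variants must survive the rarity gate.
* **Missing CADD fails** (configurable via `cadd_missing_fails`): CADD is
  the primary deleteriousness gate and a variant without it has no positive
  evidence at that stage.
* **Missing conservation scores are individually skipped** but at least one
  of the three must be present; they corroborate rather than form a hard
  conjunction over all three.
* **Missing predictor calls shrink the vote denominator** (the fraction is
  over non-missing calls), with a floor of `min_predictor_calls = 5`
  available calls; fewer available calls fail the vote unless the variant
  is rescued. dbNSFP tools frequently lack coverage, and a 3/5 vote carries
  the same 60% consensus as 6/10. The floor prevents a single stray "D"
  from passing a variant with nine missing calls.
* **Vote eligibility**: the genome-wide scan shortlists non-synonymous
  coding variants; by default synonymous and `other` consequences fail the
  vote stage. The eligible set is configurable (`vote_consequences`).
* **Half-calls** (`./1`) in VCF genotypes are conservatively missing.

Stage order is configurable; the default places rarity before segregation,
matching the reported funnel (the MAF-filtered variant count is reduced by
pedigree-based filtering). Because every predicate is computed per variant
independently, permuting the stage order changes the per-stage counts but
never the final candidate set — a property the tests verify.

## Gene intolerance ranking

No combining formula is published for the three intolerance percentiles, so
the package uses the symmetric choice: the mean of the *available*
percentiles, rescaled to [0, 1], with the neutral 0.5 when all three are
missing. The class score adds pLI (already in [0, 1]) for truncating
variants and `pnorm(mis_z)` for missense variants, mapping the unbounded Z
onto [0, 1]; a missing class score contributes 0. Missing intolerance data
can therefore never disqualify a candidate — the scores are ranks, not
cut-offs. Ties are broken by (chrom, pos) so the ranking is a deterministic
permutation.

## ACMG evidence combining

`combine_evidence()` is a generic implementation of the 2015 ACMG/AMP
combining standard; the rule table ships as a JSON fixture
(`inst/extdata/acmg_combining_rules.json`) listing the minimum counts per
evidence-strength category for each tier. Contradictory evidence (both a
pathogenic-side and a benign-side combination met) and no evidence both
yield VUS. The original study reported only the final VUS call for its
candidate without naming codes; the worked example in the tests
(`PM2 + PP1 + PP3 -> VUS`) is illustrative, not source-derived.

## Telomere assay quantification

* **T/S ratio**: $2^{-\Delta C_t}$ with $\Delta C_t = \overline{C_t}^{tel} -
  \overline{C_t}^{alb}$. Replicates are averaged within each run, a per-run
  T/S is formed, and run-level values are averaged (`aggregate =
  "runs_mean"`, the default, mirroring "triplicates, repeated twice"); a
  pooled alternative is exposed because the aggregation order is not
  specified by the protocol. No amplification-efficiency correction is
  applied (the formula is pure $2^{-\Delta C_t}$).
* **RTL**: sample T/S divided by the T/S of a reference DNA pool; the
  reference against itself is exactly 1.
* **ChIP enrichment**: the immunoprecipitated signal is normalized to the
  *total* input telomeric DNA, `chip / (input / input_fraction)`; the input
  lane is scaled up by the fraction of chromatin it represents. Whether the
  baseline is the input-normalized IgG lane or the input alone is left to
  the analyst — both normalizations are expressible with the same function.
* **Group comparison**: classical pooled-variance two-sided t-test; a
  zero-pooled-variance comparison is an error rather than a spurious
  infinity.

## The synthetic world

The generator exists because the family genome data are private. Its
defaults state the simulated world once:

* **Pedigree template**: a founder couple and nine children — four
  genotyped cases, three potential carriers (the founder mother among
  them), two genotyped controls, one untyped case, and the untyped deceased
  father through whom the planted allele enters (11 members, 9
  genotypable). This mirrors the studied family's structure and roles.
* **Planted variant**: heterozygous in the transmitting founder, dosage 1
  in every genotyped case, 0 in every control, Mendelian coin for carrier
  children; novel in both MAF sources; QUAL/depth/CADD/conservation drawn
  above the gates and at least 6/10 deleterious calls — it survives the
  cascade *by construction*, so recovery failures indicate cascade defects,
  not generator noise.
* **Background variants**: a true allele frequency from a discretized
  spectrum weighted toward rare sites (1e-4 … 0.3), founder genotypes at
  Hardy–Weinberg equilibrium, children by Mendelian transmission —
  genotypes independent of phenotype. Annotations come from a latent
  Bernoulli deleteriousness indicator (prior 0.05) that jointly shifts
  CADD (N(5,4) vs N(22,5)), GERP (N(0,2) vs N(4,1.5)), PhastCons
  (Beta(0.5,2) vs Beta(4,1)), PhyloP (N(0.5,1.5) vs N(5,2)) and the ten
  conditionally independent predictor calls (per-tool deleterious
  probability 0.15 vs 0.90, 15% missingness) — the simplest structure that
  produces realistically correlated scores and vote distributions. The
  benign CADD distribution is anchored so that roughly 10% of benign
  variants exceed CADD 10, consistent with the PHRED-scale meaning of the
  cutoff. QUAL is log-normal(log 60, 0.8), depth Poisson(30) per member,
  and 2% of variants fail caller-internal filters.
* **Reproducibility**: each variant is drawn from a deterministic substream
  keyed by `(seed, index)`, so enlarging `n_background` never changes
  earlier variants and identical configurations give byte-identical output
  files.

Because every distribution is parametric, the package also provides the
*closed-form* survivor probability (`expected_survivor_prob()`): the
segregation term sums Hardy–Weinberg founder-pair probabilities against the
role constraints (children conditionally independent given the founders);
the rarity term couples the frequency draw to the MAF-source missingness;
the CADD/conservation/vote terms are mixed over the latent indicator
because they are dependent through it. Calibration tests compare empirical
pass rates against this independent derivation at 3 binomial standard
errors.

**What a green test does not establish.** The generator has no linkage
disequilibrium, no shared haplotypes among relatives beyond single-site
Mendelian transmission, no population stratification, no sequencing
artifacts correlated across members, and annotation scores conditionally
independent given a single latent variable. Real familial data violate all
of these; in particular the real segregation-stage pass rate (thousands of
shared rare variants per family) is far higher than the independent-sites
null simulated here. The tests establish the *correctness of the
machinery*, not field performance.

## Scale of the shipped experiments

The planted-recovery suite runs 100 seeded datasets of 1,000 background
variants each (about half a minute on one CPU). The headline funnel counts
of the original genome-wide analysis (~100k rare variants) are not
reproducible at desk scale from private data and are out of scope for the
automated checks.

## Known limitations

* Dominant heterozygous inheritance only; recessive, X-linked, compound
  heterozygous and de novo models are out of scope.
* The closed-form segregation probability supports the founder-couple
  template (all children share both founders), not arbitrary pedigrees;
  `classify_segregation()` itself is general.
* Indels are taken as given (no left-alignment/re-normalization) and no
  liftover or annotation retrieval is performed — the package consumes
  already-annotated tables.
* The "local dataset" intolerance percentile is an opaque column; its
  construction is unpublished.
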