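# varfunnel

Family-based germline variant prioritization, with the wet-lab
quantification formulas that accompany a candidate-gene follow-up.

## Who this is for

Analysts working on rare, high-penetrance predisposition variants in cancer
families (the motivating use case is non-medullary thyroid carcinoma, where
family members split into **cases**, **potential carriers** with benign
nodules, and unaffected **controls**). Given an annotated multi-sample
variant table and an extended PED file, the package runs a staged funnel
and reports which variants survive and why:

```
quality (QUAL > 20, depth > 5x, caller PASS)
  -> rarity (MAF <= 0.1% in 1000G / non-TCGA ExAC columns; novel = rare)
  -> dominant co-segregation (all typed cases carry, no typed control does;
     potential carriers unconstrained)
  -> CADD (scaled PHRED score > 10)
  -> conservation (GERP > 2.0, PhastCons > 0.3, PhyloP >= 3.0)
  -> consensus vote (>= 60% of available calls from 10 dbNSFP-style
     predictors deleterious)
```

Coding variants in known cancer genes may be *rescued* past the
CADD/conservation/vote stages (never past quality, rarity or segregation).
Survivors are ranked — never filtered — by gene intolerance evidence
(intolerance percentiles, pLI for truncating variants, missense Z for
missense), and a generic ACMG/AMP 2015 combiner turns evidence codes into
the five-tier classification. A qPCR module computes telomere length as
T/S = 2^-dCt and RTL against a reference pool; a ChIP module computes
dot-blot fold enrichment normalized to total input telomeric DNA.

Because family genome data are private, the package includes a synthetic
generator: a two-generation pedigree template (founder couple, nine
children, 4/3/2 case/carrier/control among the nine genotyped members), a
planted heterozygous dominant variant entering through the untyped father,
and background variants with Hardy–Weinberg/Mendelian genotypes independent
of phenotype plus annotation scores tied to a latent deleteriousness
indicator — with closed-form survivor expectations for calibration.

## Worked example

```r
library(varfunnel)

# simulate a study: 1000 background variants + 1 planted causal variant
st    <- simulate_study(sim_config(seed = 42, n_background = 1000))
intol <- read_intolerance_table(system.file(
  "extdata", "intolerance_synthetic.tsv", package = "varfunnel"))
report <- run_cascade(st$variants, st$pedigree, filter_config(),
                      intolerance = intol)
report
```

```
Variant prioritization funnel: 1001 variants in
  quality         1001 ->    889
  rarity           889 ->    413
  segregation      413 ->      1
  cadd               1 ->      1
  conservation       1 ->      1
  vote               1 ->      1
Final candidates: 1
 rank      id chrom      pos ref alt gene consequence cadd_phred rescued
    1 planted     7 77378008   G   T POT1    missense     19.694   FALSE
 rank_score
   1.844802
```

Reading the funnel: 112 variants fail caller quality gates, 476 are too
common in the population panels, and the dominant segregation constraint —
four genotyped cases must carry, two controls must not — removes everything
except the planted variant, which then clears the deleteriousness gates.
`rank_score` is the mean intolerance percentile (rescaled to 0–1) plus the
normalized class score (here `pnorm(mis_z)` for a missense variant).

Segregation of a single genotype pattern, classification and assay math:

```r
members <- vt_members(st$variants)
gv <- setNames(as.integer(st$variants[1001, paste0("gt_", members)]), members)
classify_segregation(gv, st$pedigree)
#> Segregation: PASS (case carriers: 4, control carriers: 0, missing: 1)

combine_evidence(c("PM2", "PP1", "PP3"))
#> [1] "VUS"

ts_ratio(qpcr_measurement("mut", c(18.1, 18.0, 18.2), c(20.1, 20.0, 20.2)))
#> [1] 4            # dCt = -2 cycles => 2^2 = 4-fold telomere signal
```

A packaged fixture transcribes the motivating family's published genotype
pattern (synthetic annotation values, hence the filename):

```r
ped <- read_ped(system.file("extdata", "family5_synthetic.ped",
                            package = "varfunnel"))
vt  <- read_variant_table(system.file(
  "extdata", "pot1_family5_synthetic.tsv", package = "varfunnel"), ped)
run_cascade(vt, ped)$candidates$id
#> [1] "POT1_c85GtoT"
```

A thin CLI wraps the same functions
(`inst/cli/varfunnel.R simulate|prioritize|classify|telomere`).

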