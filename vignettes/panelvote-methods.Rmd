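---
title: "Consensus-vote variant prioritization and cohort phenotyping with panelvote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-vote variant prioritization and cohort phenotyping with panelvote}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelvote)
```

## The problem

Targeted gene-panel sequencing for Noonan syndrome and related
RASopathies yields, per proband, a table of annotated variants: genomic
coordinates, gene and transcript context, population allele
frequencies, a ClinVar assertion where one exists, and precomputed
functional predictions from a battery of dbNSFP-style tools. The
diagnostic question is which of these variants, if any, is a plausible
dominant pathogenic allele. `panelvote` implements a reusable,
fully testable version of a consensus-vote prioritization procedure:

1. **Rarity filter.** A variant is kept only if every *recorded*
   population minor allele frequency is below a threshold
   (default 0.01, against 1000 Genomes and exome-collection
   frequencies). Variants with no frequency record are kept: absence
   from population panels is what rarity looks like for novel alleles.
2. **Attribute filter.** Dominant-model defaults retain heterozygous,
   protein-altering (missense, nonsense, frameshift, splice), exonic or
   splicing variants.
3. **Consensus vote.** Each of 19 predictors casts a deleterious vote
   (below). Two selection hypotheses run in parallel: the *free*
   hypothesis keeps any variant with ≥ 10 of 19 votes; the *panel*
   hypothesis keeps variants in the 14-gene panel with ≥ 5 votes. The
   default mode is their union, and every survivor records which
   hypothesis(es) fired.
4. **Reconciliation.** ClinVar and family segregation evidence can
   overturn the vote (precedence below).

The cutoffs 10 and 5 are the procedure's published absolute counts
(roughly 50% and 25% of 19); they are configurable integers, not
fractions of non-missing tools.

## Binarizing 19 heterogeneous predictors

Eleven tools emit categorical calls and are counted as deleterious on
their conventional damaging tokens: SIFT, PolyPhen-2 HDIV/HVAR, LRT,
FATHMM, PROVEAN, MetaSVM, MetaLR and fathmm-MKL on "D";
MutationTaster on "A" or "D"; MutationAssessor on "H" or "M". Eight
tools emit scores only (GERP++, PhyloP, VEST3, DANN, CADD, integrated
fitCons, SiPhy 29-way, phastCons), for which a deleterious call is not
defined by the source procedure; `panelvote` ships widely used default
thresholds (CADD phred ≥ 20, DANN ≥ 0.96, VEST3 ≥ 0.5, GERP++ RS ≥ 4.4,
PhyloP ≥ 1.6, phastCons ≥ 0.8, SiPhy ≥ 12.17, fitCons ≥ 0.7), all
overridable via `tool_registry(thresholds = ...)`. These defaults are a
design decision of this package; sensitivity of the vote count to them
is bounded at eight votes.

A missing prediction votes neither way but stays in the denominator:
the cutoffs are absolute tool counts. Consequently a variant whose
19-slot profile is entirely missing (typical for frameshifts, which
most missense predictors do not score) can never pass either
hypothesis; `run_case()` reports such variants in a `vote_ineligible`
section rather than dropping them silently, because for a truncating
allele that is a reportable limitation of the voting stage, not
evidence of benignity.

```{r}
binarize_prediction("CADD", c(35, 12))
vote_count(study_fixture()$variants[1:3, ])
```

## Segregation classification

Carrier screening of relatives is summarized per variant by a fixed
rule cascade over *typed* members (carrier status resolved), assuming
full penetrance of a dominant allele:

1. any typed affected non-carrier, or typed unaffected carrier →
   `FAILS_TO_SEGREGATE`;
2. ≥ 2 affected carrier (half-)siblings whose shared typed parent(s)
   are non-carriers → `POSSIBLE_GERMLINE_MOSAICISM`;
3. exactly one affected carrier, both parents typed non-carrier →
   `DE_NOVO`;
4. ≥ 2 typed members, every typed affected a carrier and every typed
   unaffected a non-carrier, **and at least one typed affected
   carrier** → `SEGREGATES`;
5. otherwise `UNINFORMATIVE`.

The bolded condition in rule 4 is an implementation choice: without
it, a family in which only unaffected non-carriers were typed would be
labeled as segregating on no positive evidence. No penetrance
parameter is modeled; in a family with incomplete penetrance an
unaffected carrier will (conservatively for discovery, aggressively
for exclusion) fail the variant.

Reconciliation precedence: ClinVar benign/likely-benign excludes
outright; otherwise failed segregation excludes; otherwise ClinVar
pathogenic/likely-pathogenic confirms (`PATHOGENIC_KNOWN`) even when
the family is uninformative; otherwise supportive segregation upgrades
an unreported variant to `PATHOGENIC_NOVEL`; otherwise `VUS`. Benignity
outranking the vote mirrors the procedure's exclusion of a
vote-passing but ClinVar-benign CBL allele; ClinVar pathogenicity
outranking uninformative families mirrors its acceptance of known
alleles in singleton probands.

## The clinical module

`van_der_burgt_score()` evaluates the published major/minor (A/B)
diagnostic criteria from an editable YAML mapping onto standardized
feature codes. Unknown features never satisfy a criterion. A satisfied
major definition also counts as satisfying the minor definition of the
same criterion; under the strict published combination rule,
upgrading a minor manifestation to major could otherwise withdraw a
"definite" diagnosis, which no clinician would accept — with
A-implies-B counting the score is monotone in added features.

`frequency_table()` stratifies feature counts by age band or ancestry;
percentages are always recomputed from counts and formatted at one
decimal with round-half-even (so 5/16 prints 31.2 and 17/26 prints
65.4). Age bands follow the reporting convention newborn < 2 months,
infant 2–12 months, child 1–12 years, adult > 18 years; 12–18 years is
not a reported band and is flagged `unbanded`.

## Synthetic data and the study fixture

The generator (`simulation_config()`, `generate_case()`,
`generate_cohort()`) emulates per-proband annotated variant sets with
planted truth: common variants (MAF ≥ 0.01), rare benign variants
(votes below the panel cutoff), planted pathogenic panel variants
(heterozygous missense, MAFs absent, votes ≥ the free cutoff),
ClinVar-benign decoys (vote-passing but archived benign), non-panel
decoys (votes between the cutoffs on a non-panel gene), and optionally
non-segregating decoys. Pedigrees are drawn from a scenario mix
(proband-only, de novo trio, dominant segregating, mosaic
half-siblings); planted variants under an uninformative scenario carry
a ClinVar pathogenic assertion so that recoverability holds by
construction. Defaults mirror the reference study's shape (16 cases,
26-patient cohort, ancestry and sex mixes, tabulated feature
prevalences); per-case background counts (30 common, 10 rare benign,
1 planted, 1 benign decoy, 2 non-panel decoys) are unconstrained by
any published value and freely configurable. Each case seeds its own
RNG stream (`seed + 7919·case`), so identical config + seed is
byte-identical and cases regenerate independently.

What the generator does **not** emulate: realistic allele-frequency
spectra, haplotype or linkage structure, positional biology (background
positions are uniform over approximate gene-body intervals in a
packaged synthetic BED stub), caller artifacts, and correlated
predictor errors — predictor votes are planted, not modeled. Passing
the planted-recovery and separability suites therefore demonstrates
the logic of the filtration cascade, not calibration on real data.

`study_fixture()` is a deterministic (RNG-free) reconstruction of the
reference data set from printed values: 16 proband variant sets
containing the five reported pathogenic variants (with loci,
transcripts, exons, HGVS and ClinVar IDs), the two vote-passing CBL
decoys, per-proband background that exercises every filter stage, the
mosaicism and large-dominant-family pedigrees, and a 26-patient
cohort whose audited marginal counts match the printed tables.
Published tables constrain only margins; per-patient feature
co-occurrence is a fixture choice. Where the two stratified tables
disagree on a feature's total (epicanthic folds: 16 by age band vs 17
by ancestry), the fixture satisfies the ancestry margin and places the
extra carrier in the child band. Positions of the two CBL decoys are
synthetic placeholders (not printed in the source), and
`audit_study_fixture()` re-derives every encoded count:

```{r}
checks <- audit_study_fixture()
all(checks$pass)
```

## A worked run

```{r}
fix <- study_fixture()
res <- run_cases(fix$variants, filter_config(), fix$pedigrees,
                 fix$carriers)
s <- summarize_cases(res)
unlist(s$stage_counts)
s$detection$percent
```

Seven variants survive the consensus stage; reconciliation excludes
one as archived-benign and one as non-segregating, leaving five
pathogenic variants in 5 of 16 probands (31.2%).

## Numerical and scale choices

All percent output uses one-decimal round-half-even. Problem sizes in
the test suite are desk-scale by design: property suites run on pools
of 30–100 synthetic variants, the planted-recovery check on 100
single-case seeds, and the binomial prevalence check on a 2,000-patient
cohort — sizes at which every invariant is exercised in seconds while
brute-force oracles remain enumerable. Degenerate inputs are defined
errors (empty cohort, empty case list, zero denominator) or defined
no-ops (empty variant set flows through all stages); ties at cutoffs
are inclusive (`votes ≥ cutoff`, `MAF < threshold` strict).

## Known limitations

- Dual-hypothesis voting is a screening heuristic, not ACMG/AMP
  classification; no evidence weighting or Bayesian integration.
- Full-penetrance segregation rules; a single mistyped sample flips a
  family to `FAILS_TO_SEGREGATE`.
- Score-tool thresholds are package defaults, not part of the source
  procedure.
- The fixture reproduces printed margins, not patient-level reality;
  conclusions about real-data performance must come from real data.
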