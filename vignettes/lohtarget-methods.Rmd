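---
title: "Methods: LoF/LOH target discovery, CYP2D6 phenotyping and differential-toxicity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LoF/LOH target discovery, CYP2D6 phenotyping and differential-toxicity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohtarget)
```

# Scope and model

`lohtarget` formalizes a three-stage strategy for exploiting loss of
heterozygosity (LOH) therapeutically: find genes whose loss-of-function
(LoF) alleles are common enough in the population that many patients are
heterozygous, and whose loci are lost often enough in tumors that the tumor
plausibly retains only the LoF copy; genotype the pharmacogene of interest
(CYP2D6) in patient-derived material; and identify drugs whose toxicity
depends on that gene's activity. This vignette records the package's own
account of each model, the tunable parameters, the numerical choices, and
what the synthetic-data generators do and do not emulate.

# Consequence annotation

A variant is annotated against a transcript model (exons, strand, CDS
sequence) into one of four LoF mechanisms or `none`:

* **splice_snv / splice_indel** — the variant alters a canonical splice
  dinucleotide. Donor sites are the first two intronic bases and acceptors
  the last two, in the transcript's reading direction, so on the minus
  strand the donor sits at the genomically high end of the intron. A
  deletion "spans" the site if its reference interval intersects the 2-bp
  window; an insertion only if its insertion point falls strictly inside it
  (an insertion flush against the dinucleotide leaves both bases
  adjacent and is not called).
* **stop_snv** — an exonic substitution whose mutated codon is TAA/TAG/TGA
  on the coding strand. This requires a CDS sequence; calling it without
  one is a configuration error rather than a silent `none`.
* **frameshift_indel** — an exonic indel whose net length change is not
  divisible by 3. In-frame indels are deliberately `none`: the cascade
  targets unambiguous LoF mechanisms only.

Indel alleles are reduced to their minimal representation (shared
suffix, then shared prefix, trimmed) before any coordinate logic, so
VCF-style anchored alleles and pre-normalized alleles give identical calls.
All internal coordinates are 0-based half-open; VCF/GFF3 (1-based) and
BED (0-based) are converted at the I/O boundary.

The *protein fraction* of a truncating variant is the index of the first
affected codon, counted in translation order, divided by the codon count.
For deletions this is the leftmost affected base *in translation order*
(i.e. the genomically rightmost base for minus-strand genes); for
insertions, the first codon whose reading frame changes. The published
table's "percentage of the protein" column is not defined as lesion
position versus portion retained; the package computes the
first-affected-codon position and documents that choice here. All
transcribed values in the shipped table lie inside the 10–90% band under
either reading.

# The filter cascade

`run_cascade()` applies, in order: consequence annotation → gene-family
exclusion → allele frequency → heterozygosity → protein position →
expression → LOH → all-transcripts concordance → optional rsID validation.
Defaults (all user-overridable through `lof_thresholds()`):

| parameter | default | meaning |
|---|---|---|
| `af_min`, `af_max` | 0.005, 0.995 | discard AF < 0.5% or > 99.5% |
| `het_min`, `het_max` | 0.10, 0.90 | observed heterozygous-sample fraction |
| `pos_min`, `pos_max` | 0.10, 0.90 | truncation position band |
| `expr_min` | 300 AU | required in normal *and* cancer tissue |
| `loh_min` | 0.15 | LOH fraction in ≥ 1 common cancer type |

Boundary inclusivity follows the discard rules' strict inequalities: "AF
< 0.005 discarded" keeps 0.005 exactly, "expressed at < 300 AU removed"
keeps 300, "< 15% of cases discarded" keeps 15%, and the 10–90%
heterozygosity and position bands are closed (the published final set
itself retains 10%-HET variants, fixing the inclusive reading).

Heterozygosity is the observed fraction of heterozygous genotyped samples,
not the Hardy–Weinberg expectation; when a call set carries only site-level
AF, `het_from_af = TRUE` substitutes 2·af·(1−af) and logs the
approximation. The published table also contains one variant at 94% HET in
its final set, above the stated retention band; the package applies the
stated rule (such a variant is dropped at the heterozygosity stage) rather
than guessing at an undocumented exception.

Internally every filter is a pure predicate evaluated per variant; the
"stage at which a variant drops" is the first failing stage in cascade
order. This makes the per-stage retained counts, the survivor set's
invariance to stage permutation, and equivalence with brute-force filter
re-evaluation structural properties, all of which are still asserted by
independent re-implementation in the test suite.

The family filter is table-driven (gene → tag), not pattern-driven;
`default_family_table()` ships an explicitly heuristic prefix mapping
(OR*/TAS2R*/OPR[MKDL]*/KRT*/KRTAP*) for convenience. The validation stage
accepts arbitrary rsID lists (the original analysis used HapMap, dbSNP,
exome-chip and in-house genomes) and keeps a variant present in at least
one list; with no lists supplied the stage is skipped.

Genes are classified from their surviving variants only: one mechanism
gives classes 1–4 (stop SNV, splice SNV, frameshift indel, splice indel),
two or more distinct mechanisms give class 5.

# CYP2D6 diplotype and phenotype

Calls are QC-filtered at quality ≥ 20 and strand bias ≤ 0.90 (both
inclusive on the keep side, as the published strict exclusion rules imply;
strand bias is max(fwd, rev)/(fwd+rev) over alt-supporting reads when raw
counts are provided). Star alleles are then assigned from the
allele-defining SNVs in the shipped activity table — only alleles with a
single diagnostic SNV are callable from these inputs (∗4 via rs3892097,
∗33 via rs28371717; the table is user-extendable). The VAF thresholds for
copy assignment (0.2–0.8 = heterozygous, one copy; > 0.8 = two copies;
< 0.2 = absent) are package choices: the source analysis states only that
VAF was used "to some extent". Unfilled positions default to ∗1, and more
than two implied copies is an ambiguity reported per sample, not a crash.

Two alleles appear under two activity levels in the underlying nomenclature
lists (∗53 in full and semi; ∗41 in semi and inside the null range
∗40–∗42). The table keeps the first listing for both, warns, and is
overridable.

Phenotype prediction counts fully functional (F), semi (S) and null (N)
alleles: UM iff F > 2; EM iff F = 2, or F = 1 with S ≥ 1; IM iff F = 1
with only null partners, or S ≥ 2, or S = 1 with null partners; PM iff no
activity-bearing allele. The {semi, null} diplotype and all multisets of
size > 2 other than pure-full UM are not covered verbatim by the published
rule text; the package classifies them by the same counting logic and
flags each such call `extrapolated`. Copy numbers above 2 (needed for UM)
are representable but not inferable from the supported inputs — short-read
CNV calling is out of scope.

# Dose–response and hit calling

Viability is `100·(signal − background)/(dmso − background)`, unclipped.
The logistic model is `V(x) = bottom + (top − bottom)/(1 + (x/IC50)^h)`.
The `two_param` variant (screen stage) fixes top = 100 and bottom = 0 and
fits IC50 and the Hill slope; `four_param` (confirmation/organoid stage)
frees all four. Fitting is bounded Levenberg–Marquardt (minpack.lm) on
log10(IC50), initialized at the geometric mean of the positive doses with
h = 1, with three jittered restarts; fits are declared unconverged when the
optimizer fails, when the IC50 leaves the dose range × [10⁻², 10²], or when
no dose achieves a measurable response (all viabilities ≥ 80%). Requiring
≥ 3 (two-parameter) or ≥ 5 (four-parameter) distinct positive doses mirrors
the original assay design.

Hit calling is two-stage. Stage 1 first discards compounds inert at the
10 µM reference dose — operationalized on the *minimum* viability across
the two lines, since a compound inert in both lines is uninformative and
the source text does not specify a line — then requires the
per-concentration viability ratio (CYP2D6-proficient over LoF line,
technical replicates averaged arithmetically) to exceed 1.2 strictly at
some concentration; concentrations where the LoF-line viability is ≤ 0 are
skipped as a division guard. Confirmation requires an IC50 ratio
(proficient/LoF) of at least 2, inclusive. Input concentrations are nM (as
screening grids are printed) and converted to µM at parse time; the hit
rate is reported as a percentage with one decimal.

# Synthetic data: what it emulates, what it does not

The generators exist so that every stage is testable with known truth and
no external downloads; their defaults are the study conditions the pipeline
targets.

* **Genotype cohorts** (`simulate_cohort()`): one toy 3-exon gene locus per
  planted variant (exon lengths multiples of 3, 200-bp introns with
  canonical GT…AG, alternating strands), genotypes i.i.d. Hardy–Weinberg at
  the planted allele frequency, cohort size 1000. Each `designed_fate`
  realizes exactly one filter violation at the annotation level:
  pass-all variants plant at p = 0.2 (expected het 0.32, comfortably inside
  every band at n = 1000), `fail_het` at p = 0.02 (het ≈ 4%, AF passing),
  `fail_position` at protein fraction 0.05, and the annotation fates tweak
  expression (200 AU), LOH (5%) or family tags. One caveat is structural:
  `fail_af` plants at p = 5·10⁻⁴, and under Hardy–Weinberg any AF below
  0.005 forces heterozygosity below 1%, so the AF decoy necessarily also
  violates the (later) heterozygosity filter. The guarantee the generator
  makes — and the tests assert — is therefore that each decoy violates its
  designed filter and nothing at an *earlier* stage, dropping exactly at
  its designed stage. Real cohorts need not be in Hardy–Weinberg
  equilibrium (the 94%-HET published variant cannot arise from this
  fixture); no linkage disequilibrium, population structure, or read-level
  data are simulated.
* **Screening plates** (`generate_screen()`): logistic response per line
  on the printed 10-point grid (0–10,000 nM), additive Gaussian noise on
  the percent-viability scale truncated at 0 (the source states no noise
  model; 2% is a typical CellTiter-Glo replicate CV), three technical
  replicates, raw signals emitted (background 500, DMSO 10,000 RLU) so the
  package's own normalization is exercised. Planted hits use a wild-type/
  LoF IC50 ratio of 4 with the LoF IC50 at 1 µM (mid-grid); non-hits are
  equally toxic in both lines at 1 µM. No plate-position effects, edge
  artifacts or Z′-factor QC are modeled.
* **Organoid call sets** (`generate_organoid_calls()`): defining SNVs of
  each planted allele at VAF ~ Beta(k·c, k·(1−c)) with c = copies/2 and
  concentration k = 50 (c capped at 0.97 so homozygous calls center just
  below 1 — the mean of this parameterization is c, which is what a
  read-depth model should center on), plus per-sample decoy calls of which
  a configurable fraction carries a QC-failing quality or strand bias.

Passing tests on these fixtures demonstrates the *logic* of the cascade,
caller and screen under controlled conditions; it does not demonstrate
performance on real population VCFs, real short-read CYP2D6 data (hybrid
alleles, the ∗5 deletion and phasing are explicitly out of scope), or real
plate data with spatial artifacts.

# Problem sizes and reproducibility

Every generator takes an integer seed and is byte-identical under it; CLI
runs write a manifest (package/R versions, seed, configuration, input
checksums, no timestamps). The test suite exercises: designed-fate
recovery over 100 seed-swept cohorts of 10 planted variants × 1000
samples; cascade–oracle equivalence on cohorts of ≤ 50 variants; IC50
recovery over 200 noisy replicates with Hill slopes in [0.5, 3]; a
1000-compound null screen for the false-positive rate; and the full
525-compound screen with 12 planted hits used by the acceptance script.
These sizes keep statistical margins wide (e.g. the separation between a
4% -heterozygosity decoy and the 10% threshold is ~7 binomial SEs at
n = 1000) while remaining desk-scale.

# Known limitations

* Genome-scale counts from real population data (variant totals in the
  hundreds of thousands) are not reproducible from fixtures; the package
  reproduces the published *final-set* classification and the screen
  arithmetic, and substitutes property-based checks for the upstream
  counts.
* NMD-escape modeling, protein-domain annotation and expression
  normalization pipelines are out of scope; expression and LOH enter as
  user-supplied tables.
* The two-stage hit criteria are sensitive to near-zero denominators in
  the viability ratio; the division guard plus IC50-ratio confirmation
  keeps the false-confirmation rate below 1% at 3% noise, but heavier-
  tailed noise would require a variance-stabilized ratio.
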