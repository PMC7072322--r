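---
title: "Models and methods behind earlygc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind earlygc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`earlygc` implements the computational core of a tumor/normal sequencing
analysis of early (non-invasive, differentiated-type) gastric cancer:
somatic variant filtering, CpG-aware background mutation-rate modelling
with per-gene significance testing, Bethesda microsatellite-instability
classification, mutation-spectrum tabulation, and cohort contingency
statistics. Because patient-level sequencing data of this kind is
rarely shareable, the package is built around a synthetic cohort
generator with known ground truth, so that every downstream stage can
be validated end to end. This vignette explains the models, the tunable
parameters, and the design decisions a maintainer would want recorded.

## Somatic filtering

Two rulesets are implemented, reflecting the two sequencing stages such
studies use.

The **exome (discovery) ruleset** keeps a candidate call if and only if
all of: tumor depth >= 30 with >= 3 mutant reads (EX1); mutant allele
fraction >= 10% of all reads at the site (EX2); matched-normal depth >=
30 with at most one mutant read (EX3); minimum per-strand fraction of
mutant reads >= 0.2 (EX4); and the call is not a known population
variant -- membership in dbSNP 137, HapMap or 1000 Genomes is consumed
as a boolean flag on the record (EX5). The **targeted (deep
sequencing) ruleset** requires variant score >= 0.3 with minimum base
quality 30 (TG1), call quality >= 100 (TG2), allele frequency >= 0.1
(TG3), >= 10 mutant reads (TG4), >= 2 read pairs per barcode (TG5), and
the same known-variant exclusion (TG6).

All thresholds are inclusive ("at least"/"at most"); the strand
criterion excludes records whose minimum strand fraction is *strictly*
below 0.2. Two conventions were genuinely open and are fixed as
follows: "all reads" in EX2 means the depth reported on the record
(upstream quality masking is out of scope), and a record with zero
mutant reads is rejected under EX1 without evaluating the undefined
strand ratio. Rejected records carry *every* violated criterion rather
than the first, which makes the rejection accounting testable
(`|kept| + |rejected| = |input|`, each rejection labelled). Thresholds
live in `exome_thresholds()` / `targeted_thresholds()` with the
published values as defaults; any override is flagged on the report and
echoed to the log.

## Background mutation model and SMG testing

The number of mutations in a gene reflects its length and the local
background rate, so observed counts are compared with a background
estimated from **non-coding mutations only** (the coding signal under
test never informs its own null). The genome is divided into 1-Mb bins
and three rates are estimated per bin and pooled: point mutations per
non-coding CpG site, per non-coding non-CpG site (CpG sites are
hypermutable through deamination and must not be averaged into the
rest), and indels per non-coding bp. Each rate is
`mutations / (eligible sites x n_samples)`; a category with zero
eligible sites yields rate 0 with a warning rather than a division
error. Bins with fewer than `min_bin_mutations` (default 50) non-coding
mutations fall back to the pooled rates; a gene's rates are the
footprint-length-weighted average over the bins it overlaps. The 1-Mb
binning matters on real genomes with regional rate variation; on the
homogeneous synthetic genomes it simply reduces to the pooled rates.

Per-gene opportunity uses **fractional (Nei--Gojobori-style) site
counting**: each coding position contributes 1/3 site per possible
substitution, classified synonymous or nonsynonymous under the standard
nuclear genetic code (stop is treated as an amino-acid symbol, so stop
gain/loss is nonsynonymous), and assigned to the position's CpG
category. Counts are kept as integer thirds internally, so the
conservation identity `syn + nonsyn = coding length` holds exactly, not
merely to floating-point tolerance. The expected protein-altering count
per gene is

```
E_g = n_samples * ( r_cpg * S_cpg(g) + r_noncpg * S_noncpg(g) + r_indel * L(g) )
```

with `S_*` the nonsynonymous site counts and `L` the coding length.

**The exact test.** The per-gene test is stated as Fisher's exact test
on observed protein-altering counts versus expectation, but a 2x2
construction is not uniquely determined by that description. The
construction used here -- flagged prominently as this package's own
reconstruction -- converts heterogeneous site categories into
*effective trials*: site counts are scaled by (category rate /
non-CpG point rate), the reference category, plus `L * r_indel /
r_noncpg` for indel opportunity, times `n_samples`, rounded to the
nearest integer. The table is then

```
          successes              failures
gene      obs_g                  opp_g - obs_g
others    obs_rest               opp_rest - obs_rest
```

tested one-sided (enrichment) -- driver detection is a directional
alternative -- and BH-adjusted with significance at q < 0.05.
Rounding the effective opportunities is harmless at the scales involved
(opportunities are thousands of trials per gene). A Poisson
formulation (`ppois(obs - 1, E, lower.tail = FALSE)`) is available
behind `method = "poisson"` as a cross-check; the Fisher reconstruction
is the default. Cohort-level association tests, by contrast, are
two-sided: those analyses are reported as associations, not
pre-registered directional hypotheses.

Degenerate inputs are refused loudly: a cohort with no non-coding
mutations makes the background unidentifiable and `run_smg()` stops; a
zero non-CpG rate makes the effective-opportunity weights undefined and
is likewise an error. Results are sorted by q, then p, then gene id,
which fixes tie-breaking deterministically.

## MSI classification

The Bethesda 5-marker panel (BAT25, BAT26, D2S123, D5S346, D17S250) is
consumed as per-marker instability flags; electropherogram comparison
itself is upstream wet-lab work. Instability in more than 30% of
markers is MSI-H, more than none but at most 30% is MSI-L, and no
unstable marker is MSS. With 5 markers the exact-30% boundary is
unreachable, but the generic-panel variant fixes the convention:
exactly 30% is MSI-L, because MSI-H requires strictly more than 30%.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
not sequencing physics. Chromosomes are uniform-random A/C/G/T with the
CpG dinucleotide density *forced*: CpG is first depleted to zero, then
`round(density x (L-1))` CG dinucleotides are planted at sampled
non-adjacent positions, so the realized density is controlled rather
than emergent. Genes are two-exon CDS models (100-bp intron,
alternating strand) laid out on an even pitch, never overlapping.

True somatic SNVs are Poisson draws per site category; CpG-site
substitutions are deamination-biased (C>T / G>A with probability 0.8),
which is what makes C>T the modal class of simulated spectra, as it is
in real gastric tumors. Indels are Poisson per bp with lengths 1-3.
Driver genes receive additional nonsynonymous mutations at
`(multiplier - 1) x` the base rate over their nonsynonymous
opportunities, each drawn position-weighted by local rate and forced to
a nonsynonymous alternative allele, so the driver's effective
nonsynonymous rate is exactly the multiplied background.

Read evidence of true events is drawn around `depth_mean` (Poisson) and
`vaf_mean` (binomial), strand split binomial(alt, 0.5), then *minimally
and deterministically adjusted* into the filter-passing region: depth
clamped to >= 30, mutant reads to >= max(3, ceil(0.1 x depth)), strand
counts clamped into [ceil(0.2 x alt), alt - ceil(0.2 x alt)], normal
mutant reads capped at 1. True events therefore pass the exome filter
*by construction* -- filter sensitivity on truth is 1 by design, which
makes the filter tests sharp; specificity is probed separately by
artifact records, each violating exactly one named criterion
(low depth -> EX1, normal support -> EX3, strand bias -> EX4, known
flag -> EX5). Germline/population membership is represented only by
the known-variant flag, multi-allelic sites are never emitted, and a
truth table accompanies every cohort.

What the generator does **not** emulate -- and hence what passing tests
do not establish about real data: read-level errors and mapping
artifacts, subclonal VAF structure and clonal evolution, regional
mutation-rate covariates (expression, replication timing), transcript
isoforms, and indel realignment ambiguity. Tests against this
generator validate the *statistical machinery*, not robustness to those
real-data complications.

### Default parameters

| parameter | default | why |
|---|---|---|
| `rate_noncpg` | 5e-6 /site/sample | total point burden ~6.9/Mb, inside the 0.67-18.76/Mb range observed across early gastric cancer exomes |
| `rate_cpg` | 5e-5 | 10:1 CpG:non-CpG, the canonical deamination excess |
| `rate_indel` | 5e-7 /bp/sample | indels a minor fraction of events, as observed |
| `cpg_density` | 0.02 | CpG-depleted genome, ~2% of dinucleotides |
| `depth_mean` | 105 | typical exome mean depth in such studies |
| `vaf_mean` | 0.3 | clonal events in high-purity biopsies |
| `n_samples` | 19 | discovery-cohort scale |
| genome | 2 x 500 kb, 200 genes x 600 bp | large enough for stable background estimation, small enough for replicate studies |

The point rates were fixed once, before any calibration runs, by an a
priori power analysis of the replicate study designs the package
ships (a x50 driver over 1 kb in 30 samples should yield ~7-8 expected
protein-altering mutations, comfortably detectable, while a driver-free
200-gene cohort of 20 samples should yield essentially no BH
discoveries); they sit deliberately in the upper-middle of the
plausible burden range and are not revisited.

### Problem sizes of the replicate studies

The shipped calibration suites use: background-rate recovery over 100
replicate cohorts of 10 samples on a 1-Mb genome; null FDR control over
200 replicates of 200 genes x 20 samples; driver power over 100
replicates with a x50 driver of 999-bp CDS in 30 samples; spectrum
composition over 3 replicate cohorts, with the modal substitution class
taken on the pooled spectrum (a single ~130-SNV cohort mis-ranks the
modal class in about 0.5% of draws; the pooled mode is the cohort-level
claim and is stable). These sizes give 3-sigma Poisson envelopes
and binomial standard errors small enough to be informative while
keeping a full run of the suite in the minutes range on one CPU.

## Numerical and formatting conventions

Internal coordinates are 0-based half-open; VCF and GFF3 I/O convert
from/to 1-based (BED exports would be 0-based half-open). Frequencies
are reported in percent with *half-up* rounding to one decimal (14/49
-> 28.6), not banker's rounding. A variant overlapping several genes
is assigned every overlapping gene for the cohort matrix but counted
once (first gene in lexicographic order, deterministically) for burden
and SMG observed counts. The recurrence rule "mutated in more than
three patients with a rate above 10 mutations/Mb" is interpreted with a
cohort-aggregate numerator over the gene's coding footprint --
the phrasing is ambiguous between per-sample and aggregate readings, so
both numerator and denominator are reported in the output table.
Benjamini-Hochberg and Fisher's exact test are delegated to
`stats::p.adjust` / `stats::fisher.test`; the test suite checks both
against independent brute-force implementations (step-up formula;
hypergeometric enumeration via `lchoose`).

## Known limitations

The background model is CpG/non-CpG only -- no covariate-based rates
(MutSigCV-style), no CNA-aware burden, no signature stratification
beyond the deamination split. The effective-opportunity Fisher table is
a reconstruction, not a published construction; the Poisson switch
exists precisely so the two can be compared. Indels are pooled as
"protein-altering" without frameshift/in-frame subclassification.
Replication-stage and discovery-stage testing share one machinery.
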