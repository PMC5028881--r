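---
title: "Methods: variant scoring, phasing and clinical metrics in ph1kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant scoring, phasing and clinical metrics in ph1kit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ph1kit)
```

`ph1kit` implements the desk-side genetic workup used for families with
primary hyperoxaluria type 1 (PH1), an autosomal recessive disorder of the
liver-specific enzyme alanine:glyoxylate aminotransferase (AGT, gene
*AGXT*). This vignette documents the model behind each module, the
parameters and their defaults, the emulation scope of the synthetic-data
generators, and the numerical decisions that were made where the underlying
conventions are ambiguous.

## 1. Variant notation

`parse_variant()` accepts protein-level missense/nonsense notation
(`p.M49L`, `p.R333*`), cDNA substitutions and duplications (`c.145A>C`,
`c.33dupC`), paired notation (`p.M49L (c.145A>C)`), and the legacy
intronic marker `IVS1+74bp` (a 74 bp duplication in intron 1). For paired
notation the codon/nucleotide consistency is enforced: the cDNA position
must fall within codon `p`, i.e. within `[3p - 2, 3p]`. Stop codons may be
written `*`, `X` or `Ter`; three-letter amino-acid codes are accepted and
normalised to one-letter codes. Failures raise classed conditions
(`ph1_parse_error`, `ph1_consistency_error`) so callers can distinguish
"unparseable" from "internally contradictory".

## 2. Grantham distance

The pairwise amino-acid distance matrix of Grantham (1974) is embedded as
the published integers (range 5–215, symmetric, zero diagonal). The matrix
was verified against the generating formula

$$ D_{ij} = \rho \left[ \alpha (c_i - c_j)^2 + \beta (p_i - p_j)^2 +
   \gamma (v_i - v_j)^2 \right]^{1/2} $$

with composition $c$, polarity $p$ and molecular volume $v$, and the
published normalisation that sets the mean of the 190 pairs to 100. All
cells agree with the recomputation to within rounding except the
historical Asp–Trp cell, where the published table prints 181 while the
formula yields about 190.5; the package deliberately reproduces the
*published* value, because downstream scoring conventions were calibrated
against the printed table. The unit tests encode this exception explicitly.

## 3. Pathogenicity rubric

`score_variant()` combines two sub-scores.

**Grantham points.** Distances are binned: `[0, 60)` → 1 point,
`[60, 78.3]` → 2, `[78.4, 93.4]` → 3, `> 93.4` → 4. Any substitution that
creates or removes a cysteine scores 5 points regardless of distance
(cysteine substitutions disrupt disulfide chemistry); this override is
applied *before* binning. The published bin edges leave a gap: a distance
strictly inside `(78.3, 78.4)` belongs to no bin. Since all Grantham
distances are integers the gap is unreachable in practice, but the binning
function is defined on the reals, so the gap is resolved by assigning 3
points (the higher neighbouring bin) with a warning. This is a
conservative choice — an unclassifiable boundary case should not silently
lower a pathogenicity call.

**Conservation points.** Conservation is counted on a multiple sequence
alignment of eight vertebrate AGT homologs *including* the human reference
sequence: `conservation_count()` maps the human residue position to an
alignment column (gaps in the reference do not consume positions) and
counts sequences whose column character equals the reference residue,
case-insensitively; gap characters never count. The strict 8-species
rubric (`mode = "strict8"`) awards 8/8 → 5 points, 6–7 → 4, 4–5 → 3,
1–3 → 1. With a panel of a different size, `mode = "proportional"`
rescales the count to an 8-species equivalent and warns that the rubric is
being extrapolated beyond its calibration.

**Total and class.** The total (Grantham + conservation points) lies in
`[2, 10]`. Classification: total ≥ 8 → `high`, 6–7 → `moderate`,
≤ 5 → `probably_nonpathogenic`. The verbal convention from which this
rubric derives describes "moderate" as roughly 6–8 and "high" as ≥ 8,
which overlap at exactly 8. The package gives `high` precedence at 8: a
score of 8 requires either a cysteine substitution or near-perfect
conservation together with a radical exchange, both of which are strong
evidence, so the boundary case is resolved upward. This decision is
documented here, enforced in `classify_total()`, and pinned by tests.

Nonsense variants are refused by the missense rubric with a
`ph1_not_missense_error` whose message states the convention: a stop gain
is a null allele, presumed deleterious, and needs no scoring. A mismatch
between the variant's reference residue and the alignment's human sequence
raises `ph1_reference_mismatch_error` rather than scoring against the
wrong residue.

## 4. Pedigrees, phasing, segregation

A `pedigree()` holds a member table (id, father, mother, sex, affected)
and a genotype dose matrix (individuals × variants; entries 0/1/2 or `NA`
for untyped). Construction validates parental references, sexes of
parents, and acyclicity; `check_mendelian()` flags any child/parent trio
whose doses are jointly impossible, treating any missing genotype in the
trio as uninformative rather than as a violation.

**Phasing model.** The *AGXT* variants of interest lie within one small
gene, so the model assumes **no recombination** between them within the
pedigree: each founder chromosome is a fixed haplotype transmitted intact.
Under the compound-heterozygote hypothesis there are exactly two mutant
founder haplotypes, H1 and H2, plus the wild-type background.
`phase_variants()` enumerates the $2^{K-1}$ assignments of the $K$
alt-carrying variants to {H1, H2} (the first variant is pinned to H1 to
break the label symmetry) and, for each assignment, asks whether every
individual can be given an unordered pair of haplotypes from
{WT, H1, H2} that (a) reproduces their observed doses (missing doses
constrain nothing) and (b) respects transmission — each non-founder
receives exactly one haplotype from each parent. The transmission check is
a depth-first search over individuals in parents-first (topological)
order. Exactly one consistent assignment → `resolved`; several →
`ambiguous` (all consistent assignments are reported); none →
`inconsistent`. To keep the search honest rather than heuristic, the
function refuses more than 6 variants or more than 10 founders
(`ph1_size_error`) instead of silently sampling.

When the phased set includes the intron-1 duplication marker, the
haplotype carrying it is labelled **AGT-Mi** (the "minor" *AGXT*
haplotype, on which the marker rides) and the other mutant haplotype
**AGT-Ma** (the "major" haplotype).

**Co-segregation.** `cosegregation_test()` classifies each member as
biallelic (mutant haplotype dose ≥ 2, i.e. one from each parental side),
carrier (1), noncarrier (0) or untyped (every genotype missing), and
checks the autosomal recessive expectations: every affected member must be
biallelic and no unaffected member may be. With partially typed
individuals the haplotype dose is computed from the typed variants only;
a partially typed member with no observed alt allele counts as dose 0 for
classification, which is the standard "observed data" convention and is
documented in the function help. With `strict = FALSE` violations become
warnings instead of errors, which is how exploratory runs on imperfect
data are expected to proceed.

**Allele frequency.** `allele_frequency()` is the simple unbiased
estimator: alt-allele count divided by twice the number of typed
individuals for that variant.

## 5. Clinical metrics

**MDRD eGFR.** `egfr_mdrd()` implements the 4-variable MDRD study
equation. The default is the **classic 186-coefficient** form,

$$ \mathrm{eGFR} = 186 \times (\mathrm{Scr}/88.4)^{-1.154} \times
   \mathrm{age}^{-0.203} \times 0.742\ [\text{if female}] , $$

with serum creatinine supplied in µmol/L and converted by the factor 88.4.
The IDMS-traceable 175-coefficient variant is available as
`variant = "idms175"`. The classic form is the default because the
clinical records this package is designed around predate routine IDMS
standardisation; for the three index patients the 175 form yields values
about 6 % lower and visibly disagrees with their recorded eGFRs, whereas
the 186 form reproduces them.

A numerical point worth recording: an eGFR recomputed from *printed*
(rounded) creatinine will not generally match a value that was originally
computed from the unrounded laboratory result. If creatinine is printed to
the nearest 1 µmol/L, the induced eGFR uncertainty is approximately
$1.154 \times (0.5/\mathrm{Scr}) \times \mathrm{eGFR}$ by the delta
method. The package's tests therefore assert agreement with recorded
clinical values to within this quantisation bound plus the reporting
half-unit of 0.05 mL/min, not exact equality — exact-equality tests
against rounded inputs would be asserting a falsehood about arithmetic.
`egfr_mdrd()` itself returns the unrounded value; rounding is left to the
caller.

**Urinary oxalate.** `ocr_flag()` flags a urinary oxalate-to-creatinine
molar ratio as abnormal iff it is **strictly greater than 0.04**
mmol/mmol. `pyridoxine_response()` computes the percent reduction of OCR
on vitamin B6 and calls the patient responsive iff the reduction is
**strictly greater than 30 %**. Both thresholds are strict inequalities:
a value exactly at a published cut-off is, by convention, not beyond it.

**Diagnosis.** `diagnose_ph1()` encodes the adult rule set: the patient
must have a compatible stone phenotype (nephrolithiasis or
nephrocalcinosis) *and* at least one confirmatory finding (abnormal OCR,
demonstrated AGT deficiency, or biallelic pathogenic *AGXT* genotype).
If every confirmatory field is unknown the verdict is
`insufficient_data`, never a default negative.

## 6. Synthetic-data generators: scope and limits

The generators exist so that every algorithm can be tested against a
*planted truth* without external downloads. They emulate structure, not
biology:

- `simulate_msa()` produces an alignment whose per-column conservation
  counts are **exact** — after random generation, non-matching residues
  are resampled until the planted count holds — with optional forced
  reference residues at chosen positions. Sequences are otherwise i.i.d.
  draws with a configurable background identity (default 0.5) to the
  reference; there is no phylogeny, no indel model (the default alignment
  is gap-free), and no position-specific substitution preferences. The
  species row names are the eight panel species, but the sequences are
  synthetic.
- `simulate_pedigree()` grows a family from one founder couple carrying
  two disjoint planted mutant haplotypes, with marry-in spouses assumed
  wild type, Mendelian transmission, **no recombination**, and **complete
  penetrance** (biallelic ⇔ affected). There is no de novo mutation, no
  genotyping error, and no missingness unless the caller masks genotypes.
  These are exactly the assumptions of the phasing model, which is the
  point: the generator provides ground truth *for that model*, it does not
  stress-test model misspecification.
- `simulate_cohort()` produces a diploid control genotype table with
  **exact** heterozygote/homozygote counts per variant (placement
  randomised), not binomial draws — allele-frequency arithmetic can then
  be checked against integers.

All generators route randomness through an internal `with_seed()` that
saves and restores the global RNG state, so simulation inside a larger
script never perturbs the caller's random stream; determinism per seed is
pinned by tests.

## 7. Problem sizes and validation performed

The shipped test-suite validates, among other things: the full Grantham
matrix against an independent recomputation from the formula; 1,000
random alignments against a character-by-character conservation oracle;
200 simulated three-generation pedigrees for exact recovery of the
planted cis/trans configuration (zero errors, all resolved); 500
simulated pedigrees with zero Mendelian violations; and the monotone
decrease of phasing ambiguity as sibship size grows (1, 3, 10, 20 typed
children with unsequenced founders). Phasing 200 pedigrees of ~20 members
with 2 variants takes a few seconds; the worst case permitted by the size
guard (6 variants, 10 founders) enumerates 32 partitions and remains well
under a second per family.

## 8. Known limitations

- The phasing model is exact but assumes no recombination and at most two
  mutant founder haplotypes; it is not a general haplotype reconstruction
  tool and refuses inputs outside its design envelope rather than
  approximating.
- The conservation rubric is calibrated for an 8-species panel; the
  proportional mode is an explicit extrapolation and warns as such.
- Complete penetrance is assumed by the segregation test; reduced
  penetrance must be handled by the caller via `strict = FALSE`.
- The rubric is a literature-derived ordinal score, not a probabilistic
  classifier; it has no confidence intervals and should be read as
  structured expert reasoning, not as a posterior.
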