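# ph1kit

Variant pathogenicity scoring and pedigree analysis for primary
hyperoxaluria type 1 (PH1).

PH1 is an autosomal recessive disorder of the liver enzyme
alanine:glyoxylate aminotransferase (AGT, gene *AGXT*). Loss of AGT
activity shunts glyoxylate to oxalate, producing recurrent calcium-oxalate
kidney stones, nephrocalcinosis and, untreated, renal failure. The genetic
workup of a PH1 family asks a small set of sharply posed questions, and
this package implements each of them:

1. **Is a newly found missense change pathogenic?** Scored with a combined
   rubric: the Grantham (1974) physico-chemical distance between the two
   amino acids is binned to 1–4 points (any cysteine substitution scores
   5), and evolutionary conservation of the residue across an 8-species
   vertebrate AGT panel adds 1–5 points. Totals of ≥ 8 are classified
   `high`, 6–7 `moderate`, ≤ 5 `probably_nonpathogenic`.
2. **Are two variants in cis or in trans?** Compound heterozygosity — one
   pathogenic allele from each parent — is what makes a recessive
   diagnosis. `phase_variants()` solves the cis/trans configuration
   exactly by enumerating haplotype assignments under a no-recombination
   model and checking Mendelian transmission through the whole pedigree.
   When the intron-1 duplication marker (`IVS1+74bp`) is among the phased
   variants, the haplotype carrying it is labelled **AGT-Mi** (minor
   *AGXT* haplotype) and the opposite mutant haplotype **AGT-Ma**.
3. **Does the genotype co-segregate with disease?**
   `cosegregation_test()` classifies every family member as biallelic /
   carrier / noncarrier / untyped and checks the autosomal recessive
   expectations.
4. **Is the variant a polymorphism?** `allele_frequency()` estimates
   minor-allele frequencies in a control cohort.
5. **Do the clinical numbers support the diagnosis?** MDRD eGFR
   (`egfr_mdrd()`), the urinary oxalate-to-creatinine ratio threshold
   (abnormal iff > 0.04 mmol/mmol), the pyridoxine-response criterion
   (responsive iff OCR falls by > 30 %), and the adult PH1 diagnostic rule
   set (`diagnose_ph1()`).
6. **Synthetic data with planted truth.** `simulate_msa()`,
   `simulate_pedigree()` and `simulate_cohort()` generate alignments with
   exact planted conservation, families with known cis/trans haplotypes,
   and control cohorts with exact carrier counts, so every algorithm is
   testable offline against ground truth.

See the methods vignette (`vignettes/ph1-methods.Rmd`) for the model
assumptions, parameter defaults and the numerical edge-case decisions
(score-8 boundary, Grantham bin gap, eGFR equation variant and rounding).

## Worked example

Score the two novel *AGXT* missense variants against an 8-species homolog
panel in which both residues are fully conserved:

```r
library(ph1kit)

aln <- simulate_msa(msa_spec(
  n_species = 8L, length = 392L,
  planted_conservation = c(`49` = 8L, `72` = 8L),
  reference_residues   = c(`49` = "M", `72` = "N"),
  seed = 20160920))

cards <- score_variants(
  list("p.M49L (c.145A > C)", "p.N72I (c.215A > T)"),
  aln, reference_id = "homo_sapiens")
print(cards, row.names = FALSE)
#>            variant grantham grantham_pts conserved msa_pts total    class
#>  p.M49L (c.145A>C)       15            1       8/8       5     6 moderate
#>  p.N72I (c.215A>T)      149            4       8/8       5     9     high
```

Phase the four variants through the 20-member family (the bundled fixture
`make_family_fixture()` encodes the index pedigree) and test AR
co-segregation:

```r
fam <- make_family_fixture()
check_mendelian(fam)        # zero rows: no Mendelian violations

ph <- phase_variants(fam)
print(ph)
#> <ph1_phase> status: resolved
#>   AGT-Mi: {p.M49L, p.R333*, IVS1+74bp}
#>   AGT-Ma: {p.N72I}

print(cosegregation_test(fam, ph))
#> <ph1_segregation> autosomal recessive, biallelic
#>   biallelic 3 | carriers 7 | noncarriers 9 | untyped 1
#>   consistent with AR inheritance
```

So p.M49L, the nonsense change p.R333\* and the intronic marker ride
together in cis on the minor haplotype, p.N72I sits in trans on the major
haplotype, and the three affected siblings are compound heterozygotes —
the classic recessive picture.

Clinical side, for the three patients:

```r
round(egfr_mdrd(c(1044, 210, 94), c(52, 38, 37),
                c("female", "male", "female")), 1)
#> [1]  3.6 32.7 61.8

pyridoxine_response(0.35, 0.20)
#> $percent_reduction  42.85714
#> $responsive         TRUE
```

## License

MIT.
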