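#!/usr/bin/env Rscript
# Phase and co-segregation analysis of the PH1 family.
#
# The 20-member pedigree (encoded from the published genotype statements)
# is checked for Mendelian consistency, the four markers are phased under
# the no-recombination model, and autosomal-recessive co-segregation is
# tested. Expected outcome: the phase resolves with p.M49L, p.R333* and
# IVS1+74bp in cis on the minor allele (AGT-Mi) and p.N72I in trans on the
# major allele (AGT-Ma); 3 affected compound heterozygotes, 7 healthy
# carriers, 9 noncarriers, 1 untyped (the deceased founder).

library(ph1kit)

dir.create("results", showWarnings = FALSE)

fam <- make_family_fixture()
write_pedigree(fam, "results/family.ped")

mend <- check_mendelian(fam)
cat(sprintf("Mendelian check: %d violation(s)\n", nrow(mend)))

ph <- phase_variants(fam)
print(ph)
seg <- cosegregation_test(fam, ph)
print(seg)

jsonlite::write_json(
  list(phase = list(status = ph$status, haplotypes = ph$haplotypes),
       segregation = list(model = seg$model,
                          n_affected_biallelic = seg$n_affected_biallelic,
                          n_carriers = seg$n_carriers,
                          n_noncarriers = seg$n_noncarriers,
                          n_untyped = seg$n_untyped,
                          consistent = seg$consistent)),
  "results/family_phasing.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
write.csv(seg$classification, "results/family_classification.csv", row.names = FALSE)
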