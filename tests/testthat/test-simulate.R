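test_that("the family fixture encodes the published membership facts", {
  fam <- make_family_fixture()
  expect_equal(nrow(fam$members), 20L)
  expect_true(setequal(fam$members$id[fam$members$affected == "affected"],
                       c("IIa", "IIe", "IIf")))
  # the deceased founder is missing at every variant
  expect_true(all(is.na(fam$genotypes["Ib", ])))
  # seven heterozygous healthy carriers
  carrier_ids <- fam$members$id[
    rowSums(fam$genotypes > 0, na.rm = TRUE) > 0 &
    fam$members$affected == "unaffected"]
  expect_equal(length(carrier_ids), 7L)
  expect_true(setequal(carrier_ids,
                       c("Ia", "IIc", "IIIc", "IIIf", "IIb", "IIIa", "IIIe")))
  # minor-allele carriers are het at all three AGT-Mi markers only
  for (id in c("Ia", "IIc", "IIIc", "IIIf")) {
    expect_equal(unname(fam$genotypes[id, c("p.M49L", "p.R333*", "IVS1+74bp")]),
                 c(1L, 1L, 1L))
    expect_equal(unname(fam$genotypes[id, "p.N72I"]), 0L)
  }
  # nine members are reference at every variant
  ref_ids <- fam$members$id[
    rowSums(fam$genotypes == 0, na.rm = TRUE) == ncol(fam$genotypes)]
  expect_equal(length(ref_ids), 9L)
})

test_that("simulators are deterministic under a fixed seed and differ across seeds", {
  s1 <- simulate_pedigree(pedigree_spec(seed = 5))
  s2 <- simulate_pedigree(pedigree_spec(seed = 5))
  expect_identical(s1$pedigree$genotypes, s2$pedigree$genotypes)
  expect_identical(s1$truth, s2$truth)
  a1 <- simulate_msa(msa_spec(seed = 5)); a2 <- simulate_msa(msa_spec(seed = 5))
  expect_identical(a1, a2)
  c1 <- simulate_cohort(cohort_spec(het_carriers = c(v = 5), seed = 5))
  expect_identical(c1, simulate_cohort(cohort_spec(het_carriers = c(v = 5), seed = 5)))
  expect_false(identical(a1, simulate_msa(msa_spec(seed = 6))))
  # no global RNG state leaks
  set.seed(123); before <- .Random.seed
  invisible(simulate_msa(msa_spec(seed = 99)))
  expect_identical(.Random.seed, before)
})

test_that("simulated pedigrees obey the phenotype rule by construction", {
  for (s in 1:20) {
    sim <- simulate_pedigree(pedigree_spec(seed = s))
    carried <- sim$truth$carried
    for (id in names(carried)) {
      biallelic <- all(carried[[id]] != "WT")
      aff <- sim$pedigree$members$affected[sim$pedigree$members$id == id]
      expect_equal(aff, if (biallelic) "affected" else "unaffected")
    }
  }
})

test_that("planted MSA conservation is exact, not expected (100 random specs)", {
  set.seed(17)
  for (rep in 1:100) {
    ns <- sample(2:10, 1); L <- sample(10:50, 1)
    npl <- sample(1:3, 1)
    pos <- sample(L, npl)
    k <- sample(ns, npl, replace = TRUE)
    spec <- msa_spec(n_species = ns, length = L,
                     planted_conservation = stats::setNames(k, pos),
                     background_identity = runif(1), seed = rep)
    aln <- simulate_msa(spec)
    for (i in seq_len(npl)) {
      expect_equal(conservation_count(aln, names(aln)[1], pos[i])$n_conserved,
                   k[i])
    }
  }
})

test_that("forced reference residues and planted bins integrate with scoring", {
  aln <- simulate_msa(msa_spec(length = 80, planted_conservation = c(`20` = 3),
                               reference_residues = c(`20` = "N"), seed = 2))
  expect_equal(conservation_count(aln, "homo_sapiens", 20)$ref_residue, "N")
  expect_equal(msa_points(3), 1L)
  sc <- score_variant("p.N20I", aln, "homo_sapiens")
  expect_equal(sc$msa_points, 1L)
  expect_equal(sc$total, 5L)   # 4 (Grantham 149) + 1
})

test_that("cohort simulation honours exact carrier counts and capacity limits", {
  coh <- simulate_cohort(cohort_spec(100,
                                     het_carriers = c(a = 6, b = 4, c = 16),
                                     hom_alt = c(b = 2), seed = 8))
  expect_equal(colSums(coh == 1), c(a = 6, b = 4, c = 16))
  expect_equal(colSums(coh == 2), c(a = 0, b = 2, c = 0))
  expect_equal(allele_frequency(coh, "a"), 0.03)
  expect_equal(allele_frequency(coh, "b"), 0.04)
  expect_equal(allele_frequency(coh, "c"), 0.08)
  expect_error(cohort_spec(10, het_carriers = c(v = 9), hom_alt = c(v = 2)),
               class = "ph1_spec_error")
  # zero-carrier cohort
  z <- simulate_cohort(cohort_spec(50, het_carriers = c(v = 0), seed = 1))
  expect_equal(allele_frequency(z, "v"), 0)
})

test_that("invalid generator specifications are rejected", {
  expect_error(msa_spec(planted_conservation = c(`5` = 0)), class = "ph1_spec_error")
  expect_error(msa_spec(planted_conservation = c(`5` = 9)), class = "ph1_spec_error")
  expect_error(msa_spec(length = 10, planted_conservation = c(`11` = 2)),
               class = "ph1_spec_error")
  expect_error(simulate_pedigree(pedigree_spec(founder_haplotypes = list(
    list(c("v1", "v2"), character(0)), list("v2", character(0))))),
    class = "ph1_spec_error")
})
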