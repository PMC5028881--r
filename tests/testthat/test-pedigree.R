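trio <- function(g_father, g_mother, g_child, affected = "unknown") {
  members <- data.frame(
    id = c("F", "M", "C"), family_id = "T",
    father_id = c(NA, NA, "F"), mother_id = c(NA, NA, "M"),
    sex = c("male", "female", "unknown"),
    affected = c("unknown", "unknown", affected),
    stringsAsFactors = FALSE)
  G <- matrix(c(g_father, g_mother, g_child), ncol = 1,
              dimnames = list(c("F", "M", "C"), "v1"))
  pedigree(members, G)
}

test_that("Mendelian checking flags impossible trios and tolerates missing data", {
  expect_equal(nrow(check_mendelian(trio(0L, 0L, 1L))), 1L)  # de novo
  expect_equal(nrow(check_mendelian(trio(0L, 0L, 2L))), 1L)
  expect_equal(nrow(check_mendelian(trio(2L, 2L, 1L))), 1L)
  expect_equal(nrow(check_mendelian(trio(1L, 1L, 2L))), 0L)
  expect_equal(nrow(check_mendelian(trio(NA_integer_, 0L, 1L))), 0L)  # missing parent side
  expect_equal(nrow(check_mendelian(trio(0L, 0L, NA_integer_))), 0L)  # missing child
})

test_that("simulated transmissions never violate Mendelian rules (500 pedigrees)", {
  total <- 0L
  for (s in 1:500) {
    sim <- simulate_pedigree(pedigree_spec(seed = s))
    total <- total + nrow(check_mendelian(sim$pedigree))
  }
  expect_equal(total, 0L)
})

test_that("the study family phases to the published cis/trans configuration", {
  fam <- make_family_fixture()
  expect_equal(nrow(check_mendelian(fam)), 0L)
  ph <- phase_variants(fam)
  expect_equal(ph$status, "resolved")
  expect_true(setequal(ph$haplotypes[["AGT-Mi"]],
                       c("p.M49L", "p.R333*", "IVS1+74bp")))
  expect_true(setequal(ph$haplotypes[["AGT-Ma"]], "p.N72I"))
  # every mutation carrier constrains the phase
  expect_true(all(c("IIa", "IIe", "IIf", "Ia", "IIc") %in%
                  ph$supporting_individuals))
})

test_that("an isolated double heterozygote is ambiguous with exactly two partitions", {
  members <- data.frame(id = "X", family_id = "S", father_id = NA_character_,
                        mother_id = NA_character_, sex = "unknown",
                        affected = "unknown", stringsAsFactors = FALSE)
  G <- matrix(c(1L, 1L), 1, 2, dimnames = list("X", c("vA", "vB")))
  ph <- phase_variants(pedigree(members, G))
  expect_equal(ph$status, "ambiguous")
  expect_equal(length(ph$partitions), 2L)
})

test_that("resolved phases always recover the planted truth (200 pedigrees)", {
  wrong <- 0L; resolved <- 0L
  for (s in 1:200) {
    sim <- simulate_pedigree(pedigree_spec(seed = s))
    ph <- phase_variants(sim$pedigree)
    if (ph$status != "resolved") next
    resolved <- resolved + 1L
    observed <- unlist(ph$haplotypes)
    if (!phase_matches_truth(ph, sim$truth$haplotypes, observed)) wrong <- wrong + 1L
  }
  expect_gt(resolved, 150L)
  expect_equal(wrong, 0L)
})

test_that("phase ambiguity shrinks as the typed family around an index case grows", {
  # Two tightly linked variants on opposite founder haplotypes; the founder
  # couple is unsequenced (as the study's deceased Ib), so phase information
  # comes from the children alone. With one child a double heterozygote is
  # uninformative; more siblings resolve the phase more often.
  ambiguity_rate <- function(n_children, seeds) {
    amb <- 0L
    for (s in seeds) {
      sim <- simulate_pedigree(pedigree_spec(
        n_generations = 2L,
        founder_haplotypes = list(list("vA", character(0)),
                                  list("vB", character(0))),
        offspring_per_couple = n_children, seed = s))
      ped <- sim$pedigree
      G <- ped$genotypes
      G[c("G1-F", "G1-M"), ] <- NA_integer_
      masked <- pedigree(ped$members, G)
      ph <- phase_variants(masked)
      if (ph$status == "ambiguous") amb <- amb + 1L
    }
    amb / length(seeds)
  }
  rates <- vapply(c(1, 3, 10, 20), ambiguity_rate, numeric(1), seeds = 1:60)
  expect_true(all(diff(rates) <= 0))
  expect_gt(rates[1], rates[4])
})

test_that("oversized phase enumerations are refused", {
  members <- data.frame(id = "X", family_id = "S", father_id = NA_character_,
                        mother_id = NA_character_, sex = "unknown",
                        affected = "unknown", stringsAsFactors = FALSE)
  G <- matrix(1L, 1, 7, dimnames = list("X", paste0("v", 1:7)))
  expect_error(phase_variants(pedigree(members, G)), class = "ph1_size_error")
})

test_that("the study family co-segregates under AR inheritance with the published counts", {
  fam <- make_family_fixture()
  ph <- phase_variants(fam)
  seg <- cosegregation_test(fam, ph)
  expect_equal(seg$n_affected_biallelic, 3L)
  expect_equal(seg$n_carriers, 7L)
  expect_equal(seg$n_noncarriers, 9L)
  expect_equal(seg$n_untyped, 1L)
  expect_equal(nrow(seg$violations), 0L)
  expect_true(seg$consistent)
  # counts partition the family
  expect_equal(seg$n_affected_biallelic + seg$n_carriers + seg$n_noncarriers +
                 seg$n_untyped, nrow(fam$members))
  # the three biallelic members are exactly the patients
  bial <- seg$classification$id[seg$classification$class == "biallelic"]
  expect_true(setequal(bial, c("IIa", "IIe", "IIf")))
})

test_that("an injected unaffected biallelic individual yields exactly one violation", {
  fam <- make_family_fixture()
  # a new unaffected child of the founder couple, compound heterozygous:
  # transmissible, so the phase stays resolved, but the AR rule must flag it
  members <- rbind(fam$members,
                   data.frame(id = "IId", family_id = "PH1", father_id = "Ib",
                              mother_id = "Ia", sex = "male",
                              affected = "unaffected", stringsAsFactors = FALSE))
  G <- rbind(fam$genotypes, IId = rep(1L, ncol(fam$genotypes)))
  fam2 <- pedigree(members, G)
  ph <- phase_variants(fam2)
  expect_equal(ph$status, "resolved")
  seg <- cosegregation_test(fam2, ph)
  expect_equal(nrow(seg$violations), 1L)
  expect_equal(seg$violations$id, "IId")
  expect_false(seg$consistent)
  # the penetrance override downgrades it to a warning
  lenient <- cosegregation_test(fam2, ph, strict = FALSE)
  expect_equal(nrow(lenient$violations), 0L)
  expect_equal(nrow(lenient$warnings), 1L)
  expect_true(lenient$consistent)
})

test_that("fully penetrant simulated pedigrees never violate the AR rule", {
  for (s in 1:50) {
    sim <- simulate_pedigree(pedigree_spec(seed = s))
    ph <- phase_variants(sim$pedigree)
    if (ph$status != "resolved") next
    seg <- cosegregation_test(sim$pedigree, ph)
    expect_equal(nrow(seg$violations), 0L)
  }
})

test_that("segregation counts are invariant to member order and haplotype relabeling", {
  fam <- make_family_fixture()
  ph <- phase_variants(fam)
  seg <- cosegregation_test(fam, ph)
  # shuffle members (keeping a valid pedigree) and recompute
  set.seed(9)
  idx <- sample(nrow(fam$members))
  fam_shuf <- pedigree(fam$members[idx, ], fam$genotypes[fam$members$id[idx], ])
  seg2 <- cosegregation_test(fam_shuf, phase_variants(fam_shuf))
  # swap the haplotype classes by hand
  ph_swap <- ph
  ph_swap$haplotypes <- rev(ph$haplotypes)
  seg3 <- cosegregation_test(fam, ph_swap)
  for (f in c("n_affected_biallelic", "n_carriers", "n_noncarriers", "n_untyped")) {
    expect_equal(seg2[[f]], seg[[f]], label = f)
    expect_equal(seg3[[f]], seg[[f]], label = f)
  }
})

test_that("allele frequencies match the brute-force tally and its edge cases", {
  coh <- simulate_cohort(cohort_spec(100, het_carriers = c(v = 6), seed = 1))
  expect_equal(allele_frequency(coh, "v"), 0.03)
  # all reference
  coh0 <- simulate_cohort(cohort_spec(50, het_carriers = c(v = 0), seed = 1))
  expect_equal(allele_frequency(coh0, "v"), 0)
  # all heterozygous
  cohH <- data.frame(v = rep(1L, 10))
  expect_equal(allele_frequency(cohH, "v"), 0.5)
  # missing genotypes leave the denominator
  cohM <- data.frame(v = c(1L, NA, NA, 0L))
  expect_equal(allele_frequency(cohM, "v"), 0.25)
  expect_error(allele_frequency(data.frame(v = c(NA_integer_, NA_integer_)), "v"),
               class = "ph1_cohort_error")
  # random cohorts vs the per-allele tally oracle
  set.seed(31)
  for (rep in 1:50) {
    g <- sample(c(0L, 1L, 2L, NA), 40, replace = TRUE)
    if (all(is.na(g))) g[1] <- 0L
    coh <- data.frame(v = g)
    f <- allele_frequency(coh, "v")
    expect_equal(f, oracle_allele_freq(g))
    expect_gte(f, 0); expect_lte(f, 1)
  }
})
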