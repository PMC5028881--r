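test_that("MDRD eGFR reproduces the study patients within printed-input precision", {
  # Printed inputs (Scr umol/L, age, sex) and printed eGFRs. Creatinine is
  # printed as an integer and eGFR to 1 decimal, so the reproducible bound
  # is the half-ULP of each propagated through the equation.
  scr <- c(1044, 210, 94); age <- c(52, 38, 37)
  sex <- c("female", "male", "female"); printed <- c(3.6, 32.8, 62.0)
  got <- egfr_mdrd(scr, age, sex)
  tol <- 0.05 + 1.154 * (0.5 / scr) * got   # output half-ULP + input half-ULP
  expect_true(all(abs(got - printed) <= tol))
  expect_equal(round(got[1], 1), 3.6)
})

test_that("eGFR is monotone in creatinine and age, with the exact female factor", {
  scr <- seq(60, 1200, by = 20)
  expect_true(all(diff(egfr_mdrd(scr, 40, "male")) < 0))
  age <- seq(20, 90, by = 5)
  expect_true(all(diff(egfr_mdrd(100, age, "male")) < 0))
  expect_equal(egfr_mdrd(100, 40, "female"), 0.742 * egfr_mdrd(100, 40, "male"))
  # the IDMS variant rescales by 175/186 exactly
  expect_equal(egfr_mdrd(100, 40, "male", variant = "idms175"),
               egfr_mdrd(100, 40, "male") * 175 / 186)
  expect_error(egfr_mdrd(-1, 40, "male"), class = "ph1_clinical_error")
  expect_error(egfr_mdrd(100, 0, "male"), class = "ph1_clinical_error")
  expect_error(egfr_mdrd(100, 40, "other"), class = "ph1_clinical_error")
})

test_that("OCR abnormality is strict at the 0.04 threshold", {
  expect_equal(ocr_flag(0.35), "abnormal")
  expect_equal(ocr_flag(0.04), "normal")
  expect_equal(ocr_flag(0.0401), "abnormal")
  expect_equal(ocr_flag(0), "normal")
  expect_error(ocr_flag(-0.1), class = "ph1_clinical_error")
})

test_that("pyridoxine responsiveness requires a strict >30% OCR fall", {
  r <- pyridoxine_response(0.35, 0.20)
  expect_equal(r$percent_reduction, 100 * (0.35 - 0.20) / 0.35)
  expect_gt(r$percent_reduction, 30)
  expect_true(r$responsive)
  expect_false(pyridoxine_response(0.35, 0.35)$responsive)
  # exactly 30% is not responsive
  expect_false(pyridoxine_response(0.35, 0.245)$responsive)
  expect_error(pyridoxine_response(0, 0.1), class = "ph1_clinical_error")
  # scale invariance of the percent reduction
  for (k in c(0.1, 3, 1000)) {
    expect_equal(pyridoxine_response(0.35 * k, 0.20 * k)$percent_reduction,
                 r$percent_reduction)
  }
})

test_that("the adult diagnostic rule set distinguishes its three verdicts", {
  # study patient IIf: recurrent stones, OCR 0.35, biallelic mutations
  iif <- clinical_record(94, 37, "female", ocr_mmol_per_mmol = 0.35,
                         has_nephrolithiasis = TRUE,
                         biallelic_pathogenic = TRUE)
  expect_equal(diagnose_ph1(iif), "meets_criteria")
  # stone prong fails outright
  none <- clinical_record(94, 37, "female", ocr_mmol_per_mmol = 0.35)
  expect_equal(diagnose_ph1(none), "does_not_meet")
  # stones but no confirmatory data
  unk <- clinical_record(94, 37, "female", has_nephrolithiasis = TRUE)
  expect_equal(diagnose_ph1(unk), "insufficient_data")
  # stones, confirmatory fields known negative
  neg <- clinical_record(94, 37, "female", ocr_mmol_per_mmol = 0.02,
                         has_nephrolithiasis = TRUE,
                         biallelic_pathogenic = FALSE,
                         agt_activity_deficient = FALSE)
  expect_equal(diagnose_ph1(neg), "does_not_meet")
  # nephrocalcinosis alone satisfies the first prong
  calc <- clinical_record(1044, 52, "female", has_nephrocalcinosis = TRUE,
                          biallelic_pathogenic = TRUE)
  expect_equal(diagnose_ph1(calc), "meets_criteria")
  # normal OCR is not confirmatory but unknown enzyme/genetics keep it open
  open <- clinical_record(94, 37, "female", ocr_mmol_per_mmol = 0.02,
                          has_nephrolithiasis = TRUE)
  expect_equal(diagnose_ph1(open), "does_not_meet")
})

test_that("clinical records validate inputs and read from CSV", {
  expect_error(clinical_record(-5, 40, "male"), class = "ph1_clinical_error")
  expect_error(clinical_record(100, 40, "x"), class = "ph1_clinical_error")
  expect_error(clinical_record(100, 40, "male", ocr_mmol_per_mmol = -1),
               class = "ph1_clinical_error")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines(c("id,sex,age_years,scr_umol_per_l,ocr_mmol_per_mmol,has_nephrolithiasis,has_nephrocalcinosis,biallelic_pathogenic",
               "IIa,female,52,1044,NA,TRUE,TRUE,TRUE",
               "IIe,male,38,210,NA,TRUE,FALSE,TRUE",
               "IIf,female,37,94,0.35,TRUE,FALSE,TRUE"), path)
  recs <- read_clinical_csv(path)
  expect_equal(names(recs), c("IIa", "IIe", "IIf"))
  expect_equal(recs$IIf$ocr_mmol_per_mmol, 0.35)
  expect_true(recs$IIa$has_nephrocalcinosis)
  expect_equal(diagnose_ph1(recs$IIe), "meets_criteria")
})
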