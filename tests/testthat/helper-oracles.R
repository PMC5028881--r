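# Independent brute-force oracles used by the property tests. These stay
# deliberately naive (character loops, full tallies) so they cannot share a
# bug with the implementation they check.

# column (0-based) of the pos-th non-gap character of a row, by linear scan
oracle_column <- function(row, pos) {
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  seen <- 0L
  for (j in seq_along(chars)) {
    if (chars[j] != "-") {
      seen <- seen + 1L
      if (seen == pos) return(j - 1L)
    }
  }
  NA_integer_
}

# conservation at a reference position by scanning every row character
oracle_conservation <- function(alignment, reference_id, pos) {
  col0 <- oracle_column(alignment[[reference_id]], pos)
  ref_res <- toupper(substr(alignment[[reference_id]], col0 + 1, col0 + 1))
  n <- 0L
  for (row in alignment) {
    ch <- toupper(substr(row, col0 + 1, col0 + 1))
    if (ch != "-" && ch == ref_res) n <- n + 1L
  }
  n
}

# allele frequency by explicit per-allele tally
oracle_allele_freq <- function(doses) {
  alt <- 0L; tot <- 0L
  for (g in doses) {
    if (is.na(g)) next
    alt <- alt + g
    tot <- tot + 2L
  }
  alt / tot
}

# Grantham's original composition/polarity/volume distance formula,
# used as an independent cross-check of the embedded integer matrix.
oracle_grantham_formula <- function() {
  aa <- c("S","R","L","P","T","A","V","G","I","F",
          "Y","C","H","Q","N","K","D","E","M","W")
  comp <- c(1.42,0.65,0,0.39,0.71,0,0,0.74,0,0,0.20,2.75,0.58,0.89,1.33,0.33,1.38,0.92,0,0.13)
  pol  <- c(9.2,10.5,4.9,8.0,8.6,8.1,5.9,9.0,5.2,5.2,6.2,5.5,10.4,10.5,11.6,11.3,13.0,12.3,5.7,5.4)
  vol  <- c(32,124,111,32.5,61,31,84,3,111,132,136,55,96,85,56,119,54,83,105,170)
  m <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (i in 1:20) for (j in 1:20) if (i != j) {
    m[i, j] <- 50.723 * sqrt(1.833 * (comp[i] - comp[j])^2 +
                             0.1018 * (pol[i] - pol[j])^2 +
                             0.000399 * (vol[i] - vol[j])^2)
  }
  m
}

# does a resolved phase partition match the generator's planted truth,
# restricted to the variants actually observed in the pedigree?
phase_matches_truth <- function(phase, truth, observed) {
  t1 <- intersect(truth$H1, observed)
  t2 <- intersect(truth$H2, observed)
  p1 <- phase$haplotypes[[1]]
  p2 <- phase$haplotypes[[2]]
  (setequal(p1, t1) && setequal(p2, t2)) ||
    (setequal(p1, t2) && setequal(p2, t1))
}
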