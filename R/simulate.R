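# Default variant labels of the AGXT study haplotypes: the mutated minor
# allele (AGT-Mi) carries the two left-hand mutations plus the intron-1
# 74-bp duplication tag; the mutated major allele (AGT-Ma) carries the
# third mutation alone.
agt_mi_variants <- function() c("p.M49L", "p.R333*", "IVS1+74bp")
agt_ma_variants <- function() "p.N72I"

#' The study family, encoded from the published genotype statements
#'
#' A 20-member, 3-generation pedigree: founder couple Ia x Ib; three
#' affected sibs (IIa, IIe, IIf) compound heterozygous for the mutant
#' minor allele (AGT-Mi: p.M49L + p.R333* + IVS1+74bp) and the mutant
#' major allele (AGT-Ma: p.N72I); four AGT-Mi carriers (Ia, IIc, IIIc,
#' IIIf); three AGT-Ma carriers (IIb, IIIa, IIIe); Ib unsequenced
#' (deceased, genotypes missing); the remaining nine members reference at
#' all variants. Only the genotype/affection facts are published; the
#' marriage structure connecting the generations is a reconstruction
#' (spouses IIg/IIh and the unnamed generation-III ids are synthetic
#' placeholders, all reference).
#'
#' @return a `ph1_pedigree` with 20 individuals and 4 variant columns.
#' @export
make_family_fixture <- function() {
  vars <- c(agt_mi_variants(), agt_ma_variants())
  mem <- function(id, fa, mo, sex, aff) {
    data.frame(id = id, family_id = "PH1", father_id = fa, mother_id = mo,
               sex = sex, affected = aff, stringsAsFactors = FALSE)
  }
  members <- rbind(
    mem("Ia",   NA, NA, "female", "unaffected"),
    mem("Ib",   NA, NA, "male",   "unknown"),     # deceased, unsequenced
    mem("IIa",  "Ib", "Ia", "female", "affected"),
    mem("IIb",  "Ib", "Ia", "male",   "unaffected"),
    mem("IIc",  "Ib", "Ia", "female", "unaffected"),
    mem("IIe",  "Ib", "Ia", "male",   "affected"),
    mem("IIf",  "Ib", "Ia", "female", "affected"),
    mem("IIg",  NA, NA, "female", "unaffected"),  # spouse of IIb
    mem("IIh",  NA, NA, "male",   "unaffected"),  # spouse of IIc
    mem("IIIa", "IIb", "IIg", "male",   "unaffected"),
    mem("IIIb", "IIb", "IIg", "female", "unaffected"),
    mem("IIIe", "IIb", "IIg", "male",   "unaffected"),
    mem("IIIg", "IIb", "IIg", "female", "unaffected"),
    mem("IIIh", "IIb", "IIg", "male",   "unaffected"),
    mem("IIIc", "IIh", "IIc", "female", "unaffected"),
    mem("IIId", "IIh", "IIc", "male",   "unaffected"),
    mem("IIIf", "IIh", "IIc", "female", "unaffected"),
    mem("IIIi", "IIh", "IIc", "male",   "unaffected"),
    mem("IIIj", "IIh", "IIc", "female", "unaffected"),
    mem("IIIk", "IIh", "IIc", "male",   "unaffected"))

  G <- matrix(0L, nrow(members), length(vars),
              dimnames = list(members$id, vars))
  het_at <- function(ids, labels) {
    for (id in ids) G[id, labels] <<- 1L
  }
  het_at(c("IIa", "IIe", "IIf"), vars)                       # compound hets
  het_at(c("Ia", "IIc", "IIIc", "IIIf"), agt_mi_variants())  # AGT-Mi carriers
  het_at(c("IIb", "IIIa", "IIIe"), agt_ma_variants())        # AGT-Ma carriers
  G["Ib", ] <- NA_integer_
  pedigree(members, G)
}

#' Specification for a simulated pedigree
#'
#' Emulates the study family design: a founder couple whose two mutant
#' haplotypes segregate through `n_generations` under autosomal recessive
#' inheritance with complete penetrance. Children inherit one whole
#' haplotype from each parent uniformly at random -- no recombination, the
#' variants being tightly linked within one ~10 kb gene. Non-last-
#' generation children marry in wild-type spouses (new founders).
#'
#' @param n_generations number of generations (>= 1; default 3, as in the
#'   study family).
#' @param founder_haplotypes list of two elements (one per top founder),
#'   each a list of two character vectors of variant labels (the founder's
#'   two haplotypes). Default: one founder carries the AGT-Mi haplotype
#'   (p.M49L, p.R333*, IVS1+74bp) over wild type, the other the AGT-Ma
#'   haplotype (p.N72I) over wild type.
#' @param offspring_per_couple children per couple (default 3).
#' @param seed RNG seed; identical spec + seed gives an identical pedigree.
#' @return a `ph1_pedigree_spec`.
#' @export
pedigree_spec <- function(n_generations = 3L,
                          founder_haplotypes = list(
                            list(agt_mi_variants(), character(0)),
                            list(agt_ma_variants(), character(0))),
                          offspring_per_couple = 3L,
                          seed = 1L) {
  stopifnot(n_generations >= 1L, offspring_per_couple >= 0L,
            is.list(founder_haplotypes), length(founder_haplotypes) == 2L,
            all(vapply(founder_haplotypes, length, integer(1)) == 2L))
  structure(list(n_generations = as.integer(n_generations),
                 founder_haplotypes = founder_haplotypes,
                 offspring_per_couple = as.integer(offspring_per_couple),
                 phenotype_rule = "biallelic => affected",
                 seed = as.integer(seed)),
            class = "ph1_pedigree_spec")
}

#' Simulate a pedigree with planted haplotype ground truth
#'
#' @param spec a [pedigree_spec()].
#' @return list with `pedigree` (a `ph1_pedigree`) and `truth`: the two
#'   founder mutant haplotype variant sets (`haplotypes`) and each
#'   individual's pair of haplotype assignments (`carried`, values
#'   `"WT"`, `"H1"`, `"H2"`).
#' @export
simulate_pedigree <- function(spec) {
  stopifnot(inherits(spec, "ph1_pedigree_spec"))
  h1 <- unique(as.character(spec$founder_haplotypes[[1]][[1]]))
  h2 <- unique(as.character(spec$founder_haplotypes[[2]][[1]]))
  if (length(intersect(h1, h2)) > 0L) {
    ph1_error("the two founder mutant haplotypes must carry disjoint variants",
              "ph1_spec_error")
  }
  hap_sets <- list(WT = character(0), H1 = h1, H2 = h2)
  f2_haps <- list(
    c(hap_name(spec$founder_haplotypes[[1]][[1]], h1, h2),
      hap_name(spec$founder_haplotypes[[1]][[2]], h1, h2)),
    c(hap_name(spec$founder_haplotypes[[2]][[1]], h1, h2),
      hap_name(spec$founder_haplotypes[[2]][[2]], h1, h2)))
  vars <- c(h1, h2)
  if (length(vars) == 0L) ph1_error("no variants on any founder haplotype",
                                    "ph1_spec_error")

  with_seed(spec$seed, {
    rows <- list(); carried <- list()
    add <- function(id, fa, mo, sex, haps) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, family_id = "SIM", father_id = fa, mother_id = mo, sex = sex,
        affected = if (all(haps != "WT")) "affected" else "unaffected",
        stringsAsFactors = FALSE)
      carried[[id]] <<- haps
    }
    add("G1-F", NA, NA, "male", f2_haps[[1]])
    add("G1-M", NA, NA, "female", f2_haps[[2]])
    couples <- list(c("G1-F", "G1-M"))
    for (g in seq_len(spec$n_generations - 1L)) {
      next_couples <- list()
      ci <- 0L
      for (cp in couples) {
        ci <- ci + 1L
        for (k in seq_len(spec$offspring_per_couple)) {
          id <- sprintf("G%d-%d%s", g + 1L, ci, letters[k])
          from_f <- sample(carried[[cp[1]]], 1L)
          from_m <- sample(carried[[cp[2]]], 1L)
          sex <- sample(c("male", "female"), 1L)
          add(id, cp[1], cp[2], sex, c(from_f, from_m))
          if (g + 1L < spec$n_generations) {
            sp <- paste0(id, "-sp")
            add(sp, NA, NA, if (sex == "male") "female" else "male", c("WT", "WT"))
            next_couples[[length(next_couples) + 1L]] <-
              if (sex == "male") c(id, sp) else c(sp, id)
          }
        }
      }
      couples <- next_couples
    }
    members <- do.call(rbind, rows)
    G <- matrix(0L, nrow(members), length(vars),
                dimnames = list(members$id, vars))
    for (id in members$id) {
      for (h in carried[[id]]) {
        v <- hap_sets[[h]]
        if (length(v)) G[id, v] <- G[id, v] + 1L
      }
    }
    list(pedigree = pedigree(members, G),
         truth = list(haplotypes = list(H1 = h1, H2 = h2), carried = carried))
  })
}

hap_name <- function(set, h1, h2) {
  set <- unique(as.character(set))
  if (length(set) == 0L) "WT"
  else if (setequal(set, h1)) "H1"
  else if (setequal(set, h2)) "H2"
  else ph1_error("founder haplotype must be empty or equal to one of the two mutant sets",
                 "ph1_spec_error")
}

#' Specification for a simulated protein alignment
#'
#' @param n_species number of aligned homolog rows, reference included
#'   (default 8, the study's homolog panel size).
#' @param length ungapped reference length (default 392, the length of
#'   human AGT).
#' @param planted_conservation named integer vector: names are reference
#'   positions, values the exact number of species (reference included)
#'   that must match the reference residue there.
#' @param reference_residues optional named character vector forcing the
#'   reference residue at given positions (e.g. `c("49" = "M")`).
#' @param background_identity probability that a non-reference row matches
#'   the reference at a non-planted column (default 0.5).
#' @param seed RNG seed.
#' @return a `ph1_msa_spec`.
#' @export
msa_spec <- function(n_species = 8L, length = 392L,
                     planted_conservation = integer(0),
                     reference_residues = character(0),
                     background_identity = 0.5, seed = 1L) {
  n_species <- as.integer(n_species); length <- as.integer(length)
  stopifnot(n_species >= 1L, length >= 1L,
            background_identity >= 0, background_identity <= 1)
  pc <- as.integer(planted_conservation)
  names(pc) <- names(planted_conservation)
  if (length(pc)) {
    pos <- as.integer(names(pc))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > length)) {
      ph1_error("planted positions must lie within the reference length",
                "ph1_spec_error")
    }
    if (any(pc < 1L) || any(pc > n_species)) {
      ph1_error(sprintf("planted counts must lie in [1, %d]", n_species),
                "ph1_spec_error")
    }
  }
  structure(list(n_species = n_species, length = length,
                 planted_conservation = pc,
                 reference_residues = reference_residues,
                 background_identity = background_identity,
                 seed = as.integer(seed)),
            class = "ph1_msa_spec")
}

# species-style row ids emulating the study's 8-homolog panel; sequences
# are synthetic.
msa_row_ids <- function(n) {
  base <- c("homo_sapiens", "canis_familiaris", "felis_catus",
            "oryctolagus_cuniculus", "rattus_rattus", "mus_musculus",
            "xenopus_tropicalis", "danio_rerio")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("species_%02d", seq_len(n - length(base)) + length(base)))
}

#' Simulate an aligned homolog panel with planted conservation
#'
#' The reference row (first row, `homo_sapiens`) is drawn uniformly over
#' the 20 standard residues, then overwritten at any positions given in
#' `reference_residues`. At each planted column exactly the requested
#' number of rows (reference included) carries the reference residue; the
#' remaining rows are resampled to differ, so planted counts are exact,
#' not expected. Elsewhere each non-reference row matches the reference
#' with probability `background_identity`. No gaps are introduced.
#'
#' @param spec a [msa_spec()].
#' @return a named character vector of equal-length rows, with the requested
#'   plant stored in attribute `planted`.
#' @export
simulate_msa <- function(spec) {
  stopifnot(inherits(spec, "ph1_msa_spec"))
  with_seed(spec$seed, {
    n <- spec$n_species; L <- spec$length
    ref <- sample(AA1, L, replace = TRUE)
    if (length(spec$reference_residues)) {
      pos <- as.integer(names(spec$reference_residues))
      res <- toupper(spec$reference_residues)
      if (any(is.na(pos)) || any(pos < 1L) || any(pos > L) || any(!res %in% AA1)) {
        ph1_error("invalid reference_residues specification", "ph1_spec_error")
      }
      ref[pos] <- res
    }
    M <- matrix("", n, L)
    M[1, ] <- ref
    if (n > 1L) {
      for (j in seq_len(L)) {
        match_ref <- runif(n - 1L) < spec$background_identity
        other <- sample(setdiff(AA1, ref[j]), n - 1L, replace = TRUE)
        M[2:n, j] <- ifelse(match_ref, ref[j], other)
      }
    }
    for (k in seq_along(spec$planted_conservation)) {
      j <- as.integer(names(spec$planted_conservation)[k])
      want <- spec$planted_conservation[[k]]
      if (n > 1L) {
        conserved_rows <- if (want > 1L) 1L + sample.int(n - 1L, want - 1L) else integer(0)
        for (i in 2:n) {
          M[i, j] <- if (i %in% conserved_rows) ref[j]
                     else sample(setdiff(AA1, ref[j]), 1L)
        }
      }
    }
    rows <- apply(M, 1L, paste, collapse = "")
    names(rows) <- msa_row_ids(n)
    attr(rows, "planted") <- spec$planted_conservation
    rows
  })
}

#' Specification for a simulated diploid control cohort
#'
#' @param n_individuals cohort size (default 100, the study's healthy
#'   control panel).
#' @param het_carriers named integer vector: heterozygote count per
#'   variant.
#' @param hom_alt named integer vector: homozygous-alt count per variant.
#' @param seed RNG seed.
#' @return a `ph1_cohort_spec`.
#' @export
cohort_spec <- function(n_individuals = 100L, het_carriers = integer(0),
                        hom_alt = integer(0), seed = 1L) {
  n <- as.integer(n_individuals)
  stopifnot(n >= 1L)
  vars <- union(names(het_carriers), names(hom_alt))
  for (v in vars) {
    het <- if (v %in% names(het_carriers)) as.integer(het_carriers[[v]]) else 0L
    hom <- if (v %in% names(hom_alt)) as.integer(hom_alt[[v]]) else 0L
    if (het < 0L || hom < 0L || het + hom > n) {
      ph1_error(sprintf("carrier counts for '%s' exceed cohort capacity", v),
                "ph1_spec_error")
    }
  }
  structure(list(n_individuals = n, het_carriers = het_carriers,
                 hom_alt = hom_alt, seed = as.integer(seed)),
            class = "ph1_cohort_spec")
}

#' Simulate a control-cohort genotype table with exact carrier counts
#'
#' @param spec a [cohort_spec()].
#' @return a data.frame of alt-allele doses (0/1/2), one row per
#'   individual (`ctrl001`, ...), one column per variant; carrier
#'   positions are shuffled under the seed.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ph1_cohort_spec"))
  n <- spec$n_individuals
  vars <- union(names(spec$het_carriers), names(spec$hom_alt))
  with_seed(spec$seed, {
    m <- matrix(0L, n, max(length(vars), 1L))
    if (length(vars) == 0L) m <- matrix(integer(0), n, 0L)
    colnames(m) <- vars
    for (v in vars) {
      het <- if (v %in% names(spec$het_carriers)) spec$het_carriers[[v]] else 0L
      hom <- if (v %in% names(spec$hom_alt)) spec$hom_alt[[v]] else 0L
      idx <- sample.int(n, het + hom)
      if (hom > 0L) m[idx[seq_len(hom)], v] <- 2L
      if (het > 0L) m[idx[hom + seq_len(het)], v] <- 1L
    }
    out <- as.data.frame(m)
    rownames(out) <- sprintf("ctrl%03d", seq_len(n))
    out
  })
}
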