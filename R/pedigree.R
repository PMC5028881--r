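# Genotypes are stored as alt-allele dose: 0 (ref/ref), 1 (ref/alt),
# 2 (alt/alt), NA (missing / unsequenced individual).

#' Construct a pedigree with per-variant genotypes
#'
#' @param members data.frame with columns `id`, `family_id`, `father_id`,
#'   `mother_id` (`NA` marks a founder), `sex` (`"male"`, `"female"`,
#'   `"unknown"`), `affected` (`"affected"`, `"unaffected"`, `"unknown"`).
#' @param genotypes integer matrix of alt-allele doses (0/1/2/`NA`), rows
#'   named by individual id, columns by variant label.
#' @return an object of class `ph1_pedigree`.
#' @export
pedigree <- function(members, genotypes) {
  stopifnot(is.data.frame(members),
            all(c("id", "family_id", "father_id", "mother_id", "sex", "affected")
                %in% names(members)))
  members$id <- as.character(members$id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  if (anyDuplicated(members$id)) {
    ph1_error("duplicate individual ids in pedigree", "ph1_pedigree_error")
  }
  if (!all(members$sex %in% c("male", "female", "unknown"))) {
    ph1_error("sex must be male/female/unknown", "ph1_pedigree_error")
  }
  if (!all(members$affected %in% c("affected", "unaffected", "unknown"))) {
    ph1_error("affected must be affected/unaffected/unknown", "ph1_pedigree_error")
  }
  for (col in c("father_id", "mother_id")) {
    known <- !is.na(members[[col]])
    if (!all(members[[col]][known] %in% members$id)) {
      ph1_error(sprintf("unknown parent id in %s", col), "ph1_pedigree_error")
    }
  }
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes)) || !setequal(rownames(genotypes), members$id)) {
    ph1_error("genotype rows must be named by the pedigree's individual ids",
              "ph1_pedigree_error")
  }
  genotypes <- genotypes[members$id, , drop = FALSE]
  if (!all(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes))) {
    ph1_error("genotype doses must be 0, 1, 2 or NA", "ph1_pedigree_error")
  }
  ped <- structure(
    list(members = members, genotypes = genotypes,
         variant_labels = colnames(genotypes)),
    class = "ph1_pedigree")
  pedigree_order(ped)  # errors on ancestry cycles
  ped
}

# Topological order (parents before children); errors if an individual is
# its own ancestor.
pedigree_order <- function(ped) {
  ids <- ped$members$id
  placed <- character(0)
  remaining <- ids
  parents <- ped$members[, c("father_id", "mother_id")]
  rownames(parents) <- ids
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(i) {
      p <- unlist(parents[i, ])
      all(is.na(p) | p %in% placed)
    }, logical(1))]
    if (length(ready) == 0L) {
      ph1_error("pedigree contains an ancestry cycle", "ph1_pedigree_error")
    }
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

pedigree_founders <- function(ped) {
  ped$members$id[is.na(ped$members$father_id) & is.na(ped$members$mother_id)]
}

#' @export
print.ph1_pedigree <- function(x, ...) {
  cat(sprintf("<ph1_pedigree> %d individuals, %d variants (%s)\n",
              nrow(x$members), length(x$variant_labels),
              paste(x$variant_labels, collapse = ", ")))
  invisible(x)
}

# alleles a parent with dose g can transmit; NA dose -> either allele
transmissible <- function(g) {
  if (is.na(g)) c(0L, 1L)
  else if (g == 0L) 0L
  else if (g == 1L) c(0L, 1L)
  else 1L
}

#' Check Mendelian consistency of a pedigree
#'
#' For every child with at least one parent in the pedigree and every
#' variant, flags genotypes impossible under biparental transmission
#' (e.g. a heterozygous child of two homozygous-reference parents).
#' Missing genotypes never flag.
#'
#' @param ped a `ph1_pedigree`.
#' @return a data.frame of violations with columns `id`, `variant`, `rule`;
#'   zero rows when the pedigree is consistent.
#' @export
check_mendelian <- function(ped) {
  stopifnot(inherits(ped, "ph1_pedigree"))
  out <- list()
  G <- ped$genotypes
  for (k in seq_len(nrow(ped$members))) {
    child <- ped$members$id[k]
    fa <- ped$members$father_id[k]
    mo <- ped$members$mother_id[k]
    if (is.na(fa) && is.na(mo)) next
    for (v in ped$variant_labels) {
      gc <- G[child, v]
      if (is.na(gc)) next
      af <- if (is.na(fa)) c(0L, 1L) else transmissible(G[fa, v])
      am <- if (is.na(mo)) c(0L, 1L) else transmissible(G[mo, v])
      ok <- any(outer(af, am, "+") == gc)
      if (!ok) {
        out[[length(out) + 1L]] <- data.frame(
          id = child, variant = v,
          rule = "child allele count incompatible with parental genotypes",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(id = character(0), variant = character(0), rule = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

# --- cis/trans phasing ------------------------------------------------------

# The model: all variants lie within one small gene (AGXT spans ~10 kb), so
# no recombination is assumed and each gene copy in the family is one of at
# most three haplotype types: wild type, mutant haplotype 1, mutant
# haplotype 2. A partition of the observed alt-carrying variants over the
# two mutant haplotypes is consistent if haplotype pairs can be assigned to
# every individual so that (a) each typed individual's alt-allele doses are
# reproduced and (b) every child carries one haplotype drawn from each
# parent's pair.

# Given hap indicator vectors (logical over variants), return the unordered
# pairs (6 of them) compatible with a genotype dose vector g (NAs free).
compatible_pairs <- function(g, haps) {
  pairs <- list(c(1L, 1L), c(1L, 2L), c(1L, 3L), c(2L, 2L), c(2L, 3L), c(3L, 3L))
  keep <- vapply(pairs, function(p) {
    dose <- haps[[p[1]]] + haps[[p[2]]]
    all(is.na(g) | dose == g)
  }, logical(1))
  pairs[keep]
}

# Satisfiability search: can haplotype pairs be assigned to all individuals
# consistently with transmission? Individuals are visited parents-first.
phase_satisfiable <- function(ped, order_ids, candidates) {
  fa <- ped$members$father_id
  mo <- ped$members$mother_id
  names(fa) <- names(mo) <- ped$members$id
  assign_env <- new.env(parent = emptyenv())

  dfs <- function(k) {
    if (k > length(order_ids)) return(TRUE)
    id <- order_ids[k]
    for (pair in candidates[[id]]) {
      ok <- TRUE
      f <- fa[[id]]; m <- mo[[id]]
      fp <- if (!is.na(f)) get0(f, envir = assign_env) else NULL
      mp <- if (!is.na(m)) get0(m, envir = assign_env) else NULL
      if (!is.null(fp) || !is.null(mp)) {
        from_f <- if (is.null(fp)) c(1L, 2L, 3L) else fp
        from_m <- if (is.null(mp)) c(1L, 2L, 3L) else mp
        ok <- any(vapply(from_f, function(x)
          any(setequal_pair(pair, x, from_m)), logical(1)))
      }
      if (!ok) next
      assign(id, pair, envir = assign_env)
      if (dfs(k + 1L)) return(TRUE)
      rm(list = id, envir = assign_env)
    }
    FALSE
  }
  dfs(1L)
}

# is unordered pair `pair` formable as {x, y} with y in ys?
setequal_pair <- function(pair, x, ys) {
  vapply(ys, function(y) {
    (pair[1] == x && pair[2] == y) || (pair[1] == y && pair[2] == x)
  }, logical(1))
}

#' Infer the cis/trans phase of tightly linked variants
#'
#' Enumerates every partition of the observed alt-carrying variants over
#' two founder mutant haplotypes and keeps the partitions for which
#' haplotype pairs can be assigned to all individuals consistently with the
#' observed genotypes and with gap-free biparental transmission (no
#' recombination within the gene). A unique surviving partition resolves
#' the phase; several leave it ambiguous (all consistent partitions are
#' returned); none means the two-haplotype model cannot explain the data.
#'
#' When the minor-allele marker `IVS1+74bp` is among the phased variants,
#' the haplotype carrying it is labelled `AGT-Mi` and the other mutant
#' haplotype `AGT-Ma`, matching the study vocabulary.
#'
#' @param ped a `ph1_pedigree`.
#' @param variant_labels variants to phase; defaults to every variant with
#'   at least one observed alt allele.
#' @return a `ph1_phase`: `status` (`"resolved"`, `"ambiguous"`,
#'   `"inconsistent"`), `haplotypes` (list of two character vectors, named
#'   `AGT-Mi`/`AGT-Ma` when the minor-allele tag is present), `partitions`
#'   (all consistent partitions), `supporting_individuals`.
#' @export
phase_variants <- function(ped, variant_labels = NULL) {
  stopifnot(inherits(ped, "ph1_pedigree"))
  G <- ped$genotypes
  if (is.null(variant_labels)) {
    variant_labels <- ped$variant_labels[colSums(G > 0, na.rm = TRUE) > 0]
  }
  if (!all(variant_labels %in% ped$variant_labels)) {
    ph1_error("unknown variant label(s) requested for phasing", "ph1_pedigree_error")
  }
  K <- length(variant_labels)
  n_founders <- length(pedigree_founders(ped))
  if (K > 6L || n_founders > 10L) {
    ph1_error(sprintf(
      "phase enumeration refused: %d variants, %d founders exceeds the supported size (6 variants, 10 founders)",
      K, n_founders), "ph1_size_error")
  }
  supporting <- ped$members$id[rowSums(G[, variant_labels, drop = FALSE] > 0,
                                       na.rm = TRUE) > 0]
  if (K == 0L) {
    return(structure(list(status = "resolved",
                          haplotypes = list(character(0), character(0)),
                          partitions = list(), supporting_individuals = character(0)),
                     class = "ph1_phase"))
  }

  order_ids <- pedigree_order(ped)
  Gv <- G[, variant_labels, drop = FALSE]

  consistent <- list()
  # assignment vector a in {1,2}^K; fix a[1] = 1 to quotient out the
  # haplotype-label swap
  n_assign <- 2^(K - 1L)
  for (code in 0:(n_assign - 1L)) {
    a <- c(1L, if (K > 1L) as.integer(intToBits(code)[seq_len(K - 1L)]) + 1L)
    h1 <- a == 1L
    h2 <- a == 2L
    haps <- list(rep(FALSE, K), h1, h2)  # wild type, hap1, hap2
    candidates <- lapply(ped$members$id, function(id) compatible_pairs(Gv[id, ], haps))
    names(candidates) <- ped$members$id
    if (any(vapply(candidates, length, integer(1)) == 0L)) next
    if (phase_satisfiable(ped, order_ids, candidates)) {
      consistent[[length(consistent) + 1L]] <-
        list(variant_labels[h1], variant_labels[h2])
    }
  }

  status <- if (length(consistent) == 1L) "resolved"
            else if (length(consistent) > 1L) "ambiguous"
            else "inconsistent"
  hap <- if (status == "resolved") consistent[[1]] else list(character(0), character(0))
  if (status == "resolved") {
    ivs <- grepl("^IVS", hap[[1]]) ; ivs2 <- grepl("^IVS", hap[[2]])
    if (any(ivs)) names(hap) <- c("AGT-Mi", "AGT-Ma")
    else if (any(ivs2)) { hap <- rev(hap); names(hap) <- c("AGT-Mi", "AGT-Ma") }
    else names(hap) <- c("hap1", "hap2")
  }
  structure(list(status = status, haplotypes = hap, partitions = consistent,
                 supporting_individuals = supporting),
            class = "ph1_phase")
}

#' @export
print.ph1_phase <- function(x, ...) {
  cat(sprintf("<ph1_phase> status: %s\n", x$status))
  if (x$status == "resolved") {
    for (nm in names(x$haplotypes)) {
      cat(sprintf("  %s: {%s}\n", nm, paste(x$haplotypes[[nm]], collapse = ", ")))
    }
  } else if (x$status == "ambiguous") {
    cat(sprintf("  %d consistent partitions\n", length(x$partitions)))
  }
  invisible(x)
}

#' Test autosomal-recessive co-segregation
#'
#' With the phase resolved, each typed individual carries a known dose of
#' each mutant haplotype; individuals are classified as biallelic (two
#' mutant haplotypes -- compound heterozygous or homozygous), carrier
#' (exactly one) or noncarrier. Under a fully penetrant autosomal recessive
#' model every affected individual must be biallelic and no unaffected
#' individual may be; deviations are reported as violations (or downgraded
#' to warnings with `strict = FALSE`, for incomplete-penetrance scenarios).
#'
#' @param ped a `ph1_pedigree`.
#' @param phase a resolved `ph1_phase` for the pedigree's variants.
#' @param strict if `FALSE`, AR-rule deviations are reported in `warnings`
#'   instead of `violations`.
#' @return a `ph1_segregation` report: `model`, `n_affected_biallelic`
#'   (count of biallelic individuals; all affected when segregation is
#'   consistent), `n_carriers`, `n_noncarriers`, `n_untyped`, `violations`,
#'   `warnings`, `classification` (per-individual data.frame), `consistent`.
#' @export
cosegregation_test <- function(ped, phase, strict = TRUE) {
  stopifnot(inherits(ped, "ph1_pedigree"), inherits(phase, "ph1_phase"))
  if (!identical(phase$status, "resolved")) {
    ph1_error("co-segregation requires a resolved phase", "ph1_phase_error")
  }
  hap1 <- phase$haplotypes[[1]]
  hap2 <- phase$haplotypes[[2]]
  G <- ped$genotypes

  dose_of <- function(id, vars) {
    if (length(vars) == 0L) return(0L)
    g <- G[id, vars]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NA_integer_)
    if (length(unique(g)) > 1L) return(-1L)  # internally inconsistent
    g[[1]]
  }

  cls <- character(nrow(ped$members))
  viol <- list()
  for (k in seq_len(nrow(ped$members))) {
    id <- ped$members$id[k]
    if (all(is.na(G[id, ]))) { cls[k] <- "untyped"; next }
    d1 <- dose_of(id, hap1)
    d2 <- dose_of(id, hap2)
    if (identical(d1, -1L) || identical(d2, -1L)) {
      cls[k] <- "inconsistent"
      viol[[length(viol) + 1L]] <- data.frame(
        id = id, rule = "unequal doses within one phased haplotype",
        stringsAsFactors = FALSE)
      next
    }
    if (is.na(d1)) d1 <- 0L
    if (is.na(d2)) d2 <- 0L
    n_mut <- d1 + d2
    cls[k] <- if (n_mut >= 2L) "biallelic" else if (n_mut == 1L) "carrier" else "noncarrier"
  }

  aff <- ped$members$affected
  for (k in seq_len(nrow(ped$members))) {
    if (cls[k] %in% c("untyped", "inconsistent")) next
    if (aff[k] == "affected" && cls[k] != "biallelic") {
      viol[[length(viol) + 1L]] <- data.frame(
        id = ped$members$id[k], rule = "affected individual is not biallelic",
        stringsAsFactors = FALSE)
    }
    if (aff[k] == "unaffected" && cls[k] == "biallelic") {
      viol[[length(viol) + 1L]] <- data.frame(
        id = ped$members$id[k], rule = "unaffected individual is biallelic",
        stringsAsFactors = FALSE)
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(id = character(0), rule = character(0), stringsAsFactors = FALSE)

  res <- list(model = "autosomal recessive, biallelic",
              n_affected_biallelic = sum(cls == "biallelic"),
              n_carriers = sum(cls == "carrier"),
              n_noncarriers = sum(cls == "noncarrier"),
              n_untyped = sum(cls %in% c("untyped", "inconsistent")),
              violations = if (strict) viol else viol[0, ],
              warnings = if (strict) viol[0, ] else viol,
              classification = data.frame(id = ped$members$id, class = cls,
                                          affected = aff, stringsAsFactors = FALSE),
              consistent = if (strict) nrow(viol) == 0L else TRUE)
  structure(res, class = "ph1_segregation")
}

#' @export
print.ph1_segregation <- function(x, ...) {
  cat(sprintf("<ph1_segregation> %s\n", x$model))
  cat(sprintf("  biallelic %d | carriers %d | noncarriers %d | untyped %d\n",
              x$n_affected_biallelic, x$n_carriers, x$n_noncarriers, x$n_untyped))
  cat(sprintf("  %s\n", if (nrow(x$violations) == 0L) "consistent with AR inheritance"
              else sprintf("%d violation(s)", nrow(x$violations))))
  invisible(x)
}

#' Alt-allele frequency in a diploid cohort
#'
#' The minor allele of each marker is the alt allele by construction, so
#' the reported frequency is alt-allele count over twice the number of
#' typed individuals; individuals with a missing genotype at the marker are
#' excluded from the denominator.
#'
#' @param cohort a data.frame or matrix of alt-allele doses (0/1/2/`NA`),
#'   one row per individual, columns named by variant label.
#' @param variant_label the column to summarize.
#' @return the allele frequency in `[0, 1]`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_individuals = 100,
#'                                       het_carriers = c(`IVS1+74bp` = 6), seed = 1))
#' allele_frequency(cohort, "IVS1+74bp") # 0.03
#' @export
allele_frequency <- function(cohort, variant_label) {
  m <- as.matrix(cohort)
  if (nrow(m) == 0L) ph1_error("empty cohort", "ph1_cohort_error")
  if (!variant_label %in% colnames(m)) {
    ph1_error(sprintf("variant '%s' not in cohort table", variant_label),
              "ph1_cohort_error")
  }
  g <- m[, variant_label]
  typed <- !is.na(g)
  if (!any(typed)) {
    ph1_error(sprintf("all genotypes missing for '%s'", variant_label),
              "ph1_cohort_error")
  }
  if (!all(g[typed] %in% c(0, 1, 2))) {
    ph1_error("cohort doses must be 0, 1, 2 or NA", "ph1_cohort_error")
  }
  sum(g[typed]) / (2 * sum(typed))
}
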