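## Pedigree simulation: Hardy-Weinberg founders, gene dropping through
## three-generation families, per-allele genotyping error.  A desk-scale
## simulator for validating the likelihood-ratio classifier on data whose
## true relationships are known by construction.

#' Three-generation family template
#'
#' The built-in family structure used by [simulate_study()]: two founder
#' couples, one with five children and one with a single child, a marriage
#' between the two sibships, and five grandchildren, fifteen members in
#' all.  Second degree is the most distant blood relationship present.
#' The labeled pairs derived from this template ([pedigree_pairs()]) number
#' 22 parent-child, 20 full-sibling, 40 second-degree and 22 unrelated
#' pairs per family.
#'
#' @return A data frame with columns `id`, `father`, `mother`,
#'   `generation`; founders have `NA` parents.
#' @export
family_template <- function() {
  data.frame(
    id = c("gp1", "gp2", "gp3", "gp4",
           "c1", "c2", "c3", "c4", "c5", "d1",
           "g1", "g2", "g3", "g4", "g5"),
    father = c(NA, NA, NA, NA,
               rep("gp1", 5), "gp3",
               rep("c1", 5)),
    mother = c(NA, NA, NA, NA,
               rep("gp2", 5), "gp4",
               rep("d1", 5)),
    generation = c(1L, 1L, 1L, 1L, rep(2L, 6), rep(3L, 5)),
    stringsAsFactors = FALSE
  )
}

check_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("id", "father", "mother") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate ids in pedigree")
  nonf <- !is.na(ped$father) | !is.na(ped$mother)
  if (any(nonf & (is.na(ped$father) | is.na(ped$mother))))
    stop("non-founders must have exactly two parents")
  parents <- c(ped$father[nonf], ped$mother[nonf])
  if (!all(parents %in% ped$id)) stop("pedigree refers to unknown parent ids")
  # topological order check (parents precede children when sorted)
  ord <- topo_order(ped)
  if (anyNA(ord)) stop("pedigree contains a cycle")
  invisible(ped)
}

topo_order <- function(ped) {
  n <- nrow(ped)
  placed <- is.na(ped$father) & is.na(ped$mother)
  ord <- ped$id[placed]
  while (length(ord) < n) {
    ready <- !placed & ped$father %in% ord & ped$mother %in% ord
    if (!any(ready)) return(NA)
    ord <- c(ord, ped$id[ready])
    placed <- placed | ready
  }
  ord
}

ancestor_sets <- function(ped) {
  anc <- stats::setNames(vector("list", nrow(ped)), ped$id)
  for (id in topo_order(ped)) {
    i <- match(id, ped$id)
    if (is.na(ped$father[i])) anc[[id]] <- id
    else anc[[id]] <- unique(c(id, anc[[ped$father[i]]], anc[[ped$mother[i]]]))
  }
  anc
}

#' Labeled pairs implied by a pedigree
#'
#' Derives the true relationship of every pair of pedigree members from
#' the structure alone (never from genotypes).  Parent-child, full-sibling
#' and second-degree (half-sibling, avuncular, grandparent-grandchild)
#' pairs are labeled as such; pairs with no common ancestor are labeled
#' unrelated, except that a mated pair in which either member descends
#' from other pedigree members (an in-law couple inside the family tree)
#' is excluded from the manifest.  Pairs with more distant blood
#' relationships than second degree are not labeled.
#'
#' @param ped a pedigree data frame (see [family_template()]).
#' @return A data frame with columns `id_a`, `id_b`, `relationship`.
#' @export
pedigree_pairs <- function(ped) {
  check_pedigree(ped)
  anc <- ancestor_sets(ped)
  ids <- ped$id
  fa <- stats::setNames(ped$father, ids)
  mo <- stats::setNames(ped$mother, ids)
  is_founder <- stats::setNames(is.na(ped$father), ids)
  # children lookup for mate detection
  kids_of <- function(x, y) {
    any((fa == x & mo == y) | (fa == y & mo == x), na.rm = TRUE)
  }
  parents <- function(x) c(fa[[x]], mo[[x]])
  fullsib <- function(x, y) {
    px <- parents(x); py <- parents(y)
    !anyNA(px) && !anyNA(py) && setequal(px, py) && x != y
  }
  halfsib <- function(x, y) {
    px <- parents(x); py <- parents(y)
    !anyNA(px) && !anyNA(py) && length(intersect(px, py)) == 1
  }
  grandparent <- function(x, y) {
    py <- parents(y)
    !anyNA(py) && any(vapply(py, function(p) x %in% parents(p) &&
                               !anyNA(parents(p)), logical(1)))
  }
  avuncular <- function(x, y) {
    py <- parents(y)
    !anyNA(py) && any(vapply(py, function(p) fullsib(x, p), logical(1)))
  }
  out <- list()
  n <- length(ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- ids[i]; y <- ids[j]
    rel <- NA_character_
    if (x %in% parents(y) || y %in% parents(x)) rel <- "parent_child"
    else if (fullsib(x, y)) rel <- "full_sibs"
    else if (halfsib(x, y) || grandparent(x, y) || grandparent(y, x) ||
             avuncular(x, y) || avuncular(y, x)) rel <- "second_degree"
    else if (!length(intersect(anc[[x]], anc[[y]]))) {
      mated <- kids_of(x, y)
      if (!(mated && (!is_founder[[x]] || !is_founder[[y]])))
        rel <- "unrelated"
    }
    if (!is.na(rel)) out[[length(out) + 1]] <-
        data.frame(id_a = x, id_b = y, relationship = rel,
                   stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## ---- genotype containers ------------------------------------------------

# geno_set: genotypes for a set of samples over one panel, stored as two
# allele matrices (loci x samples); columns A1/A2 are the two transmitted
# haplotypes, so phase is preserved through gene dropping.
geno_set <- function(panel, samples, A1, A2) {
  structure(list(snp_id = panel$snp_id, chrom = panel$chrom,
                 pos = panel$pos, cm = panel$cm,
                 ref = panel$ref, alt = panel$alt,
                 samples = samples, A1 = A1, A2 = A2),
            class = "geno_set")
}

#' @export
print.geno_set <- function(x, ...) {
  cat("Genotype set: ", length(x$samples), " sample(s) x ",
      length(x$snp_id), " marker(s)\n", sep = "")
  invisible(x)
}

#' Extract one sample's genotype profile from a genotype set
#'
#' @param x a `geno_set` (from [simulate_founders()], [gene_drop()] or a
#'   [simulate_study()] result's `$genotypes`).
#' @param id sample identifier.
#' @return A `genotype_profile` data frame with columns `snp_id`, `chrom`,
#'   `pos`, `a1`, `a2` (alleles in canonical order).
#' @export
study_profile <- function(x, id) {
  if (inherits(x, "kin_study")) x <- x$genotypes
  stopifnot(inherits(x, "geno_set"))
  j <- match(id, x$samples)
  if (is.na(j)) stop("unknown sample id: ", id)
  a1 <- x$A1[, j]; a2 <- x$A2[, j]
  structure(data.frame(snp_id = x$snp_id, chrom = x$chrom, pos = x$pos,
                       a1 = pmin(a1, a2), a2 = pmax(a1, a2),
                       stringsAsFactors = FALSE),
            class = c("genotype_profile", "data.frame"))
}

#' Draw founder genotypes under Hardy-Weinberg equilibrium
#'
#' Each founder receives, at every panel marker, two alleles drawn
#' independently with the panel's ALT-allele frequency in the chosen
#' population.
#'
#' @param panel an `snp_panel`.
#' @param pop population label (panel frequency column).
#' @param n number of founders.
#' @param ids optional sample ids (default `"F1"..."Fn"`).
#' @param seed optional integer seed; RNG state is restored.
#' @return A `geno_set` of `n` samples.
#' @export
simulate_founders <- function(panel, pop, n = 1, ids = paste0("F", seq_len(n)),
                              seed = NULL) {
  if (!pop %in% panel_populations(panel))
    stop("population ", pop, " has no frequency column in this panel")
  stopifnot(n >= 1, length(ids) == n)
  with_seed(seed, {
    L <- nrow(panel)
    p <- panel[[pop]]
    draw <- function() ifelse(stats::runif(L * n) < rep(p, n),
                              rep(panel$alt, n), rep(panel$ref, n))
    A1 <- matrix(draw(), L, n)
    A2 <- matrix(draw(), L, n)
    colnames(A1) <- colnames(A2) <- ids
    geno_set(panel, ids, A1, A2)
  })
}

# one meiosis: the haplotype a parent transmits, as a vector of alleles
meiosis <- function(gs, j, mode, loci_by_chrom) {
  L <- length(gs$snp_id)
  if (mode == "independent") {
    pick <- stats::runif(L) < 0.5
    return(ifelse(pick, gs$A1[, j], gs$A2[, j]))
  }
  out <- character(L)
  for (idx in loci_by_chrom) {
    cm <- gs$cm[idx]
    span <- max(cm) - min(cm)
    ncross <- stats::rpois(1, span / 100)   # Haldane: no interference
    cuts <- sort(stats::runif(ncross, min(cm), max(cm)))
    phase <- (findInterval(cm, cuts) + stats::rbinom(1, 1, 0.5)) %% 2
    out[idx] <- ifelse(phase == 0, gs$A1[idx, j], gs$A2[idx, j])
  }
  out
}

#' Gene-drop genotypes through a pedigree
#'
#' Propagates founder genotypes down a pedigree by Mendelian transmission:
#' each non-founder receives one allele from each parent.  Under
#' `mode = "independent"` every locus segregates independently (each
#' transmitted allele is a uniform draw from the parent's two), which is
#' appropriate for marker panels thinned to large genetic distances.
#' Under `mode = "haldane"` each parent transmits per-chromosome
#' recombinant haplotypes, with crossovers falling as a Poisson process on
#' the genetic-map (cM) scale -- no crossover interference.
#'
#' @param ped pedigree data frame.
#' @param founders a `geno_set` containing a profile for every founder in
#'   `ped`.
#' @param mode `"independent"` or `"haldane"`.
#' @param seed optional integer seed.
#' @return A `geno_set` covering every pedigree member.
#' @export
gene_drop <- function(ped, founders, mode = c("independent", "haldane"),
                      seed = NULL) {
  mode <- match.arg(mode)
  check_pedigree(ped)
  stopifnot(inherits(founders, "geno_set"))
  fids <- ped$id[is.na(ped$father)]
  missing <- setdiff(fids, founders$samples)
  if (length(missing)) stop("no founder profile for: ",
                            paste(missing, collapse = ", "))
  with_seed(seed, {
    L <- length(founders$snp_id)
    ord <- topo_order(ped)
    A1 <- matrix(NA_character_, L, nrow(ped),
                 dimnames = list(NULL, ped$id))
    A2 <- A1
    for (f in fids) {
      j <- match(f, founders$samples)
      A1[, f] <- founders$A1[, j]
      A2[, f] <- founders$A2[, j]
    }
    gs <- geno_set(list(snp_id = founders$snp_id, chrom = founders$chrom,
                        pos = founders$pos, cm = founders$cm,
                        ref = founders$ref, alt = founders$alt),
                   ped$id, A1, A2)
    loci_by_chrom <- split(seq_len(L), gs$chrom)
    for (id in setdiff(ord, fids)) {
      i <- match(id, ped$id)
      gs$A1[, id] <- meiosis(gs, match(ped$father[i], gs$samples),
                             mode, loci_by_chrom)
      gs$A2[, id] <- meiosis(gs, match(ped$mother[i], gs$samples),
                             mode, loci_by_chrom)
    }
    gs
  })
}

#' Inject per-allele genotyping error
#'
#' Substitutes each allele independently with probability `rate`,
#' uniformly among the three other nucleotides -- the same channel assumed
#' by the likelihood error model.
#'
#' @param x a `geno_set` or a `genotype_profile` data frame.
#' @param rate per-allele substitution probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return Object of the same type as `x`.
#' @export
inject_error <- function(x, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("error rate must be in [0, 1)")
  if (rate == 0) return(x)
  nts <- c("A", "C", "G", "T")
  alt3 <- matrix(c("C", "G", "T",  "A", "G", "T",
                   "A", "C", "T",  "A", "C", "G"), nrow = 3)
  colnames(alt3) <- nts
  corrupt <- function(a) {
    hit <- !is.na(a) & stats::runif(length(a)) < rate
    if (any(hit)) {
      pick <- sample.int(3, sum(hit), replace = TRUE)
      a[hit] <- alt3[cbind(pick, match(a[hit], nts))]
    }
    a
  }
  with_seed(seed, {
    if (inherits(x, "geno_set")) {
      x$A1[] <- corrupt(x$A1)
      x$A2[] <- corrupt(x$A2)
      x
    } else {
      a1 <- corrupt(x$a1); a2 <- corrupt(x$a2)
      x$a1 <- pmin(a1, a2); x$a2 <- pmax(a1, a2)
      x
    }
  })
}

#' Simulate a multi-family relationship-testing study
#'
#' Generates `n_families` independent copies of the three-generation
#' [family_template()]: fresh Hardy-Weinberg founders per family,
#' genotypes gene-dropped through the pedigree, per-allele genotyping
#' error injected at `error_rate`, and the labeled pairs of each family
#' collected into one manifest (ids are prefixed `fam<k>_`).
#'
#' @param n_families number of families.
#' @param panel an `snp_panel` (typically [synthetic_panel()] output or a
#'   [select_snps()] selection).
#' @param pop population label whose frequencies found the families.
#' @param error_rate per-allele genotyping error rate.
#' @param mode transmission mode, see [gene_drop()].
#' @param seed optional integer seed; the full study is reproducible from
#'   it.
#' @return An object of class `kin_study`: list with `genotypes` (a
#'   `geno_set`), `pairs` (manifest data frame `id_a`, `id_b`,
#'   `relationship`), `panel`, `pop`, `error_rate`, `mode`.
#' @export
simulate_study <- function(n_families, panel, pop, error_rate = 0,
                           mode = c("independent", "haldane"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_families >= 1, nrow(panel) >= 1)
  with_seed(seed, {
    ped <- family_template()
    base_pairs <- pedigree_pairs(ped)
    fids <- ped$id[is.na(ped$father)]
    all_A1 <- list(); all_A2 <- list(); samples <- character(0)
    pairs <- vector("list", n_families)
    for (k in seq_len(n_families)) {
      founders <- simulate_founders(panel, pop, n = length(fids), ids = fids)
      gs <- gene_drop(ped, founders, mode = mode)
      pre <- paste0("fam", k, "_")
      all_A1[[k]] <- gs$A1; all_A2[[k]] <- gs$A2
      samples <- c(samples, paste0(pre, gs$samples))
      pairs[[k]] <- data.frame(id_a = paste0(pre, base_pairs$id_a),
                               id_b = paste0(pre, base_pairs$id_b),
                               relationship = base_pairs$relationship,
                               stringsAsFactors = FALSE)
    }
    A1 <- do.call(cbind, all_A1); A2 <- do.call(cbind, all_A2)
    colnames(A1) <- colnames(A2) <- samples
    gs <- geno_set(panel, samples, A1, A2)
    gs <- inject_error(gs, error_rate)
    structure(list(genotypes = gs, pairs = do.call(rbind, pairs),
                   panel = panel, pop = pop, error_rate = error_rate,
                   mode = mode),
              class = "kin_study")
  })
}

#' @export
print.kin_study <- function(x, ...) {
  cat("Simulated kinship study: ", length(x$genotypes$samples),
      " samples, ", nrow(x$pairs), " labeled pairs (",
      paste(names(table(x$pairs$relationship)),
            table(x$pairs$relationship), sep = "=", collapse = ", "),
      "), error rate ", format(x$error_rate), "\n", sep = "")
  invisible(x)
}

## ---- exact IBD enumeration ----------------------------------------------

#' Exact IBD coefficients by exhaustive transmission enumeration
#'
#' Enumerates every combination of Mendelian transmission choices in a
#' (small) pedigree, tracking uniquely labeled founder alleles, and counts
#' how often the given pair shares 0, 1 or 2 alleles identical by
#' descent.  This recovers the relationship IBD coefficients exactly
#' (e.g. (1/4, 1/2, 1/4) for full siblings) without reference to the
#' built-in coefficient table, so it serves as an independent check of it.
#' The cost is `4^m` for `m` non-founders; pedigrees with more than ~8
#' non-founders are rejected.
#'
#' @param ped pedigree data frame.
#' @param a,b ids of the pair.
#' @return Named numeric vector `c(phi2, phi1, phi0)`.
#' @examples
#' rp <- relationship_pedigree("full_sibs")
#' enumerate_ibd(rp$ped, rp$pair[1], rp$pair[2])
#' @export
enumerate_ibd <- function(ped, a, b) {
  check_pedigree(ped)
  stopifnot(a %in% ped$id, b %in% ped$id)
  nonf <- ped$id[!is.na(ped$father)]
  m <- length(nonf)
  if (m > 8) stop("pedigree too large for exhaustive enumeration")
  ord <- topo_order(ped)
  fa <- stats::setNames(ped$father, ped$id)
  mo <- stats::setNames(ped$mother, ped$id)
  counts <- c(`2` = 0, `1` = 0, `0` = 0)
  nstates <- 4^m
  choices <- integer(m)
  for (s in 0:(nstates - 1)) {
    v <- s
    for (i in seq_len(m)) { choices[i] <- v %% 4; v <- v %/% 4 }
    alleles <- list()
    for (id in ord) {
      if (is.na(fa[[id]])) {
        alleles[[id]] <- paste0(id, c(".1", ".2"))
      } else {
        ci <- match(id, nonf)
        fpick <- choices[ci] %% 2 + 1
        mpick <- choices[ci] %/% 2 + 1
        alleles[[id]] <- c(alleles[[fa[[id]]]][fpick],
                           alleles[[mo[[id]]]][mpick])
      }
    }
    ga <- alleles[[a]]; gb <- alleles[[b]]
    shared <- sum(pmin(table(ga)[unique(c(ga, gb))],
                       table(gb)[unique(c(ga, gb))]), na.rm = TRUE)
    counts[as.character(shared)] <- counts[as.character(shared)] + 1
  }
  p <- counts / nstates
  c(phi2 = unname(p["2"]), phi1 = unname(p["1"]), phi0 = unname(p["0"]))
}

#' Minimal pedigrees for the standard relationships
#'
#' Convenience pedigrees, each just large enough to contain one pair with
#' the named relationship, for use with [enumerate_ibd()] and small
#' gene-dropping checks.
#'
#' @param name one of `"parent_child"`, `"full_sibs"`, `"half_sibs"`,
#'   `"grandparent"`, `"avuncular"`, `"first_cousins"`, `"unrelated"`.
#' @return List with `ped` (pedigree data frame) and `pair` (the two ids).
#' @export
relationship_pedigree <- function(name) {
  P <- function(id, father = NA, mother = NA)
    data.frame(id = id, father = father, mother = mother,
               stringsAsFactors = FALSE)
  switch(name,
    parent_child = list(
      ped = rbind(P("f1"), P("f2"), P("c", "f1", "f2")),
      pair = c("f1", "c")),
    full_sibs = list(
      ped = rbind(P("f1"), P("f2"), P("s1", "f1", "f2"), P("s2", "f1", "f2")),
      pair = c("s1", "s2")),
    half_sibs = list(
      ped = rbind(P("f1"), P("f2"), P("f3"),
                  P("s1", "f1", "f2"), P("s2", "f1", "f3")),
      pair = c("s1", "s2")),
    grandparent = list(
      ped = rbind(P("f1"), P("f2"), P("f3"),
                  P("p", "f1", "f2"), P("g", "p", "f3")),
      pair = c("f1", "g")),
    avuncular = list(
      ped = rbind(P("f1"), P("f2"), P("f3"),
                  P("s1", "f1", "f2"), P("s2", "f1", "f2"),
                  P("n", "s2", "f3")),
      pair = c("s1", "n")),
    first_cousins = list(
      ped = rbind(P("f1"), P("f2"), P("f3"), P("f4"),
                  P("s1", "f1", "f2"), P("s2", "f1", "f2"),
                  P("c1", "s1", "f3"), P("c2", "s2", "f4")),
      pair = c("c1", "c2")),
    unrelated = list(
      ped = rbind(P("f1"), P("f2")),
      pair = c("f1", "f2")),
    stop("unknown relationship pedigree: ", name)
  )
}
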