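# Independent oracles and small file fixtures used across the tests.

NTS <- c("A", "C", "G", "T")

# all unordered genotypes over an allele set
all_genotypes <- function(alleles) {
  unique(unlist(lapply(seq_along(alleles), function(i)
    lapply(i:length(alleles), function(j)
      genotype(alleles[i], alleles[j])))))
}

# Brute-force parent-child likelihood: enumerate parent ordered genotypes,
# the transmitted-allele choice, the mutation event over all nucleotides,
# and the population allele completing the child genotype.  Direction is
# then symmetrised the same way the tested function defines it.
oracle_parent_child <- function(x, y, freqs, mu) {
  alleles <- names(freqs)
  directional <- function(par, chi) {
    tot <- 0
    for (p1 in alleles) for (p2 in alleles) {            # ordered parent
      gpar <- genotype(p1, p2)
      if (gpar != par) next
      prob_par <- freqs[[p1]] * freqs[[p2]]
      for (t in c(p1, p2)) {                             # transmitted allele
        for (m_out in NTS) {                             # mutation outcome
          w_mut <- if (m_out == t) 1 - mu else mu / 3
          for (d in alleles) {                           # population allele
            if (genotype(m_out, d) == chi)
              tot <- tot + prob_par * 0.5 * w_mut * freqs[[d]]
          }
        }
      }
    }
    tot
  }
  0.5 * (directional(x, y) + directional(y, x))
}

# Exact maximum number of markers selectable on one chromosome subject to
# a minimum spacing, by dynamic programming over sorted positions (an
# exhaustive maximisation, independent of the greedy sweep).
oracle_max_selectable <- function(cm, mgd) {
  cm <- sort(cm)
  n <- length(cm)
  if (!n) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    prev <- which(cm <= cm[i] - mgd)
    if (length(prev)) best[i] <- 1L + max(best[prev])
  }
  max(best)
}

# Plain-definition scorer used to cross-check score_calls()
oracle_metrics <- function(true, pred, classes) {
  acc <- mean(true == pred)
  f1s <- numeric(0); supports <- numeric(0)
  for (cl in classes) {
    support <- sum(true == cl)
    if (!support) next
    tp <- sum(true == cl & pred == cl)
    prec <- if (sum(pred == cl)) tp / sum(pred == cl) else 0
    rec <- tp / support
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    f1s <- c(f1s, f1); supports <- c(supports, support)
  }
  list(accuracy = acc, weighted_f1 = sum(f1s * supports) / sum(supports))
}

# founder genotype set whose alleles are unique origin labels, so IBD
# sharing is directly observable in gene-dropped output
labeled_founders <- function(panel, ids) {
  L <- nrow(panel)
  A1 <- sapply(ids, function(id) rep(paste0(id, ".1"), L))
  A2 <- sapply(ids, function(id) rep(paste0(id, ".2"), L))
  snpkin:::geno_set(panel, ids, matrix(A1, L), matrix(A2, L))
}

shared_ibd <- function(ga1, ga2, gb1, gb2) {
  mapply(function(a1, a2, b1, b2) {
    labs <- unique(c(a1, a2, b1, b2))
    ca <- table(factor(c(a1, a2), levels = labs))
    cb <- table(factor(c(b1, b2), levels = labs))
    sum(pmin(ca, cb))
  }, ga1, ga2, gb1, gb2)
}

# empirical (phi2, phi1, phi0) for a pair in a pedigree, over n independent loci
empirical_phi <- function(name, pair_ids = NULL, n = 2e4, seed = 1) {
  rp <- relationship_pedigree(name)
  if (is.null(pair_ids)) pair_ids <- rp$pair
  panel <- synthetic_panel(n, c(0.4, 0.5), populations = "SIM", seed = seed)
  founders <- labeled_founders(panel, rp$ped$id[is.na(rp$ped$father)])
  gs <- gene_drop(rp$ped, founders, mode = "independent", seed = seed + 1)
  ja <- match(pair_ids[1], gs$samples); jb <- match(pair_ids[2], gs$samples)
  sh <- shared_ibd(gs$A1[, ja], gs$A2[, ja], gs$A1[, jb], gs$A2[, jb])
  c(phi2 = mean(sh == 2), phi1 = mean(sh == 1), phi0 = mean(sh == 0))
}

write_map_file <- function(rows, header = TRUE) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(if (header) "chrom\tpos\tcM", rows), f)
  f
}

# deterministic two-chromosome map: exactly 1 cM per Mb (cm = pos / 1e6)
toy_map <- function() {
  f <- write_map_file(c("1\t1000000\t1", "1\t201000000\t201",
                        "2\t1000000\t1", "2\t201000000\t201"))
  read_genetic_map(f)
}

write_panel_file <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

toy_panel_df <- function() {
  data.frame(snp_id = paste0("rs", 1:5), chrom = "1",
             pos = c(1e6, 10e6, 25e6, 40e6, 70e6),
             ref = "A", alt = "G",
             P1 = c(0.45, 0.30, 0.41, 0.44, 0.50),
             stringsAsFactors = FALSE, check.names = FALSE)
}

write_profile_file <- function(prof) {
  f <- tempfile(fileext = ".tsv")
  names(prof)[names(prof) %in% c("a1", "a2")] <- c("allele1", "allele2")
  utils::write.table(prof, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# random frequency vector over k alleles, strictly positive, sums to 1
random_freqs <- function(k) {
  p <- stats::runif(k, 0.05, 1)
  p <- p / sum(p)
  stats::setNames(p, NTS[seq_len(k)])
}
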