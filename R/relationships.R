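#' Built-in relationship hypotheses and their IBD coefficients
#'
#' Pairwise relationships are summarised by the Cotterman coefficients
#' (phi2, phi1, phi0): the probabilities that the pair shares 2, 1 or 0
#' alleles identical by descent at an autosomal locus.  The built-in set:
#'
#' | relationship      | phi2 | phi1 | phi0 |
#' |-------------------|------|------|------|
#' | identical_twins   | 1    | 0    | 0    |
#' | parent_child      | 0    | 1    | 0    |
#' | full_sibs         | 1/4  | 1/2  | 1/4  |
#' | second_degree     | 0    | 1/2  | 1/2  |
#' | first_cousins     | 0    | 1/4  | 3/4  |
#' | unrelated         | 0    | 0    | 1    |
#'
#' `second_degree` carries the half-sibling coefficients, which are shared
#' by all second-degree relationships (half sibs, avuncular,
#' grandparent-grandchild).
#'
#' @param name optional relationship name; if given, returns that row's
#'   coefficients as a named numeric vector `c(phi2, phi1, phi0)`.
#' @return With no argument, a data frame of all built-in hypotheses.
#' @examples
#' ibd_coefficients("full_sibs")
#' @export
ibd_coefficients <- function(name = NULL) {
  tab <- data.frame(
    relationship = c("identical_twins", "parent_child", "full_sibs",
                     "second_degree", "first_cousins", "unrelated"),
    phi2 = c(1, 0, 0.25, 0, 0, 0),
    phi1 = c(0, 1, 0.5, 0.5, 0.25, 0),
    phi0 = c(0, 0, 0.25, 0.5, 0.75, 1),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) return(tab)
  i <- match(name, tab$relationship)
  if (is.na(i)) stop("unknown relationship: ", name)
  c(phi2 = tab$phi2[i], phi1 = tab$phi1[i], phi0 = tab$phi0[i])
}

#' Default hypothesis set for pairwise classification
#'
#' The four relationships tested by default, in the fixed order used for
#' deterministic tie-breaking: unrelated, parent-child, full sibs,
#' second degree.
#'
#' @return Character vector of relationship names.
#' @export
kinship_hypotheses <- function() {
  c("unrelated", "parent_child", "full_sibs", "second_degree")
}

#' Canonicalize an unordered diploid genotype
#'
#' Genotypes are stored as two-character strings with alleles sorted, so
#' `"AG"` and `"GA"` are the same genotype.  `NA` (or any non-ACGT allele)
#' yields the missing genotype `NA`.
#'
#' @param a1,a2 single-character alleles.
#' @return Character scalar such as `"AG"`, or `NA_character_`.
#' @export
genotype <- function(a1, a2) {
  nts <- c("A", "C", "G", "T")
  a1 <- toupper(a1); a2 <- toupper(a2)
  out <- ifelse(is.na(a1) | is.na(a2) | !(a1 %in% nts) | !(a2 %in% nts),
                NA_character_,
                paste0(pmin(a1, a2), pmax(a1, a2)))
  out
}

geno_alleles <- function(g) {
  if (is.na(g) || nchar(g) != 2) stop("invalid or missing genotype: ", g)
  c(substr(g, 1, 1), substr(g, 2, 2))
}
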