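## Per-locus kinship likelihoods.
##
## The joint probability of two unordered single-locus genotypes X, Y given
## an IBD state k is computed from three primitives that reproduce, allele
## count by allele count, the classical joint genotype probability table:
##   IBD = 0:  Pr = HWE(X) * HWE(Y)
##   IBD = 2:  Pr = HWE(X) * 1[X == Y]
##   IBD = 1:  Pr = HWE(X) * T(X -> Y)
## where HWE() is the Hardy-Weinberg genotype probability and T(X -> Y) is
## the probability that Y arises by transmitting one allele of X (each with
## weight 1/2) and drawing the other from the population.  T generalises to
## a mutation model by letting the transmitted allele substitute to each of
## the three other nucleotides with probability mu/3.

p_lookup <- function(allele, freqs) {
  p <- freqs[allele]
  if (anyNA(p)) stop("allele ", paste(allele[is.na(p)], collapse = ","),
                     " has no frequency in the supplied table")
  as.numeric(p)
}

hwe_prob <- function(g, freqs) {
  a <- geno_alleles(g)
  p <- p_lookup(a, freqs)
  if (a[1] == a[2]) p[1]^2 else 2 * p[1] * p[2]
}

# Pr(Y | transmitted allele a + population allele), with per-transmission
# substitution rate mu (mu = 0 gives the exact-transmission kernel).
trans_prob <- function(a, y, freqs, mu = 0) {
  b <- geno_alleles(y)
  m <- function(to) if (a == to) 1 - mu else mu / 3
  p <- p_lookup(b, freqs)
  if (b[1] == b[2]) m(b[1]) * p[1] else m(b[1]) * p[2] + m(b[2]) * p[1]
}

#' Joint probability of two genotypes given an IBD state
#'
#' The probability of observing the unordered genotype pair (X, Y) at one
#' locus given that the pair shares exactly `ibd` alleles identical by
#' descent, under Hardy-Weinberg proportions at the supplied allele
#' frequencies.  Symmetric in (X, Y); supports loci with up to four
#' alleles.
#'
#' @param x,y genotypes as canonical two-character strings (see
#'   [genotype()]); missing genotypes are a contract violation -- callers
#'   must skip them.
#' @param ibd IBD state, 0, 1 or 2.
#' @param freqs named numeric vector of allele frequencies (names are
#'   nucleotides); every allele of `x` and `y` must be present.
#' @return A probability.
#' @examples
#' joint_prob_ibd("AA", "AA", 2, c(A = 0.5, G = 0.5))  # p^2 = 0.25
#' @export
joint_prob_ibd <- function(x, y, ibd, freqs) {
  if (is.na(x) || is.na(y)) stop("missing genotype passed to joint_prob_ibd()")
  if (!ibd %in% 0:2) stop("ibd must be 0, 1 or 2")
  hx <- hwe_prob(x, freqs)
  if (ibd == 0) return(hx * hwe_prob(y, freqs))
  if (ibd == 2) return(hx * as.numeric(x == y))
  ax <- geno_alleles(x)
  hx * mean(c(trans_prob(ax[1], y, freqs), trans_prob(ax[2], y, freqs)))
}

#' Parent-child likelihood with a transmission mutation model
#'
#' The likelihood of an unordered genotype pair under the parent-child
#' hypothesis: the parent's Hardy-Weinberg genotype probability times the
#' transmission probability from parent to child, where the transmitted
#' allele substitutes to each of the three other nucleotides with
#' probability `mu/3` (transitions and transversions treated as equally
#' probable).  Because the direction of the relationship is unknown in a
#' pairwise comparison, the two parent/child assignments are averaged with
#' equal weight; at `mu = 0` the two directions coincide and the result
#' equals [joint_prob_ibd()] with `ibd = 1`.
#'
#' With `mu > 0`, genotype pairs that are Mendelian-impossible for
#' parent-child (opposite homozygotes) receive a small positive likelihood
#' instead of excluding the hypothesis outright.
#'
#' @inheritParams joint_prob_ibd
#' @param mu per-transmission substitution rate (mutation plus genotyping
#'   error); default `1e-3`.
#' @return A probability.
#' @export
parent_child_likelihood <- function(x, y, freqs, mu = 1e-3) {
  if (is.na(x) || is.na(y)) stop("missing genotype passed to parent_child_likelihood()")
  if (mu < 0 || mu >= 1) stop("mu must be in [0, 1)")
  ax <- geno_alleles(x); ay <- geno_alleles(y)
  t_xy <- mean(c(trans_prob(ax[1], y, freqs, mu), trans_prob(ax[2], y, freqs, mu)))
  t_yx <- mean(c(trans_prob(ay[1], x, freqs, mu), trans_prob(ay[2], x, freqs, mu)))
  0.5 * (hwe_prob(x, freqs) * t_xy + hwe_prob(y, freqs) * t_yx)
}

#' Single-locus likelihood under a relationship hypothesis
#'
#' Mixes the IBD-conditional joint genotype probabilities with the
#' hypothesis's IBD coefficients:
#' `sum_k phi_k * Pr(X, Y | IBD = k)`.
#' For the parent-child hypothesis the IBD = 1 term is replaced by the
#' mutation-model likelihood of [parent_child_likelihood()], so that
#' opposite homozygotes do not zero out the hypothesis.
#'
#' If `genotyping_error > 0`, observed genotypes are additionally treated
#' as noisy reads of underlying true genotypes: the likelihood sums over
#' all true genotype pairs formed from alleles with positive frequency,
#' weighting by the per-allele substitution channel (each allele
#' mis-called with probability `genotyping_error`, uniformly over the
#' three other nucleotides).  This applies the error model to every
#' hypothesis and is off (0) by default, matching the convention that the
#' mutation/error rate enters only the parent-child transmission.
#'
#' @inheritParams parent_child_likelihood
#' @param rel relationship name (see [ibd_coefficients()]).
#' @param genotyping_error per-allele observation error rate applied to
#'   all hypotheses; default 0 (off).
#' @return A probability.
#' @export
locus_likelihood <- function(x, y, rel, freqs, mu = 1e-3,
                             genotyping_error = 0) {
  if (is.na(x) || is.na(y)) stop("missing genotype passed to locus_likelihood()")
  phi <- ibd_coefficients(rel)
  if (genotyping_error > 0) {
    return(locus_likelihood_err(x, y, rel, freqs, mu, genotyping_error))
  }
  base_locus_lik(x, y, rel, phi, freqs, mu)
}

base_locus_lik <- function(x, y, rel, phi, freqs, mu) {
  p2 <- if (phi["phi2"] > 0) joint_prob_ibd(x, y, 2, freqs) else 0
  p0 <- if (phi["phi0"] > 0) joint_prob_ibd(x, y, 0, freqs) else 0
  p1 <- if (phi["phi1"] > 0) {
    if (rel == "parent_child") parent_child_likelihood(x, y, freqs, mu)
    else joint_prob_ibd(x, y, 1, freqs)
  } else 0
  as.numeric(phi["phi2"] * p2 + phi["phi1"] * p1 + phi["phi0"] * p0)
}

# error-integrated likelihood: sum over true genotypes on the panel alleles
locus_likelihood_err <- function(x, y, rel, freqs, mu, err) {
  phi <- ibd_coefficients(rel)
  alleles <- names(freqs)[freqs > 0]
  m <- function(from, to) ifelse(from == to, 1 - err, err / 3)
  obs_prob <- function(obs, true) {
    o <- geno_alleles(obs); t <- geno_alleles(true)
    if (o[1] == o[2]) m(t[1], o[1]) * m(t[2], o[1])
    else m(t[1], o[1]) * m(t[2], o[2]) + m(t[1], o[2]) * m(t[2], o[1])
  }
  gts <- unique(unlist(lapply(seq_along(alleles), function(i)
    lapply(i:length(alleles), function(j) genotype(alleles[i], alleles[j])))))
  tot <- 0
  for (tx in gts) for (ty in gts) {
    w <- obs_prob(x, tx) * obs_prob(y, ty)
    if (w > 0) tot <- tot + w * base_locus_lik(tx, ty, rel, phi, freqs, mu)
  }
  tot
}

## ---- vectorised engine over panel loci (biallelic ref/alt records) ------

# per-locus likelihood for one hypothesis, vectorised over loci.
# a1,a2,b1,b2: observed alleles (canonical order within each genotype);
# ref, alt, p_alt: panel columns aligned with the loci.
locus_lik_engine <- function(a1, a2, b1, b2, ref, alt, p_alt,
                             rel, mu, err = 0) {
  phi <- ibd_coefficients(rel)
  pf <- function(a) ifelse(a == alt, p_alt, ifelse(a == ref, 1 - p_alt, 0))
  base <- function(a1, a2, b1, b2) {
    pa1 <- pf(a1); pa2 <- pf(a2); pb1 <- pf(b1); pb2 <- pf(b2)
    hx <- ifelse(a1 == a2, pa1^2, 2 * pa1 * pa2)
    hy <- ifelse(b1 == b2, pb1^2, 2 * pb1 * pb2)
    kv <- function(a, c1, c2, pc1, pc2)
      ifelse(c1 == c2, (a == c1) * pc1, (a == c1) * pc2 + (a == c2) * pc1)
    tmu <- function(a, c1, c2, pc1, pc2) {
      mm <- function(to) ifelse(a == to, 1 - mu, mu / 3)
      ifelse(c1 == c2, mm(c1) * pc1, mm(c1) * pc2 + mm(c2) * pc1)
    }
    p1 <- if (phi["phi1"] > 0) {
      if (rel == "parent_child") {
        0.5 * (hx * 0.5 * (tmu(a1, b1, b2, pb1, pb2) + tmu(a2, b1, b2, pb1, pb2)) +
               hy * 0.5 * (tmu(b1, a1, a2, pa1, pa2) + tmu(b2, a1, a2, pa1, pa2)))
      } else {
        hx * 0.5 * (kv(a1, b1, b2, pb1, pb2) + kv(a2, b1, b2, pb1, pb2))
      }
    } else 0
    p2 <- if (phi["phi2"] > 0) hx * as.numeric(a1 == b1 & a2 == b2) else 0
    p0 <- if (phi["phi0"] > 0) hx * hy else 0
    phi["phi2"] * p2 + phi["phi1"] * p1 + phi["phi0"] * p0
  }
  if (err <= 0) return(as.numeric(base(a1, a2, b1, b2)))
  # integrate the per-allele observation channel over true genotypes
  # (ref/ref, ref/alt, alt/alt at each locus)
  mch <- function(from, to) ifelse(from == to, 1 - err, err / 3)
  obsp <- function(o1, o2, t1, t2)
    ifelse(o1 == o2, mch(t1, o1) * mch(t2, o1),
           mch(t1, o1) * mch(t2, o2) + mch(t1, o2) * mch(t2, o1))
  truth <- list(c(1L, 1L), c(1L, 2L), c(2L, 2L))  # 1 = ref, 2 = alt
  pick <- function(sel) if (sel == 1L) ref else alt
  tot <- 0
  for (tx in truth) for (ty in truth) {
    ta1 <- pick(tx[1]); ta2 <- pick(tx[2])
    tb1 <- pick(ty[1]); tb2 <- pick(ty[2])
    w <- obsp(a1, a2, ta1, ta2) * obsp(b1, b2, tb1, tb2)
    tot <- tot + w * base(ta1, ta2, tb1, tb2)
  }
  as.numeric(tot)
}

# align two profiles with a panel; returns aligned allele/frequency vectors
# and the usable-locus mask (both genotypes called; alleles on the panel's
# frequency support unless the observation-error channel is active).
align_pair <- function(a, b, panel, err = 0) {
  ia <- match(panel$snp_id, a$snp_id)
  ib <- match(panel$snp_id, b$snp_id)
  a1 <- a$a1[ia]; a2 <- a$a2[ia]
  b1 <- b$a1[ib]; b2 <- b$a2[ib]
  called <- !(is.na(a1) | is.na(a2) | is.na(b1) | is.na(b2))
  usable <- called
  if (err <= 0) {
    onpanel <- (a1 == panel$ref | a1 == panel$alt) &
      (a2 == panel$ref | a2 == panel$alt) &
      (b1 == panel$ref | b1 == panel$alt) &
      (b2 == panel$ref | b2 == panel$alt)
    usable <- called & !is.na(onpanel) & onpanel
  }
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, usable = usable)
}

#' Cumulative log-likelihood over a marker panel
#'
#' Sums natural-log per-locus likelihoods over the panel markers at which
#' both samples have called genotypes, assuming independence of the
#' (MGD-thinned) markers.  Loci at which either sample carries an allele
#' outside the panel's frequency support are skipped in the same way as
#' missing genotypes (they would force a zero likelihood under every
#' hypothesis), unless `genotyping_error > 0`, in which case the
#' observation channel accounts for them.  The skipped count is reported
#' via `n_loci`.
#'
#' @param a,b genotype profiles: data frames with columns `snp_id`, `a1`,
#'   `a2` (see [read_profile()]).
#' @param panel an `snp_panel`, normally the output of [select_snps()].
#' @param rel relationship hypothesis name.
#' @param pop population label selecting the panel frequency column.
#' @param mu parent-child mutation/error rate.
#' @param genotyping_error observation error rate applied to all
#'   hypotheses (0 = off).
#' @return A list with `loglik` (natural log) and `n_loci` (markers used).
#' @export
cumulative_loglik <- function(a, b, panel, rel, pop, mu = 1e-3,
                              genotyping_error = 0) {
  if (!pop %in% panel_populations(panel))
    stop("population ", pop, " not present in panel")
  al <- align_pair(a, b, panel, err = genotyping_error)
  if (!any(al$usable))
    stop("no overlapping markers between the two profiles on this panel")
  u <- al$usable
  lik <- locus_lik_engine(al$a1[u], al$a2[u], al$b1[u], al$b2[u],
                          panel$ref[u], panel$alt[u], panel[[pop]][u],
                          rel, mu, genotyping_error)
  list(loglik = sum(log(lik)), n_loci = sum(u))
}

#' Log10 likelihood ratio between two relationship hypotheses
#'
#' Computes `log10 [ Pr(data | relA) / Pr(data | relB) ]` over the
#' identical set of usable markers.
#'
#' @inheritParams cumulative_loglik
#' @param relA,relB the two relationship hypotheses being compared.
#' @return A list with `log10_lr` and `n_loci`.
#' @export
pair_lr <- function(a, b, panel, relA, relB, pop, mu = 1e-3,
                    genotyping_error = 0) {
  la <- cumulative_loglik(a, b, panel, relA, pop, mu, genotyping_error)
  lb <- cumulative_loglik(a, b, panel, relB, pop, mu, genotyping_error)
  list(log10_lr = (la$loglik - lb$loglik) / log(10), n_loci = la$n_loci)
}

#' Classify a pair by maximum likelihood over a hypothesis set
#'
#' Computes the cumulative log-likelihood under each hypothesis and calls
#' the relationship with the maximum likelihood.  The margin is the ratio
#' of the maximum to the second-maximum likelihood, reported as log10.
#' Exact ties are resolved by the fixed order of `hypotheses` and flagged.
#'
#' @inheritParams cumulative_loglik
#' @param hypotheses character vector (>= 2) of relationship names, in the
#'   fixed tie-break order.
#' @return A list with `call`, `margin_log10`, `tie`, `logliks` (named,
#'   natural log) and `n_loci`.
#' @export
classify_pair <- function(a, b, panel, pop, mu = 1e-3, genotyping_error = 0,
                          hypotheses = kinship_hypotheses()) {
  if (length(hypotheses) < 2) stop("need at least two hypotheses")
  ll <- vapply(hypotheses, function(h)
    cumulative_loglik(a, b, panel, h, pop, mu, genotyping_error)$loglik,
    numeric(1))
  n <- cumulative_loglik(a, b, panel, hypotheses[1], pop, mu,
                         genotyping_error)$n_loci
  best <- which.max(ll)
  second <- max(ll[-best])
  list(call = hypotheses[best],
       margin_log10 = unname(ll[best] - second) / log(10),
       tie = any(ll[-best] == ll[best]),
       logliks = ll, n_loci = n)
}
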