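#' Classify every labeled pair of a simulated study
#'
#' Vectorised maximum-likelihood classification of all pairs in a
#' [simulate_study()] result: for each pair, cumulative log-likelihoods
#' over the panel markers under each hypothesis, the argmax call, and the
#' log10 margin between the best and second-best hypothesis.  Loci with a
#' missing genotype, or carrying an allele outside the panel's frequency
#' support (possible after error injection) are skipped pairwise, exactly
#' as in [cumulative_loglik()].
#'
#' @param study a `kin_study`.
#' @param panel marker panel to use; defaults to the study's panel, but a
#'   [select_snps()] subset of it may be supplied.
#' @param mu parent-child mutation/error rate used in the likelihoods.
#' @param genotyping_error observation-error rate applied to all
#'   hypotheses (0 = off).
#' @param hypotheses hypothesis set in fixed tie-break order.
#' @return A data frame with one row per labeled pair: `id_a`, `id_b`,
#'   `relationship` (truth), `predicted`, `margin_log10`, `n_loci`, and
#'   one `loglik_<hypothesis>` column per hypothesis (natural log).
#' @export
classify_study <- function(study, panel = study$panel, mu = 1e-3,
                           genotyping_error = 0,
                           hypotheses = kinship_hypotheses()) {
  stopifnot(inherits(study, "kin_study"))
  gs <- study$genotypes
  li <- match(panel$snp_id, gs$snp_id)
  if (anyNA(li)) stop("panel contains markers absent from the study genotypes")
  pairs <- study$pairs
  P <- nrow(pairs); L <- length(li)
  ia <- match(pairs$id_a, gs$samples)
  ib <- match(pairs$id_b, gs$samples)
  if (anyNA(ia) || anyNA(ib)) stop("pair manifest refers to unknown samples")
  # flatten to locus-major vectors of length L * P
  a1 <- as.vector(gs$A1[li, ia, drop = FALSE])
  a2 <- as.vector(gs$A2[li, ia, drop = FALSE])
  b1 <- as.vector(gs$A1[li, ib, drop = FALSE])
  b2 <- as.vector(gs$A2[li, ib, drop = FALSE])
  # canonical within-genotype allele order
  ca1 <- pmin(a1, a2); ca2 <- pmax(a1, a2)
  cb1 <- pmin(b1, b2); cb2 <- pmax(b1, b2)
  ref <- rep(panel$ref, P); alt <- rep(panel$alt, P)
  p_alt <- rep(panel[[study$pop]], P)
  usable <- !(is.na(ca1) | is.na(cb1))
  if (genotyping_error <= 0) {
    usable <- usable &
      (ca1 == ref | ca1 == alt) & (ca2 == ref | ca2 == alt) &
      (cb1 == ref | cb1 == alt) & (cb2 == ref | cb2 == alt)
    usable[is.na(usable)] <- FALSE
  }
  grp <- rep(seq_len(P), each = L)
  n_loci <- tabulate(grp[usable], nbins = P)
  ll <- matrix(0, P, length(hypotheses), dimnames = list(NULL, hypotheses))
  for (h in hypotheses) {
    lik <- locus_lik_engine(ca1[usable], ca2[usable], cb1[usable],
                            cb2[usable], ref[usable], alt[usable],
                            p_alt[usable], h, mu, genotyping_error)
    rs <- rowsum(log(lik), grp[usable])
    ll[as.integer(rownames(rs)), h] <- rs[, 1]
  }
  best <- max.col(ll, ties.method = "first")
  idx <- cbind(seq_len(P), best)
  mx <- ll[idx]
  ll2 <- ll; ll2[idx] <- -Inf
  second <- apply(ll2, 1, max)
  out <- data.frame(pairs, predicted = hypotheses[best],
                    margin_log10 = (mx - second) / log(10),
                    n_loci = n_loci, stringsAsFactors = FALSE)
  out$predicted[n_loci == 0] <- NA_character_
  colnames(ll) <- paste0("loglik_", hypotheses)
  cbind(out, as.data.frame(ll))
}

#' Score relationship calls against truth
#'
#' Builds the confusion matrix (rows = true relationship, columns =
#' predicted) and classification metrics: overall accuracy, per-class
#' one-vs-rest precision/recall/F1, and the support-weighted mean F1
#' (classes with zero support are excluded from the weighted mean).
#'
#' @param calls data frame with columns `id_a`, `id_b`, `predicted` (a
#'   [classify_study()] result works directly).
#' @param truth data frame with columns `id_a`, `id_b`, `relationship`.
#'   If `calls` already carries a `relationship` column it is used and
#'   `truth` may be omitted.
#' @param classes class order for the confusion matrix; defaults to
#'   [kinship_hypotheses()] extended with any further observed labels.
#' @return A list of class `kin_score`: `confusion` (table), `accuracy`,
#'   `weighted_f1`, `per_class` (data frame), `n`.
#' @export
score_calls <- function(calls, truth = NULL, classes = NULL) {
  if (is.null(truth)) {
    if (!"relationship" %in% names(calls))
      stop("no truth labels: supply `truth` or a `relationship` column")
    merged <- calls
  } else {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    i <- match(key(calls$id_a, calls$id_b), key(truth$id_a, truth$id_b))
    if (anyNA(i)) stop(sum(is.na(i)), " called pair(s) have no truth label")
    merged <- calls
    merged$relationship <- truth$relationship[i]
  }
  if (anyNA(merged$predicted)) stop("calls contain NA predictions")
  if (is.null(classes)) {
    classes <- union(intersect(kinship_hypotheses(),
                               c(merged$relationship, merged$predicted)),
                     union(merged$relationship, merged$predicted))
  }
  cm <- table(true = factor(merged$relationship, levels = classes),
              predicted = factor(merged$predicted, levels = classes))
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), NA_real_)
  rec <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), 0)
  pos <- support > 0
  wf1 <- sum(support[pos] * f1[pos]) / sum(support[pos])
  per_class <- data.frame(class = classes, support = as.integer(support),
                          precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1),
                          stringsAsFactors = FALSE)
  structure(list(confusion = cm, accuracy = acc, weighted_f1 = wf1,
                 per_class = per_class, n = n),
            class = "kin_score")
}

#' @export
print.kin_score <- function(x, ...) {
  cat("Relationship classification over", x$n, "pairs\n")
  cat(sprintf("  accuracy %.4f, weighted F1 %.4f\n", x$accuracy,
              x$weighted_f1))
  print(x$confusion)
  invisible(x)
}

#' Margin distribution summary
#'
#' For each threshold `t`, the fraction of pairs whose max/second-max
#' likelihood ratio is below `t`, reported for three groups: pairs whose
#' true relationship is first degree (parent-child or full sibs), pairs
#' whose true relationship is unrelated or second degree, and incorrectly
#' called pairs.  Small margins flag calls that additional markers could
#' overturn.
#'
#' @param results a [classify_study()] result (needs `relationship`,
#'   `predicted`, `margin_log10`).
#' @param thresholds likelihood-ratio thresholds (raw ratios, e.g.
#'   `c(10, 100)`).
#' @return Data frame with columns `group`, `threshold`, `n`,
#'   `fraction_below`.
#' @export
margin_summary <- function(results, thresholds = c(10, 100)) {
  stopifnot(all(thresholds > 0))
  groups <- list(
    first_degree = results$relationship %in% c("parent_child", "full_sibs"),
    unrelated_or_second = results$relationship %in%
      c("unrelated", "second_degree"),
    incorrect = results$predicted != results$relationship
  )
  out <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    for (t in thresholds) {
      frac <- if (any(sel))
        mean(results$margin_log10[sel] < log10(t)) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        group = g, threshold = t, n = sum(sel), fraction_below = frac,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Parameter sweep over selection and error settings
#'
#' Runs the full pipeline over a grid of MAF thresholds, MGD spacings and
#' genotyping error rates: simulate a study per error rate (one study per
#' error rate, shared across all selection settings and likelihood error
#' rates so comparisons are on the same genotypes), select markers per
#' (MAF, MGD) cell, classify, and score.  By default the likelihood
#' mutation/error rate is matched to the simulation error rate; supplying
#' `mu_rates` crosses each simulation error rate with each likelihood
#' rate, which exposes the cost of a mismatched error model.
#'
#' @param panel candidate `snp_panel` (before selection).
#' @param maf_grid,mgd_grid numeric grids for [select_snps()].
#' @param error_rates per-allele simulation error rates.
#' @param mu_rates likelihood error rates; `NULL` = matched to
#'   `error_rates`.
#' @param n_families families per study.
#' @param pop population label.
#' @param mode transmission mode for [gene_drop()].
#' @param seed integer seed; each error rate derives its study seed from
#'   it, so the whole sweep is reproducible.
#' @return Data frame with one row per grid cell: `error_rate`, `mu`,
#'   `maf_min`, `mgd_cm`, `n_snps`, `accuracy`, `weighted_f1`.
#' @export
sweep_study <- function(panel, maf_grid, mgd_grid, error_rates = 0.001,
                        mu_rates = NULL, n_families = 10, pop,
                        mode = "independent", seed = NULL) {
  stopifnot(length(maf_grid) >= 1, length(mgd_grid) >= 1,
            length(error_rates) >= 1)
  with_seed(seed, {
    study_seeds <- sample.int(.Machine$integer.max, length(error_rates))
    out <- list()
    for (e in seq_along(error_rates)) {
      study <- simulate_study(n_families, panel, pop,
                              error_rate = error_rates[e], mode = mode,
                              seed = study_seeds[e])
      mus <- if (is.null(mu_rates)) error_rates[e] else mu_rates
      for (maf in maf_grid) for (mgd in mgd_grid) {
        sel <- suppressWarnings(select_snps(panel, maf, mgd, pop))
        for (mu in mus) {
          row <- data.frame(error_rate = error_rates[e], mu = mu,
                            maf_min = maf, mgd_cm = mgd,
                            n_snps = nrow(sel), accuracy = NA_real_,
                            weighted_f1 = NA_real_)
          if (nrow(sel) > 0) {
            res <- classify_study(study, panel = sel, mu = mu)
            sc <- score_calls(res)
            row$accuracy <- sc$accuracy
            row$weighted_f1 <- sc$weighted_f1
          }
          out[[length(out) + 1]] <- row
        }
      }
    }
    do.call(rbind, out)
  })
}
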