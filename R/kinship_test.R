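#' Likelihood-ratio kinship test for a pair of genotype profiles
#'
#' Fits the pairwise kinship model: for each requested population, the
#' cumulative log-likelihood of the two profiles is computed over the
#' panel markers under each relationship hypothesis, assuming marker
#' independence (the panel should be the output of [select_snps()]).  The
#' relationship call in each population is the hypothesis with the maximum
#' likelihood; the margin is the ratio of the maximum to the second
#' maximum likelihood (log10).  Likelihood ratios versus the unrelated
#' hypothesis are reported when `"unrelated"` is in the hypothesis set.
#'
#' @param a,b genotype profiles (data frames with columns `snp_id`, `a1`,
#'   `a2`; see [read_profile()]).
#' @param panel an `snp_panel` of selected markers.
#' @param populations populations to evaluate; default all panel
#'   populations.
#' @param hypotheses relationship hypotheses, in fixed tie-break order.
#' @param mu parent-child mutation/genotyping-error rate.
#' @param genotyping_error observation error rate applied to all
#'   hypotheses (0 = off; see [locus_likelihood()]).
#' @return An object of class `kinship_test` with components:
#'   `loglik` (population x hypothesis matrix of natural-log cumulative
#'   likelihoods), `calls` (data frame with call, log10 margin, log10 LR
#'   versus unrelated, loci used, tie flag, per population), `per_marker`
#'   (long data frame of per-locus likelihoods), and the configuration.
#' @seealso [write_results()] for the two-file output,
#'   [classify_pair()] for the bare call.
#' @export
kinship_test <- function(a, b, panel, populations = panel_populations(panel),
                         hypotheses = kinship_hypotheses(), mu = 1e-3,
                         genotyping_error = 0) {
  stopifnot(inherits(panel, "snp_panel"))
  if (length(hypotheses) < 2) stop("need at least two hypotheses")
  bad <- setdiff(populations, panel_populations(panel))
  if (length(bad)) stop("unknown population label(s): ",
                        paste(bad, collapse = ", "))
  al <- align_pair(a, b, panel, err = genotyping_error)
  if (!any(al$usable))
    stop("no overlapping markers between the two profiles on this panel")
  u <- al$usable
  n_loci <- sum(u)
  loglik <- matrix(NA_real_, length(populations), length(hypotheses),
                   dimnames = list(populations, hypotheses))
  per_marker <- vector("list", length(populations))
  names(per_marker) <- populations
  for (pop in populations) {
    liks <- vapply(hypotheses, function(h)
      locus_lik_engine(al$a1[u], al$a2[u], al$b1[u], al$b2[u],
                       panel$ref[u], panel$alt[u], panel[[pop]][u],
                       h, mu, genotyping_error),
      numeric(n_loci))
    liks <- matrix(liks, nrow = n_loci,
                   dimnames = list(NULL, hypotheses))
    loglik[pop, ] <- colSums(log(liks))
    pm <- data.frame(snp_id = panel$snp_id[u], chrom = panel$chrom[u],
                     pos = panel$pos[u], population = pop,
                     genotype_a = genotype(al$a1[u], al$a2[u]),
                     genotype_b = genotype(al$b1[u], al$b2[u]),
                     stringsAsFactors = FALSE)
    per_marker[[pop]] <- cbind(pm, as.data.frame(liks))
  }
  calls <- data.frame(population = populations, call = NA_character_,
                      margin_log10 = NA_real_, log10_lr_unrelated = NA_real_,
                      n_loci = n_loci, tie = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(populations)) {
    ll <- loglik[i, ]
    best <- which.max(ll)
    calls$call[i] <- hypotheses[best]
    calls$margin_log10[i] <- (ll[best] - max(ll[-best])) / log(10)
    calls$tie[i] <- any(ll[-best] == ll[best])
    if ("unrelated" %in% hypotheses)
      calls$log10_lr_unrelated[i] <- (ll[best] - ll["unrelated"]) / log(10)
  }
  structure(list(loglik = loglik, calls = calls,
                 per_marker = do.call(rbind, per_marker),
                 hypotheses = hypotheses, populations = populations,
                 mu = mu, genotyping_error = genotyping_error,
                 n_loci = n_loci),
            class = "kinship_test")
}

#' @export
print.kinship_test <- function(x, ...) {
  cat("Pairwise kinship likelihood-ratio test\n")
  cat("  markers used:", x$n_loci,
      "  mu:", format(x$mu),
      if (x$genotyping_error > 0)
        paste0("  genotyping error: ", format(x$genotyping_error)) else "",
      "\n")
  for (i in seq_len(nrow(x$calls))) {
    cl <- x$calls[i, ]
    cat(sprintf("  %s: %s (log10 margin %.2f, log10 LR vs unrelated %.2f)\n",
                cl$population, cl$call, cl$margin_log10,
                cl$log10_lr_unrelated))
  }
  invisible(x)
}

#' @export
summary.kinship_test <- function(object, ...) {
  out <- list(calls = object$calls,
              log10_loglik = object$loglik / log(10),
              hypotheses = object$hypotheses)
  class(out) <- "summary.kinship_test"
  out
}

#' @export
print.summary.kinship_test <- function(x, ...) {
  cat("Cumulative log10 likelihoods (population x hypothesis):\n")
  print(round(x$log10_loglik, 3))
  cat("\nCalls:\n")
  print(x$calls, row.names = FALSE)
  invisible(x)
}

#' @describeIn kinship_test cumulative log10 likelihood matrix
#'   (population x hypothesis).
#' @param object,... method arguments.
#' @export
coef.kinship_test <- function(object, ...) object$loglik / log(10)

#' @export
plot.kinship_test <- function(x, population = x$populations[1], ...) {
  ll <- x$loglik[population, ] / log(10)
  rel <- ll - max(ll)
  graphics::barplot(rel, ylab = "log10 likelihood (relative to maximum)",
                    main = paste("Relationship support,", population),
                    las = 2, ...)
  invisible(x)
}
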