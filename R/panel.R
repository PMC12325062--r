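#' Read a candidate SNP frequency panel
#'
#' Reads a tab-separated panel with a header row and columns `snp_id`,
#' `chrom`, `pos`, `ref`, `alt`, followed by one column per population
#' giving the ALT-allele frequency in that population.  Each record is
#' annotated with its genetic position (cM) via [bp_to_cm()]; records on
#' chromosomes absent from the map are dropped with a warning.  Records
#' with any frequency outside the open interval (0, 1) are monomorphic or
#' malformed and are rejected, with the count reported.  Duplicate SNP ids
#' are an error.
#'
#' @param path path to the panel file.
#' @param map a `genetic_map` used to fill genetic positions.
#' @return A data frame of class `snp_panel`, sorted by (chrom, pos), with
#'   columns `snp_id`, `chrom`, `pos`, `cm`, `ref`, `alt` and one numeric
#'   column per population; attribute `populations` lists those columns.
#' @export
read_panel <- function(path, map) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("panel file lacks column(s): ",
                         paste(miss, collapse = ", "))
  pops <- setdiff(names(d), need)
  if (!length(pops)) stop("panel file has no population frequency column")
  make_panel(d[["snp_id"]], d[["chrom"]], d[["pos"]], d[["ref"]], d[["alt"]],
             d[pops], map = map)
}

# shared constructor + validation for panels built from files or in code
make_panel <- function(snp_id, chrom, pos, ref, alt, freqs, map = NULL,
                       cm = NULL) {
  chrom <- normalize_chrom(chrom)
  pos <- as.numeric(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (anyDuplicated(snp_id)) {
    stop("duplicate snp_id in panel: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  }
  if (any(!ref %in% c("A", "C", "G", "T")) || any(!alt %in% c("A", "C", "G", "T")))
    stop("panel alleles must be A/C/G/T")
  if (any(ref == alt)) stop("panel records with ref == alt")
  freqs <- as.data.frame(freqs)
  for (p in names(freqs)) freqs[[p]] <- as.numeric(freqs[[p]])
  ok <- rowSums(is.na(freqs) | freqs <= 0 | freqs >= 1) == 0
  if (any(!ok)) {
    message("rejected ", sum(!ok),
            " panel record(s) with allele frequency outside (0, 1)")
  }
  panel <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                      cm = NA_real_, ref = ref, alt = alt,
                      stringsAsFactors = FALSE, check.names = FALSE)
  panel <- cbind(panel, freqs)
  panel <- panel[ok, , drop = FALSE]
  if (!is.null(map)) {
    mapped <- panel$chrom %in% names(map$knots)
    if (any(!mapped)) {
      warning("dropping ", sum(!mapped),
              " panel record(s) on chromosome(s) absent from the genetic map: ",
              paste(unique(panel$chrom[!mapped]), collapse = ", "))
      panel <- panel[mapped, , drop = FALSE]
    }
    for (ch in unique(panel$chrom)) {
      idx <- panel$chrom == ch
      panel$cm[idx] <- bp_to_cm(map, ch, panel$pos[idx])
    }
  } else if (!is.null(cm)) {
    panel$cm <- as.numeric(cm)[ok]
  } else {
    stop("either a genetic map or explicit cm positions are required")
  }
  panel <- panel[order(suppressWarnings(as.integer(panel$chrom)),
                       panel$chrom, panel$pos, panel$snp_id), , drop = FALSE]
  rownames(panel) <- NULL
  structure(panel, populations = names(freqs),
            class = c("snp_panel", "data.frame"))
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("SNP panel: ", nrow(x), " marker(s) on ",
      length(unique(x$chrom)), " chromosome(s); populations: ",
      paste(attr(x, "populations"), collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Population labels carried by a panel
#' @param panel an `snp_panel`.
#' @return Character vector of population column names.
#' @export
panel_populations <- function(panel) attr(panel, "populations")

# keep class/attributes through row subsetting inside the package
panel_rows <- function(panel, idx) {
  out <- as.data.frame(panel)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, populations = attr(panel, "populations"),
            class = c("snp_panel", "data.frame"))
}

#' Filter panel markers by minor allele frequency
#'
#' Retains exactly the markers whose minor allele frequency,
#' `min(f, 1 - f)` of the ALT frequency `f`, is strictly greater than
#' `maf_min` in every requested population.  High-MAF markers are the most
#' informative for kinship: heterozygosity (and hence the expected
#' log-likelihood-ratio contribution per locus) is maximal at MAF 0.5.
#'
#' @param panel an `snp_panel`.
#' @param maf_min MAF threshold in (0, 0.5); strict inequality is applied.
#' @param populations populations that must all pass; default all panel
#'   populations.
#' @return The retained rows, original order preserved.
#' @export
filter_by_maf <- function(panel, maf_min, populations = panel_populations(panel)) {
  stopifnot(is.numeric(maf_min), length(maf_min) == 1)
  if (maf_min <= 0 || maf_min >= 0.5) stop("maf_min must be in (0, 0.5)")
  bad <- setdiff(populations, panel_populations(panel))
  if (length(bad)) stop("unknown population label(s): ",
                        paste(bad, collapse = ", "))
  keep <- rep(TRUE, nrow(panel))
  for (p in populations) {
    f <- panel[[p]]
    keep <- keep & (pmin(f, 1 - f) > maf_min)
  }
  panel_rows(panel, keep)
}

#' Greedy minimum-genetic-distance marker thinning
#'
#' Sweeps each chromosome once from its lowest genetic position inward,
#' selecting the first marker and then every subsequent marker lying at
#' least `mgd_cm` centimorgans beyond the last selected one.  On an ordered
#' line this greedy sweep attains the maximum possible number of markers
#' subject to the spacing constraint, which is what matters when all
#' candidates have similarly high MAF.  Chromosomes are swept
#' independently.  Ties in cM are broken by lower bp, then by snp_id, so
#' the selection is deterministic.
#'
#' @param panel an `snp_panel` (normally already MAF-filtered).
#' @param mgd_cm minimum genetic distance between consecutively selected
#'   markers, in cM; must be > 0.
#' @return The selected rows.
#' @export
select_mgd <- function(panel, mgd_cm) {
  stopifnot(is.numeric(mgd_cm), length(mgd_cm) == 1)
  if (mgd_cm <= 0) stop("mgd_cm must be > 0")
  if (!nrow(panel)) return(panel_rows(panel, logical(0)))
  ord <- order(suppressWarnings(as.integer(panel$chrom)), panel$chrom,
               panel$cm, panel$pos, panel$snp_id)
  keep <- logical(nrow(panel))
  for (idx in split(ord, panel$chrom[ord])) {
    last <- -Inf
    for (i in idx) {
      if (panel$cm[i] >= last + mgd_cm || !is.finite(last)) {
        keep[i] <- TRUE
        last <- panel$cm[i]
      }
    }
  }
  panel_rows(panel, keep)
}

#' Dynamic case-specific marker selection
#'
#' The two-stage dynamic selection: [filter_by_maf()] followed by
#' [select_mgd()].  The result is the case-specific marker set over which
#' cumulative likelihoods are computed; because the retained markers are
#' spaced by at least `mgd_cm` (typically 30 cM or more), per-locus
#' likelihoods may be multiplied as approximately independent.
#'
#' @inheritParams filter_by_maf
#' @inheritParams select_mgd
#' @return The selected `snp_panel` rows.
#' @examples
#' gm_file <- tempfile(); panel_file <- tempfile()
#' writeLines(c("1\t1\t0", "1\t100000000\t100"), gm_file)
#' gm <- read_genetic_map(gm_file)
#' writeLines(c("snp_id\tchrom\tpos\tref\talt\tPOP",
#'              "rs1\t1\t1000000\tA\tG\t0.45",
#'              "rs2\t1\t40000000\tA\tC\t0.42"), panel_file)
#' p <- read_panel(panel_file, gm)
#' select_snps(p, maf_min = 0.4, mgd_cm = 30)
#' @export
select_snps <- function(panel, maf_min, mgd_cm,
                        populations = panel_populations(panel)) {
  out <- select_mgd(filter_by_maf(panel, maf_min, populations), mgd_cm)
  if (!nrow(out)) warning("dynamic selection returned an empty marker set")
  out
}

#' Generate a synthetic biallelic SNP panel
#'
#' Builds an in-silico candidate panel for simulation studies: `n` biallelic
#' markers with minor allele frequencies drawn uniformly from `maf_range`
#' (the ALT allele is the minor or major allele with equal probability),
#' placed round-robin across autosomes 1..22 at a fixed genetic spacing so
#' that, at the default 35 cM, consecutive markers on a chromosome are
#' effectively unlinked.  All populations share the same frequencies unless
#' `perturb_sd > 0`, in which case per-population frequencies are jittered
#' on the logit scale.
#'
#' @param n number of markers.
#' @param maf_range length-2 numeric range for the minor allele frequency.
#' @param populations character vector of population labels.
#' @param spacing_cm genetic distance between consecutive markers placed on
#'   the same chromosome.
#' @param n_chrom number of chromosomes to spread markers over.
#' @param perturb_sd logit-scale standard deviation of per-population
#'   frequency jitter (0 = identical across populations).
#' @param seed optional integer seed; the global RNG state is restored.
#' @return An `snp_panel` with `cm` filled (1 cM taken as 1 Mb for the
#'   synthetic physical coordinates).
#' @export
synthetic_panel <- function(n, maf_range = c(0.4, 0.5), populations = "SIM",
                            spacing_cm = 35, n_chrom = 22, perturb_sd = 0,
                            seed = NULL) {
  stopifnot(n >= 1, length(maf_range) == 2, all(maf_range > 0),
            all(maf_range <= 0.5), spacing_cm > 0)
  with_seed(seed, {
    chrom <- as.character(rep_len(seq_len(n_chrom), n))
    idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
    cm <- (idx - 1) * spacing_cm
    pos <- round(cm * 1e6) + 1e6
    nts <- c("A", "C", "G", "T")
    ref <- sample(nts, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
    maf <- stats::runif(n, maf_range[1], maf_range[2])
    f_alt <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)
    freqs <- as.data.frame(stats::setNames(
      lapply(populations, function(p) {
        if (perturb_sd > 0) {
          stats::plogis(stats::qlogis(f_alt) + stats::rnorm(n, 0, perturb_sd))
        } else f_alt
      }), populations), check.names = FALSE)
    make_panel(sprintf("snp%04d", seq_len(n)), chrom, pos, ref, alt,
               freqs, cm = cm)
  })
}
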