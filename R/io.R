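## File formats: tab-separated genotype profiles, VCF input, and the
## two-file results output (per-population summary + per-marker detail).

user_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("snpkin_user_error",
                                             "error", "condition")))
}

#' Read a genotype profile
#'
#' Reads one sample's genotypes either from a tab-separated table with
#' header columns `snp_id`, `chrom`, `pos`, `allele1`, `allele2`, or from
#' a VCF (4.x, `GT` field).  Genotypes are canonicalized to unordered
#' allele pairs; half calls and non-ACGT alleles become missing.  For a
#' multi-sample VCF the `sample` argument is required.  If a `panel` is
#' supplied, only markers present in the panel are retained; VCF records
#' are matched by (chrom, pos) with the panel's ref/alt pair in either
#' orientation (swapped records are accepted and counted in a message).
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`; default guesses from the extension.
#' @param sample sample id (VCF only; required when multi-sample).
#' @param panel optional `snp_panel` to restrict and align markers.
#' @return A `genotype_profile` data frame: `snp_id`, `chrom`, `pos`,
#'   `a1`, `a2` (NA alleles = missing genotype).
#' @export
read_profile <- function(path, format = c("auto", "tsv", "vcf"),
                         sample = NULL, panel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) user_error("profile file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  prof <- if (format == "vcf") read_profile_vcf(path, sample)
          else read_profile_tsv(path)
  if (!is.null(panel)) prof <- restrict_to_panel(prof, panel)
  prof
}

read_profile_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "allele1", "allele2")
  miss <- setdiff(need, names(d))
  if (length(miss)) user_error("profile file lacks column(s): ",
                               paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.numeric(d$pos))
  if (anyNA(pos)) {
    user_error("unparseable position at data line ",
               which(is.na(pos))[1], " of ", path)
  }
  g1 <- toupper(as.character(d$allele1))
  g2 <- toupper(as.character(d$allele2))
  nts <- c("A", "C", "G", "T")
  bad <- !(g1 %in% nts) | !(g2 %in% nts)
  g1[bad] <- NA_character_; g2[bad] <- NA_character_
  structure(data.frame(snp_id = as.character(d$snp_id),
                       chrom = normalize_chrom(d$chrom), pos = pos,
                       a1 = pmin(g1, g2), a2 = pmax(g1, g2),
                       stringsAsFactors = FALSE),
            class = c("genotype_profile", "data.frame"))
}

read_profile_vcf <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || !ncol(gt)) user_error("VCF has no genotype columns: ", path)
  if (is.null(sample)) {
    if (ncol(gt) > 1)
      user_error("multi-sample VCF: a sample id must be given (",
                 paste(colnames(gt), collapse = ", "), ")")
    sample <- colnames(gt)[1]
  }
  if (!sample %in% colnames(gt))
    user_error("sample ", sample, " not present in ", path)
  calls <- gt[, sample]
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  alleles <- lapply(seq_along(ref), function(i)
    c(ref[i], strsplit(alt[i], ",", fixed = TRUE)[[1]]))
  decode <- function(call, al) {
    if (is.na(call)) return(c(NA_character_, NA_character_))
    idx <- strsplit(call, "[/|]")[[1]]
    if (length(idx) != 2 || any(idx == ".")) return(c(NA, NA))
    i <- as.integer(idx) + 1L
    if (anyNA(i) || any(i > length(al))) return(c(NA, NA))
    a <- al[i]
    if (!all(a %in% c("A", "C", "G", "T"))) return(c(NA, NA))
    a
  }
  g <- t(mapply(decode, calls, alleles))
  id <- fix[, "ID"]
  pos <- as.numeric(fix[, "POS"])
  chrom <- normalize_chrom(fix[, "CHROM"])
  id <- ifelse(is.na(id) | id == ".", paste0(chrom, ":", pos), id)
  a1 <- g[, 1]; a2 <- g[, 2]
  structure(data.frame(snp_id = as.character(id), chrom = chrom, pos = pos,
                       a1 = pmin(a1, a2), a2 = pmax(a1, a2),
                       ref = ref, alt = alt, stringsAsFactors = FALSE),
            class = c("genotype_profile", "data.frame"))
}

restrict_to_panel <- function(prof, panel) {
  key <- paste(prof$chrom, prof$pos)
  pkey <- paste(panel$chrom, panel$pos)
  i <- match(key, pkey)
  keep <- !is.na(i)
  if (all(c("ref", "alt") %in% names(prof))) {
    # record-level allele check against the panel, either orientation
    straight <- prof$ref == panel$ref[i] & prof$alt == panel$alt[i]
    swapped <- prof$ref == panel$alt[i] & prof$alt == panel$ref[i]
    ok <- !is.na(straight) & (straight | swapped)
    if (any(swapped & keep, na.rm = TRUE))
      message(sum(swapped & keep, na.rm = TRUE),
              " record(s) matched the panel with ref/alt swapped")
    keep <- keep & ok
  }
  out <- prof[keep, setdiff(names(prof), c("ref", "alt")), drop = FALSE]
  out$snp_id <- panel$snp_id[i[keep]]   # align ids to the panel
  rownames(out) <- NULL
  structure(out, class = c("genotype_profile", "data.frame"))
}

fmt12 <- function(x) formatC(x, digits = 12, format = "g")

#' Write kinship test results to the two-file output
#'
#' Writes a summary table (one row per population and hypothesis:
#' cumulative log10 likelihood, log10 LR versus unrelated, the called
#' relationship, margin and loci used) and a per-marker table (one row
#' per marker and population with the per-locus likelihood under each
#' hypothesis).  Numeric values are written with 12 significant digits so
#' the files round-trip losslessly for downstream re-analysis.
#'
#' @param fit a [kinship_test()] result.
#' @param prefix output path prefix; files `<prefix>_summary.tsv` and
#'   `<prefix>_markers.tsv` are created.
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(fit, prefix) {
  stopifnot(inherits(fit, "kinship_test"))
  sum_path <- paste0(prefix, "_summary.tsv")
  mark_path <- paste0(prefix, "_markers.tsv")
  rows <- list()
  for (pop in fit$populations) {
    cl <- fit$calls[fit$calls$population == pop, ]
    for (h in fit$hypotheses) {
      rows[[length(rows) + 1]] <- data.frame(
        population = pop, hypothesis = h,
        log10_loglik = fmt12(fit$loglik[pop, h] / log(10)),
        log10_lr_vs_unrelated = fmt12(
          if ("unrelated" %in% fit$hypotheses)
            (fit$loglik[pop, h] - fit$loglik[pop, "unrelated"]) / log(10)
          else NA_real_),
        call = cl$call, margin_log10 = fmt12(cl$margin_log10),
        n_loci = cl$n_loci, stringsAsFactors = FALSE)
    }
  }
  summary_df <- do.call(rbind, rows)
  utils::write.table(summary_df, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pm <- fit$per_marker
  for (h in fit$hypotheses) pm[[h]] <- fmt12(pm[[h]])
  utils::write.table(pm, mark_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(summary = sum_path, markers = mark_path))
}

#' Write a simulated study to disk
#'
#' Writes each sample's genotype table (the tab-separated profile format
#' of [read_profile()]) into `dir`, plus the labeled-pair manifest
#' `pairs.tsv` (`id_a`, `id_b`, `relationship`) and the panel as
#' `panel.tsv`.
#'
#' @param study a `kin_study`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "kin_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in study$genotypes$samples) {
    p <- study_profile(study, id)
    names(p) <- c("snp_id", "chrom", "pos", "allele1", "allele2")
    utils::write.table(p, file.path(dir, paste0(id, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(study$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pan <- as.data.frame(study$panel)
  utils::write.table(pan, file.path(dir, "panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
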