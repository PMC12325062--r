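#' Read a sex-averaged genetic map
#'
#' Reads a whitespace- or tab-delimited genetic map with one row per knot:
#' chromosome, physical position (bp) and cumulative genetic position (cM)
#' from the chromosome start.  A header row is detected automatically.
#' Chromosome names are normalised (`"chr1"` and `"1"` are equivalent);
#' only autosomes are kept -- X/Y/MT rows are dropped with a warning, as
#' kinship likelihoods here use autosomal sex-averaged maps only.
#'
#' Within each chromosome physical positions must be strictly increasing and
#' genetic positions non-decreasing; violations are an error naming the
#' chromosome.  Chromosomes with fewer than two knots cannot support
#' interpolation and are dropped with a warning.
#'
#' @param path path to the map file.
#' @param build genome build tag the positions refer to, `"GRCh38"` or
#'   `"GRCh37"`.  Stored on the object; no lift-over is performed.
#' @return An object of class `genetic_map`: a list with elements `knots`
#'   (named list of data frames with columns `bp`, `cm`) and `build`.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr\tpos\tcM", "1\t1000000\t0.0", "1\t2000000\t2.5"), f)
#' gm <- read_genetic_map(f)
#' bp_to_cm(gm, "1", 1500000)
#' @export
read_genetic_map <- function(path, build = c("GRCh38", "GRCh37")) {
  build <- match.arg(build)
  if (!file.exists(path)) stop("map file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("map file is empty: ", path)
  fields <- strsplit(trimws(lines), "[\t ]+")
  # header auto-detection: first row whose 2nd/3rd fields are non-numeric
  first <- fields[[1]]
  start <- 1L
  if (length(first) >= 3 &&
      (is.na(suppressWarnings(as.numeric(first[2]))) ||
       is.na(suppressWarnings(as.numeric(first[3]))))) {
    start <- 2L
  }
  if (start > length(fields)) stop("map file has a header but no data rows")
  rows <- fields[start:length(fields)]
  nf <- lengths(rows)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1] + start - 1L
    stop("malformed map row (need >= 3 columns) at line ", bad)
  }
  chrom <- vapply(rows, `[`, character(1), 1L)
  bp <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 2L)))
  cm <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 3L)))
  if (anyNA(bp) || anyNA(cm)) {
    bad <- which(is.na(bp) | is.na(cm))[1] + start - 1L
    stop("malformed map row (non-numeric position) at line ", bad)
  }
  chrom <- normalize_chrom(chrom)
  auto <- chrom %in% as.character(1:22)
  if (any(!auto)) {
    warning("dropping ", sum(!auto), " non-autosomal map row(s) (",
            paste(unique(chrom[!auto]), collapse = ", "), ")")
  }
  chrom <- chrom[auto]; bp <- bp[auto]; cm <- cm[auto]
  if (!length(chrom)) stop("no autosomal map rows found")
  knots <- lapply(split(data.frame(bp = bp, cm = cm), chrom), function(d) {
    d[order(d$bp), , drop = FALSE]
  })
  short <- names(knots)[vapply(knots, nrow, integer(1)) < 2]
  if (length(short)) {
    warning("dropping chromosome(s) with < 2 map knots: ",
            paste(short, collapse = ", "))
    knots <- knots[setdiff(names(knots), short)]
  }
  if (!length(knots)) stop("no chromosome has >= 2 map knots")
  for (ch in names(knots)) {
    k <- knots[[ch]]
    if (any(diff(k$bp) <= 0)) {
      stop("duplicate physical positions in genetic map on chromosome ", ch)
    }
    if (any(diff(k$cm) < 0)) {
      stop("genetic positions decrease along chromosome ", ch,
           ": map is not monotone")
    }
    if (any(k$cm < 0)) stop("negative cM values on chromosome ", ch)
  }
  # order chromosomes numerically for stable downstream output
  knots <- knots[as.character(sort(as.integer(names(knots))))]
  structure(list(knots = knots, build = build), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  nk <- vapply(x$knots, nrow, integer(1))
  cat("Genetic map (", x$build, "): ", length(x$knots),
      " chromosome(s), ", sum(nk), " knots\n", sep = "")
  invisible(x)
}

# "chr1" / "Chr1" / "1" -> "1"; "chrX" -> "X"; "M" -> "MT"
normalize_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  x <- toupper(x)
  x[x == "M"] <- "MT"
  x
}

#' Convert physical positions to genetic positions
#'
#' Maps base-pair positions to cumulative centimorgans using the map knots:
#' exact at knots, linear interpolation between flanking knots, and linear
#' extrapolation beyond the terminal knots using the terminal interval's
#' slope, floored at 0 cM.  The result is monotone non-decreasing in `bp`.
#'
#' @param map a `genetic_map` from [read_genetic_map()].
#' @param chrom chromosome identifier (with or without a `"chr"` prefix).
#' @param bp numeric vector of physical positions.
#' @return Numeric vector of genetic positions in cM.
#' @export
bp_to_cm <- function(map, chrom, bp) {
  stopifnot(inherits(map, "genetic_map"))
  ch <- normalize_chrom(chrom)
  if (length(ch) != 1) stop("bp_to_cm() takes a single chromosome")
  k <- map$knots[[ch]]
  if (is.null(k)) stop("chromosome ", ch, " not present in genetic map")
  n <- nrow(k)
  i <- findInterval(bp, k$bp)          # 0 = before first knot
  lo <- pmin(pmax(i, 1L), n - 1L)      # lower knot of the bracketing/terminal interval
  hi <- lo + 1L
  slope <- (k$cm[hi] - k$cm[lo]) / (k$bp[hi] - k$bp[lo])
  pmax(0, k$cm[lo] + (bp - k$bp[lo]) * slope)
}

#' Genetic distance between two physical positions on one chromosome
#'
#' @inheritParams bp_to_cm
#' @param bp1,bp2 physical positions.
#' @return `abs(bp_to_cm(bp1) - bp_to_cm(bp2))`, in cM.
#' @export
genetic_distance <- function(map, chrom, bp1, bp2) {
  abs(bp_to_cm(map, chrom, bp1) - bp_to_cm(map, chrom, bp2))
}
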