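#' GWAS summary statistics
#'
#' A `sumstats` object holds one trait's per-variant marginal association
#' estimates: identifier, chromosome, 1-based position, effect/other allele,
#' effect-allele frequency, beta (log-odds per allele for binary traits, SD
#' units per allele for quantitative traits), standard error, p-value and
#' sample size, plus trait name and type.
#'
#' @name sumstats
NULL

#' Construct and validate a summary-statistics object
#'
#' Rows violating hard invariants (non-positive SE, alleles outside ACGT,
#' allele frequency outside (0,1), p-value outside (0,1], duplicated
#' identifier, missing mandatory values) are dropped with a warning giving
#' the count. A p-value inconsistent with `|beta/se|` under the normal
#' approximation by more than two orders of magnitude triggers a validation
#' warning but the row is kept.
#'
#' @param data data.frame with columns `variant_id`, `chr`, `pos`, `ea`,
#'   `oa`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @param trait trait name.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @return a `sumstats` object.
#' @export
sumstats <- function(data, trait, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  req <- c("variant_id", "chr", "pos", "ea", "oa", "eaf", "beta", "se",
           "pvalue", "n")
  miss <- setdiff(req, names(data))
  if (length(miss)) abort("missing mandatory column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(data) == 0) abort("summary-statistics table is empty")
  d <- data[, req]
  d$variant_id <- as.character(d$variant_id)
  d$chr <- as.character(d$chr)
  d$ea <- toupper(as.character(d$ea)); d$oa <- toupper(as.character(d$oa))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    d[[col]] <- as.numeric(d[[col]])

  bad <- !stats::complete.cases(d) |
    d$se <= 0 |
    !(d$ea %in% c("A", "C", "G", "T")) | !(d$oa %in% c("A", "C", "G", "T")) |
    d$ea == d$oa |
    d$eaf <= 0 | d$eaf >= 1 |
    d$pvalue <= 0 | d$pvalue > 1 |
    duplicated(d$variant_id)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning(sprintf("dropped %d of %d rows failing summary-statistic invariants (trait %s)",
                    sum(bad), nrow(d), trait), call. = FALSE)
    d <- d[!bad, , drop = FALSE]
  }
  if (nrow(d) == 0) abort("no valid rows remain for trait %s", trait)

  z <- abs(d$beta / d$se)
  lp_expect <- log10(2) + stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
  incons <- abs(log10(d$pvalue) - lp_expect) > 2 & z > 1
  if (any(incons))
    warning(sprintf("%d row(s) have p-values inconsistent with |beta/se| by > 2 orders of magnitude (trait %s)",
                    sum(incons), trait), call. = FALSE)
  rownames(d) <- NULL
  structure(list(trait = trait, trait_type = trait_type, data = d),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s), %d variants\n",
              x$trait, x$trait_type, nrow(x$data)))
  invisible(x)
}

#' Default column mapping for summary-statistics files
#'
#' Maps the package's internal field names to the header names of the
#' tab-delimited dialect read and written by [read_sumstats()] /
#' [write_sumstats()].
#'
#' @return named character vector (internal name -> file header).
#' @export
default_col_map <- function() {
  c(variant_id = "SNP", chr = "CHR", pos = "POS", ea = "EA", oa = "NEA",
    eaf = "EAF", beta = "BETA", se = "SE", pvalue = "P", n = "N")
}

#' Read summary statistics from a tab-delimited file
#'
#' @param path file path.
#' @param trait trait name.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param col_map named character vector mapping internal names to file
#'   headers; see [default_col_map()].
#' @return a `sumstats` object.
#' @export
read_sumstats <- function(path, trait, trait_type = c("quantitative", "binary"),
                          col_map = default_col_map()) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) abort("summary-statistics file not found: %s", path)
  raw <- read_tsv_plain(path)
  if (nrow(raw) == 0) abort("summary-statistics file is empty: %s", path)
  miss <- setdiff(unname(col_map), names(raw))
  if (length(miss)) abort("file %s is missing mandatory column(s): %s",
                          path, paste(miss, collapse = ", "))
  d <- stats::setNames(raw[, unname(col_map)], names(col_map))
  sumstats(d, trait = trait, trait_type = trait_type)
}

#' Write summary statistics to a tab-delimited file
#'
#' @param stats a `sumstats` object.
#' @param path file path.
#' @param col_map see [default_col_map()].
#' @return the path, invisibly.
#' @export
write_sumstats <- function(stats, path, col_map = default_col_map()) {
  d <- stats$data
  names(d) <- unname(col_map[names(d)])
  write_tsv_exact(d, path)
}

#' Gene-region definitions
#'
#' Coordinates are 1-based and end-inclusive throughout, matching the
#' dominant GWAS summary-file convention (note: not BED half-open).
#'
#' @param name region label (e.g. a gene symbol).
#' @param chr chromosome.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param flank base pairs added to both sides (>= 0).
#' @return a `region` object.
#' @export
region <- function(name, chr, start, end, flank = 0) {
  if (start > end) abort("region %s has start > end", name)
  if (flank < 0) abort("region %s has negative flank", name)
  structure(list(name = name, chr = as.character(chr), start = start,
                 end = end, flank = flank), class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s chr%s:%s-%s (+/- %s bp)\n", x$name, x$chr,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$flank))
  invisible(x)
}

#' Read region definitions from a TSV
#'
#' Expects columns `NAME CHR START END` and optionally `FLANK`; coordinates
#' 1-based inclusive.
#'
#' @param path file path.
#' @return list of `region` objects, named by region name.
#' @export
read_regions <- function(path) {
  d <- read_tsv_plain(path)
  fl <- if ("FLANK" %in% names(d)) d$FLANK else rep(0, nrow(d))
  out <- lapply(seq_len(nrow(d)), function(i)
    region(d$NAME[i], d$CHR[i], d$START[i], d$END[i], fl[i]))
  stats::setNames(out, d$NAME)
}

region_contains <- function(reg, chr, pos) {
  chr == reg$chr & pos >= reg$start - reg$flank & pos <= reg$end + reg$flank
}

#' Restrict an object to a gene region
#'
#' Keeps variants with `start - flank <= position <= end + flank` on the
#' region's chromosome, preserving order. An empty result is permitted.
#'
#' @param x a `sumstats`, `harmonised_pair` or `ld_panel`.
#' @param reg a `region`.
#' @return object of the same class restricted to the region.
#' @export
extract_region <- function(x, reg) UseMethod("extract_region")

#' @export
extract_region.sumstats <- function(x, reg) {
  keep <- region_contains(reg, x$data$chr, x$data$pos)
  out <- x
  out$data <- x$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' @export
extract_region.ld_panel <- function(x, reg) {
  keep <- region_contains(reg, x$chr, x$positions)
  subset_panel(x, x$variant_ids[keep])
}
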