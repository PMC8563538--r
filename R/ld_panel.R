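#' LD reference panels
#'
#' An `ld_panel` holds a variant manifest (identifiers, chromosome, 1-based
#' positions, effect/other alleles, effect-allele frequencies) together with
#' the signed pairwise allelic correlation matrix `R` (r, not r-squared) used
#' for clumping, conditional colocalisation and summary-statistic simulation.
#'
#' @name ld_panel
NULL

new_ld_panel <- function(variant_ids, chr, positions, ea, oa, eaf, R,
                         block = NULL) {
  structure(
    list(variant_ids = as.character(variant_ids),
         chr = rep_len(as.character(chr), length(variant_ids)),
         positions = as.numeric(positions),
         ea = as.character(ea), oa = as.character(oa),
         eaf = as.numeric(eaf),
         R = R,
         block = if (is.null(block)) rep(NA_character_, length(variant_ids))
                 else as.character(block)),
    class = "ld_panel")
}

validate_ld_panel <- function(panel) {
  n <- length(panel$variant_ids)
  R <- panel$R
  if (!is.matrix(R) || nrow(R) != n || ncol(R) != n)
    abort("LD matrix dimension (%d x %d) does not match %d variants",
          nrow(R), ncol(R), n)
  if (anyDuplicated(panel$variant_ids))
    abort("duplicate variant identifiers in LD panel")
  if (max(abs(diag(R) - 1)) > 1e-12) abort("LD matrix diagonal must be 1")
  if (max(abs(R - t(R))) > 1e-12) abort("LD matrix must be symmetric")
  if (any(abs(R) > 1 + 1e-12)) abort("LD correlations must lie in [-1, 1]")
  if (any(panel$eaf <= 0 | panel$eaf >= 1)) abort("eaf must lie in (0, 1)")
  for (ch in unique(panel$chr)) {
    p <- panel$positions[panel$chr == ch]
    if (is.unsorted(p, strictly = TRUE))
      abort("positions must be strictly increasing within chromosome %s", ch)
  }
  invisible(panel)
}

#' Build an AR(1) LD reference panel
#'
#' Constructs a synthetic LD panel in which the allelic correlation between
#' variants i and j is `decay^|i - j|` (first-order autoregressive structure),
#' which is positive definite for any `decay` in `[0, 1)`. Allele frequencies
#' are drawn uniformly between `maf_low` and `maf_high`, alleles are random
#' distinct ACGT pairs, and positions increase strictly.
#'
#' @param n_variants number of variants (>= 1).
#' @param decay adjacent-variant correlation, in `[0, 1)`.
#' @param maf_low,maf_high effect-allele-frequency bounds, `0 < maf_low <=
#'   maf_high < 0.5`.
#' @param chr chromosome label for the manifest.
#' @param start first base-pair position (1-based).
#' @param seed integer seed (NULL uses the current RNG stream).
#' @param id_start integer from which rs-style identifiers are numbered.
#' @param block optional region label applied to every variant.
#' @return an `ld_panel`.
#' @examples
#' p <- make_ld_panel(10, decay = 0.8, seed = 1)
#' p$R[1, 3]  # 0.8^2
#' @export
make_ld_panel <- function(n_variants, decay = 0.8, maf_low = 0.05,
                          maf_high = 0.45, chr = "1", start = 1e6,
                          seed = NULL, id_start = 1L, block = NULL) {
  if (n_variants < 1) abort("n_variants must be >= 1")
  if (!is.finite(decay) || decay >= 1 || decay < 0)
    abort("decay must lie in [0, 1): the AR(1) correlation matrix is not positive definite otherwise")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high < 0.5))
    abort("require 0 < maf_low <= maf_high < 0.5")
  with_seed(seed, {
    idx <- seq_len(n_variants)
    R <- decay^abs(outer(idx, idx, "-"))
    eaf <- stats::runif(n_variants, maf_low, maf_high)
    bases <- c("A", "C", "G", "T")
    al <- vapply(idx, function(i) sample(bases, 2L), character(2))
    pos <- start + cumsum(c(0, sample(100:1000, n_variants - 1, replace = TRUE)))
    ids <- sprintf("rs%d", id_start + idx - 1L)
    validate_ld_panel(new_ld_panel(ids, chr, pos, al[1, ], al[2, ], eaf, R,
                                   block = rep(block %||% NA_character_,
                                               n_variants)))
  })
}

#' Concatenate LD panels into one block-diagonal panel
#'
#' Variants from different input panels are mutually uncorrelated (zero LD
#' between blocks); each block keeps (or receives) a region label so that
#' gene-exclusion filters can be exercised downstream.
#'
#' @param panels list of `ld_panel` objects with disjoint variant identifiers.
#' @param labels optional character vector of block labels, one per panel.
#' @return an `ld_panel`.
#' @export
bind_panels <- function(panels, labels = NULL) {
  stopifnot(length(panels) >= 1)
  if (!is.null(labels)) stopifnot(length(labels) == length(panels))
  sizes <- vapply(panels, function(p) length(p$variant_ids), integer(1))
  n <- sum(sizes)
  R <- matrix(0, n, n)
  off <- 0L
  for (p in panels) {
    k <- length(p$variant_ids)
    R[off + seq_len(k), off + seq_len(k)] <- p$R
    off <- off + k
  }
  blk <- unlist(lapply(seq_along(panels), function(i) {
    b <- panels[[i]]$block
    if (!is.null(labels)) rep(labels[i], sizes[i]) else b
  }))
  out <- new_ld_panel(
    unlist(lapply(panels, `[[`, "variant_ids")),
    unlist(lapply(panels, `[[`, "chr")),
    unlist(lapply(panels, `[[`, "positions")),
    unlist(lapply(panels, `[[`, "ea")),
    unlist(lapply(panels, `[[`, "oa")),
    unlist(lapply(panels, `[[`, "eaf")),
    R, block = blk)
  validate_ld_panel(out)
}

#' Subset an LD panel to a set of variants
#'
#' @param panel an `ld_panel`.
#' @param variant_ids identifiers to keep (panel order preserved).
#' @return an `ld_panel`.
#' @export
subset_panel <- function(panel, variant_ids) {
  keep <- which(panel$variant_ids %in% variant_ids)
  new_ld_panel(panel$variant_ids[keep], panel$chr[keep],
               panel$positions[keep], panel$ea[keep], panel$oa[keep],
               panel$eaf[keep], panel$R[keep, keep, drop = FALSE],
               block = panel$block[keep])
}

#' Squared LD between one variant and others
#'
#' @param panel an `ld_panel`.
#' @param id reference variant identifier.
#' @param ids identifiers to compare against (default: all panel variants).
#' @return named numeric vector of r-squared values.
#' @export
panel_r2 <- function(panel, id, ids = panel$variant_ids) {
  i <- match(id, panel$variant_ids)
  if (is.na(i)) abort("variant '%s' not found in LD panel", id)
  j <- match(ids, panel$variant_ids)
  if (anyNA(j)) abort("variant '%s' not found in LD panel", ids[which(is.na(j))[1]])
  stats::setNames(panel$R[i, j]^2, ids)
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d variants, chr %s, %d block(s)\n",
              length(x$variant_ids),
              paste(unique(x$chr), collapse = ","),
              length(unique(x$block[!is.na(x$block)])) + anyNA(x$block)))
  invisible(x)
}

#' Write / read an LD panel
#'
#' The manifest is a TSV (`SNP CHR POS EA NEA EAF BLOCK`) and the correlation
#' matrix a dense whitespace-delimited table in manifest order.
#'
#' @param panel an `ld_panel`.
#' @param manifest_path,matrix_path file paths.
#' @return `write_ld_panel` returns the manifest path invisibly;
#'   `read_ld_panel` returns an `ld_panel`.
#' @export
write_ld_panel <- function(panel, manifest_path, matrix_path) {
  man <- data.frame(SNP = panel$variant_ids, CHR = panel$chr,
                    POS = panel$positions, EA = panel$ea, NEA = panel$oa,
                    EAF = panel$eaf, BLOCK = panel$block)
  write_tsv_exact(man, manifest_path)
  utils::write.table(matrix(sprintf("%.17g", panel$R), nrow(panel$R)),
                     matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(manifest_path)
}

#' @rdname write_ld_panel
#' @export
read_ld_panel <- function(manifest_path, matrix_path) {
  man <- read_tsv_plain(manifest_path)
  R <- as.matrix(utils::read.table(matrix_path, header = FALSE, sep = "\t"))
  dimnames(R) <- NULL
  blk <- if ("BLOCK" %in% names(man)) as.character(man$BLOCK) else NULL
  validate_ld_panel(new_ld_panel(man$SNP, man$CHR, man$POS, man$EA, man$NEA,
                                 man$EAF, R, block = blk))
}
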