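# Internal numerical and plumbing helpers.

#' Numerically stable log(sum(exp(x)))
#'
#' @param x numeric vector (may contain -Inf).
#' @return scalar log-sum-exp.
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(1 - exp(a)) for a <= 0, accurate near both ends.
log1mexp <- function(a) {
  stopifnot(all(a <= 0))
  out <- numeric(length(a))
  small <- a > -log(2)
  out[small] <- log(-expm1(a[small]))
  out[!small] <- log1p(-exp(a[!small]))
  out
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so no function in the package mutates global random state.
#' A `NULL` seed evaluates the code under the current RNG stream.
#'
#' @param seed integer seed or NULL.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf-style formatting and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Write a data.frame as TSV with full double precision (%.17g) so that
# read-back reproduces every numeric bit. Used for all result tables.
write_tsv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}
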