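# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a named substream seed from a top-level seed. All randomness in
# the package flows from one integer seed through this map; the result is
# kept inside the 32-bit signed range.
#' @noRd
seed_for <- function(seed, stream) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  s <- (abs(as.numeric(seed)) %% m) * 48271 %% m
  out <- (s + h) %% m
  as.integer(max(1, out))
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Write a data.frame as TSV with a header row; the exchange format used
# by all report tables.
#' @export
#' @rdname write_tsv_table
#' @param x a data.frame.
#' @param path output file path.
#' @title Write a report table as tab-separated text
#' @description Writes a data.frame as UTF-8 TSV with a header row and no
#'   row names, the plain-text exchange format used for all fit and report
#'   tables in this package.
#' @return `path`, invisibly.
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
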