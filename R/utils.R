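# Internal helpers shared across the pipeline stages.

#' @keywords internal
ct_log <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

# Run `expr` under `seed` without clobbering the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# TSV dialect used for every table: tab separator, '.' decimal, no quoting.
#' @keywords internal
write_tsv_file <- function(x, path, row_names = FALSE) {
  utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

#' @keywords internal
read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
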