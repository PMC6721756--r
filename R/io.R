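#' Read a gene-by-sample count matrix from TSV
#'
#' The expected layout is a header row of sample identifiers, a first column
#' of gene identifiers, and non-negative integer counts in the body. Row and
#' column order are preserved.
#'
#' @param path Path to a tab-separated count file.
#' @return An integer matrix with gene identifiers as row names and sample
#'   identifiers as column names.
#' @seealso [write_counts()] for the inverse operation.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t0\t1", "g2\t2\t3"), tf)
#' read_counts(tf)
read_counts <- function(path) {
  df <- read_tsv_file(path)
  if (ncol(df) < 2L) {
    stop("count file must have a gene id column plus at least one sample")
  }
  gene_ids <- as.character(df[[1L]])
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "double"
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer or negative count for gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- gene_ids
  validate_counts(counts)
  counts
}

#' Write a count matrix as TSV
#'
#' @param counts Integer matrix with gene row names and sample column names.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' @keywords internal
validate_counts <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts))) {
    stop("counts must be a matrix with gene row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop(sprintf("duplicate gene id '%s' in count matrix", dup))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids in count matrix")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and complete")
  }
  invisible(counts)
}

.stimulation_levels <- c("NS", "IFNB_TNF")
.silencing_levels <- c("CTRL", "STAT2", "IRF9")

#' Read a sample sheet from TSV
#'
#' Columns: `sample_id`, `stimulation` (`NS` or `IFNB_TNF`), `silencing`
#' (`CTRL`, `STAT2` or `IRF9`) and `replicate` (positive integer).
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A data.frame with the four columns above.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_file(path)
  validate_sample_sheet(df)
}

#' Write a sample sheet as TSV
#'
#' @param sheet Sample sheet data.frame (see [read_sample_sheet()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  write_tsv_file(sheet, path)
}

#' Validate a sample sheet
#'
#' @param sheet A data.frame with columns `sample_id`, `stimulation`,
#'   `silencing`, `replicate`.
#' @return The validated sheet (character/integer columns), invisibly usable.
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "stimulation", "silencing", "replicate")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$stimulation <- as.character(sheet$stimulation)
  sheet$silencing <- as.character(sheet$silencing)
  if (anyDuplicated(sheet$sample_id)) {
    stop("sample ids must be unique")
  }
  bad_stim <- setdiff(unique(sheet$stimulation), .stimulation_levels)
  if (length(bad_stim) > 0L) {
    stop("unknown stimulation level(s): ", paste(bad_stim, collapse = ", "))
  }
  bad_sil <- setdiff(unique(sheet$silencing), .silencing_levels)
  if (length(bad_sil) > 0L) {
    stop("unknown silencing level(s): ", paste(bad_sil, collapse = ", "))
  }
  if (anyNA(sheet$replicate) || any(sheet$replicate < 1) ||
      any(sheet$replicate != round(sheet$replicate))) {
    stop("replicate must be a positive integer")
  }
  sheet$replicate <- as.integer(sheet$replicate)
  sheet[required]
}

#' Construct a module collection
#'
#' A module collection holds named gene sets (transcriptional modules) used
#' as the reference for over-representation analysis.
#'
#' @param genes Named list of character vectors; names are module ids.
#' @param titles Optional character vector of human-readable titles, one per
#'   module (recycled from ids when absent).
#' @return An object of class `module_collection`.
#' @export
module_collection <- function(genes, titles = NULL) {
  if (length(genes) > 0L &&
      (is.null(names(genes)) || anyDuplicated(names(genes)))) {
    stop("module ids must be present and unique")
  }
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (any(lengths(genes) == 0L)) {
    stop("module gene sets must be nonempty")
  }
  if (is.null(titles)) titles <- names(genes)
  titles <- stats::setNames(as.character(titles), names(genes))
  structure(list(genes = genes, titles = titles),
            class = "module_collection")
}

#' @export
print.module_collection <- function(x, ...) {
  cat(sprintf("module_collection: %d modules, %d distinct genes\n",
              length(x$genes), length(unique(unlist(x$genes)))))
  invisible(x)
}

#' @export
length.module_collection <- function(x) length(x$genes)

#' Read gene-set modules from a GMT file
#'
#' Standard GMT: one module per line, tab-separated fields
#' `id<TAB>title<TAB>gene1<TAB>gene2...`. Duplicate member genes within a
#' line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A [module_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(module_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields",
                 short[1L]))
  }
  ids <- vapply(fields, `[[`, "", 1L)
  titles <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(genes) <- ids
  module_collection(genes, titles)
}

#' Write a module collection to a GMT file
#'
#' @param modules A [module_collection()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(modules, path) {
  stopifnot(inherits(modules, "module_collection"))
  lines <- vapply(names(modules$genes), function(id) {
    paste(c(id, modules$titles[[id]], modules$genes[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
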