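# Hypergeometric over-representation of gene sets (modular transcription
# analysis) with Benjamini-Hochberg correction.

#' Hypergeometric gene-set over-representation
#'
#' For each module, counts the overlap `b` between the foreground and the
#' module (both intersected with the universe) and computes the upper-tail
#' hypergeometric probability of an overlap at least that large when `n`
#' foreground genes are drawn without replacement from the `N`-gene
#' universe containing `B` module genes:
#' `p = sum_{k >= b} C(B,k) C(N-B, n-k) / C(N,n)` (the observed overlap is
#' included). q-values are Benjamini-Hochberg over all modules tested in
#' the run.
#'
#' @param foreground Character vector of genes of interest (must be a
#'   subset of `universe`).
#' @param universe Character vector: the reference gene set (e.g. all genes
#'   passing the expression filter).
#' @param modules A [module_collection()].
#' @param min_module_size Modules with fewer than this many genes inside
#'   the universe are skipped.
#' @return A data.frame sorted by `p` with columns `module_id`, `title`,
#'   `b`, `n`, `B`, `N`, `ratio` (`(b/n)/(B/N)`), `p`, `q`.
#' @export
hypergeom_enrich <- function(foreground, universe, modules,
                             min_module_size = 3) {
  stopifnot(inherits(modules, "module_collection"))
  universe <- unique(as.character(universe))
  foreground <- unique(as.character(foreground))
  outside <- setdiff(foreground, universe)
  if (length(outside) > 0L) {
    stop("foreground genes outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "),
         if (length(outside) > 5L) ", ...")
  }
  in_universe <- lapply(modules$genes, intersect, universe)
  keep <- lengths(in_universe) >= min_module_size
  if (!any(keep)) {
    warning("no module meets the minimum size within the universe")
    return(data.frame(module_id = character(0), title = character(0),
                      b = integer(0), n = integer(0), B = integer(0),
                      N = integer(0), ratio = numeric(0),
                      p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE))
  }
  in_universe <- in_universe[keep]
  N <- length(universe)
  n <- length(foreground)
  B <- lengths(in_universe)
  b <- vapply(in_universe, function(g) length(intersect(g, foreground)),
              integer(1))
  # upper tail including the observed overlap: P[X >= b]
  p <- stats::phyper(b - 1L, m = B, n = N - B, k = n, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  ratio <- if (n > 0) (b / n) / (B / N) else rep(0, length(B))
  out <- data.frame(module_id = names(in_universe),
                    title = unname(modules$titles[names(in_universe)]),
                    b = unname(b), n = n, B = unname(B), N = N,
                    ratio = unname(ratio), p = unname(p),
                    q = bh_adjust(unname(p)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$module_id), , drop = FALSE]
}

#' Per-category module enrichment
#'
#' Runs [hypergeom_enrich()] once per nonempty regulation category, using
#' that category's genes as foreground, and flags significance at
#' `q < fdr` within each run.
#'
#' @param assignments A `category_assignment` (see [classify_genes()]).
#' @param modules A [module_collection()].
#' @param universe Reference gene set (e.g. all filtered genes).
#' @param fdr Significance threshold on the adjusted p.
#' @param min_module_size Passed to [hypergeom_enrich()].
#' @return A data.frame stacking the per-category tables with leading
#'   `category` and trailing `significant` columns; empty categories
#'   contribute no rows.
#' @export
per_category_enrichment <- function(assignments, modules, universe,
                                    fdr = 0.05, min_module_size = 3) {
  stopifnot(inherits(assignments, "category_assignment"))
  a <- assignments$assignments
  if (nrow(a) == 0L) {
    warning("no classified genes; enrichment skipped")
  }
  cats <- LETTERS[1:9][assignments$counts > 0]
  pieces <- lapply(cats, function(cc) {
    fg <- intersect(a$gene_id[a$category == cc], universe)
    if (length(fg) == 0L) return(NULL)
    tab <- suppressWarnings(
      hypergeom_enrich(fg, universe, modules, min_module_size))
    if (nrow(tab) == 0L) return(NULL)
    cbind(category = cc, tab, significant = tab$q < fdr,
          stringsAsFactors = FALSE)
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L) {
    return(data.frame(category = character(0), module_id = character(0),
                      title = character(0), b = integer(0), n = integer(0),
                      B = integer(0), N = integer(0), ratio = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
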