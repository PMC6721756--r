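# Classification of stimulation-induced genes into the nine regulation
# categories defined by their response to the two knockdowns.

# The 3x3 grid of (STAT2 call, IRF9 call) -> category. DOWN means the
# transcript drops when the factor is silenced (positive regulation by the
# factor); UP means it rises (negative regulation). The orientation of the
# two opposite-effect classes is a frozen convention:
# H = (DOWN, UP), I = (UP, DOWN).
.category_grid <- c(
  "DOWN.DOWN" = "A", "UP.UP" = "B", "NS.NS" = "C",
  "DOWN.NS" = "D", "UP.NS" = "E",
  "NS.DOWN" = "F", "NS.UP" = "G",
  "DOWN.UP" = "H", "UP.DOWN" = "I"
)

#' Regulation category from the two knockdown calls
#'
#' Maps the pair of differential-expression calls of a stimulation-induced
#' gene in the two knockdown contrasts to one of nine categories:
#' A = positively regulated by both factors (silencing either one drops the
#' transcript); B = negatively regulated by both; C = independent of both;
#' D/E = positively/negatively regulated by the first factor only;
#' F/G = positively/negatively regulated by the second factor only;
#' H/I = opposite effects of the two factors (H = first factor positive,
#' second negative; I = the mirror).
#'
#' @param stat2_call,irf9_call Character vectors over
#'   `c("DOWN", "UP", "NS")`: the gene's status in the siSTAT2 and siIRF9
#'   contrasts (test = knockdown, reference = control, both stimulated).
#' @return Character vector of categories `"A"`..`"I"`.
#' @export
#' @examples
#' assign_category("NS", "NS")    # "C"
#' assign_category("NS", "DOWN")  # "F"
assign_category <- function(stat2_call, irf9_call) {
  calls <- c("DOWN", "UP", "NS")
  stat2_call <- as.character(stat2_call)
  irf9_call <- as.character(irf9_call)
  bad <- !(stat2_call %in% calls) | !(irf9_call %in% calls)
  if (any(bad)) {
    stop("regulation calls must be one of DOWN, UP, NS")
  }
  unname(.category_grid[paste(stat2_call, irf9_call, sep = ".")])
}

#' Classify stimulation-induced genes by their knockdown response
#'
#' Restricts to genes called `UP` in the baseline (stimulated vs
#' unstimulated) contrast and assigns each its category from the two
#' knockdown contrasts via [assign_category()]. Genes missing from a
#' knockdown table (e.g. dropped by filtering there) are treated as `NS`
#' with a warning, so every induced gene receives exactly one category.
#'
#' @param baseline,stat2,irf9 `GeneTestResult` data.frames (with `status`)
#'   for the stimulation contrast and the two knockdown contrasts.
#' @return A list of class `category_assignment` with `assignments`
#'   (data.frame: `gene_id`, `stat2_call`, `irf9_call`, `category`) and
#'   `counts` (named integer vector over A..I, zero-filled).
#' @export
classify_genes <- function(baseline, stat2, irf9) {
  for (tab in list(baseline, stat2, irf9)) {
    stopifnot(is.data.frame(tab),
              all(c("gene_id", "status") %in% names(tab)))
  }
  up <- baseline$gene_id[baseline$status == "UP"]
  lookup_call <- function(tab, genes, label) {
    call <- as.character(tab$status[match(genes, tab$gene_id)])
    n_missing <- sum(is.na(call))
    if (n_missing > 0L) {
      warning(sprintf(
        "%d induced gene(s) absent from the %s contrast; treated as NS",
        n_missing, label))
      call[is.na(call)] <- "NS"
    }
    call
  }
  s2 <- lookup_call(stat2, up, "siSTAT2")
  i9 <- lookup_call(irf9, up, "siIRF9")
  assignments <- data.frame(
    gene_id = up,
    stat2_call = s2,
    irf9_call = i9,
    category = if (length(up) > 0L) assign_category(s2, i9) else character(0),
    stringsAsFactors = FALSE
  )
  counts <- table(factor(assignments$category, levels = LETTERS[1:9]))
  structure(list(assignments = assignments,
                 counts = stats::setNames(as.integer(counts), names(counts))),
            class = "category_assignment")
}

#' @export
print.category_assignment <- function(x, ...) {
  cat(sprintf("category_assignment: %d induced genes\n",
              nrow(x$assignments)))
  print(x$counts)
  invisible(x)
}
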