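#' Canonical label for a treatment comparison
#'
#' @param a,b Treatment labels.
#' @return `"A vs B"` with the two labels sorted lexicographically.
#' @export
comparison_label <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = " vs ")
}

#' Expand multi-arm studies into comparison-level observations
#'
#' Each study with \eqn{T_i} arms contributes \eqn{\binom{T_i}{2}} rows, one
#' per within-study treatment pair, all sharing the study's characteristic
#' values. This expansion is what allows each comparison of a multi-arm study
#' to be contrasted with every other study in the dissimilarity matrix.
#'
#' @param ds A [study_dataset()].
#' @return An object of class `comparison_table` with elements:
#'   * `study_id`, `comparison`: one entry per expanded row;
#'   * `values`: characteristic values per row (inherited from the study);
#'   * `comparisons`: data frame of the `P` distinct comparisons with their
#'     study counts `h`;
#'   * `specs`, `study_values`: carried over for range computation.
#' @export
expand_comparisons <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  rows <- do.call(rbind, lapply(seq_along(ds$study_id), function(i) {
    prs <- utils::combn(sort(ds$arms[[i]]), 2L)
    data.frame(study_id = ds$study_id[i],
               comparison = comparison_label(prs[1L, ], prs[2L, ]),
               study_row = i, stringsAsFactors = FALSE)
  }))
  cmp_tab <- as.data.frame(table(comparison = rows$comparison),
                           stringsAsFactors = FALSE)
  names(cmp_tab)[2L] <- "h"
  cmp_tab <- cmp_tab[order(cmp_tab$comparison), , drop = FALSE]
  rownames(cmp_tab) <- NULL
  if (nrow(cmp_tab) < 2L)
    stop("a network needs at least two observed comparisons", call. = FALSE)
  values <- ds$values[rows$study_row, , drop = FALSE]
  rownames(values) <- NULL
  structure(
    list(study_id = rows$study_id,
         comparison = rows$comparison,
         values = values,
         comparisons = cmp_tab,
         specs = ds$specs,
         study_values = ds$values),
    class = "comparison_table"
  )
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %d rows from %d studies, %d comparisons\n",
              length(x$study_id), length(unique(x$study_id)),
              nrow(x$comparisons)))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Row labels of an expanded comparison table
#'
#' @param ct A `comparison_table`.
#' @return Character vector `"study_id: comparison"`, used to label the
#'   dissimilarity matrix and dendrogram leaves.
#' @export
row_labels <- function(ct) {
  paste(ct$study_id, ct$comparison, sep = ": ")
}
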