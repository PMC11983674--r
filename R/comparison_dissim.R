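#' Root mean square of a set of Gower dissimilarities
#'
#' Population-style RMS with the mean replaced by zero: the spread of the
#' dissimilarities from 0 (complete similarity). Undefined (`NA`) values are
#' excluded; their count is attached as attribute `n_undefined`. All values
#' undefined yields `NA`.
#'
#' @param d Numeric vector of dissimilarities (may contain `NA`).
#' @return RMS value with attribute `n_undefined`.
#' @keywords internal
rms_dissim <- function(d) {
  und <- sum(is.na(d))
  d <- d[!is.na(d)]
  out <- if (!length(d)) NA_real_ else sqrt(sum(d^2) / length(d))
  attr(out, "n_undefined") <- und
  out
}

rows_of_comparison <- function(ct, p) {
  idx <- which(ct$comparison == p)
  if (!length(idx))
    stop("comparison '", p, "' not observed in the network", call. = FALSE)
  idx
}

#' Within-comparison dissimilarity
#'
#' The RMS of the \eqn{\binom{h}{2}} pairwise Gower dissimilarities among the
#' `h` studies informing comparison `p`; it quantifies the non-statistical
#' (clinical and methodological) heterogeneity of that comparison. A
#' single-study comparison has zero within-comparison dissimilarity.
#'
#' @param dm A [build_dissimilarity_matrix()] result.
#' @param ct The matching `comparison_table`.
#' @param p Comparison label (e.g., `"A vs B"`).
#' @return RMS dissimilarity in \[0,1\].
#' @export
within_comparison_dissimilarity <- function(dm, ct, p) {
  idx <- rows_of_comparison(ct, p)
  if (length(idx) == 1L) return(structure(0, n_undefined = 0L))
  prs <- utils::combn(idx, 2L)
  d <- dm$values[cbind(prs[1L, ], prs[2L, ])]
  d[!dm$defined[cbind(prs[1L, ], prs[2L, ])]] <- NA_real_
  rms_dissim(d)
}

#' Between-comparison dissimilarity
#'
#' The RMS of the \eqn{h \times h'} Gower dissimilarities between the studies
#' of comparison `p` and those of comparison `p2`. High values flag imbalances
#' in the distribution of the characteristics across the two comparisons,
#' i.e., potential intransitivity. Cross pairs formed by two comparisons of
#' the same multi-arm study contribute their (zero) dissimilarity; their
#' count is attached as attribute `n_same_study`.
#'
#' @inheritParams within_comparison_dissimilarity
#' @param p2 Second comparison label, different from `p`.
#' @return RMS dissimilarity in \[0,1\].
#' @export
between_comparison_dissimilarity <- function(dm, ct, p, p2) {
  if (identical(p, p2))
    stop("p and p2 must be different comparisons", call. = FALSE)
  i <- rows_of_comparison(ct, p)
  j <- rows_of_comparison(ct, p2)
  prs <- cbind(rep(i, times = length(j)), rep(j, each = length(i)))
  d <- dm$values[prs]
  d[!dm$defined[prs]] <- NA_real_
  out <- rms_dissim(d)
  attr(out, "n_same_study") <-
    sum(ct$study_id[prs[, 1L]] == ct$study_id[prs[, 2L]])
  out
}

#' Comparison-by-comparison dissimilarity matrix
#'
#' Assembles the symmetric \eqn{P \times P} matrix \eqn{\{D\}} with the
#' within-comparison dissimilarities on the diagonal and the
#' between-comparison dissimilarities off the diagonal. Unlike an ordinary
#' dissimilarity matrix, the diagonal is not zero (except for single-study
#' comparisons).
#'
#' @inheritParams within_comparison_dissimilarity
#' @return Object of class `comparison_dissim`: list with `comparisons`,
#'   `values` (P x P), `n_pairs` (backing pair counts per cell) and
#'   `n_undefined` (excluded undefined pairs per cell).
#' @export
build_comparison_matrix <- function(dm, ct) {
  cmp <- ct$comparisons$comparison
  P <- length(cmp)
  if (P < 2L) stop("need at least two observed comparisons", call. = FALSE)
  values <- matrix(NA_real_, P, P, dimnames = list(cmp, cmp))
  n_pairs <- matrix(0L, P, P, dimnames = list(cmp, cmp))
  n_undef <- matrix(0L, P, P, dimnames = list(cmp, cmp))
  for (a in seq_len(P)) {
    w <- within_comparison_dissimilarity(dm, ct, cmp[a])
    values[a, a] <- as.numeric(w)
    h <- ct$comparisons$h[a]
    n_pairs[a, a] <- choose(h, 2L)
    n_undef[a, a] <- attr(w, "n_undefined")
    if (a < P) for (b in seq((a + 1L), P)) {
      d <- between_comparison_dissimilarity(dm, ct, cmp[a], cmp[b])
      values[a, b] <- values[b, a] <- as.numeric(d)
      n_pairs[a, b] <- n_pairs[b, a] <-
        ct$comparisons$h[a] * ct$comparisons$h[b]
      n_undef[a, b] <- n_undef[b, a] <- attr(d, "n_undefined")
    }
  }
  structure(
    list(comparisons = cmp, values = values, n_pairs = n_pairs,
         n_undefined = n_undef),
    class = "comparison_dissim"
  )
}

#' @export
print.comparison_dissim <- function(x, digits = 2, ...) {
  cat(sprintf("<comparison_dissim> %d x %d within/between-comparison RMS dissimilarities\n",
              nrow(x$values), ncol(x$values)))
  print(round(x$values, digits))
  invisible(x)
}

# Table of "low" dissimilarity thresholds: medians (and 95% intervals) of
# empirically derived predictive distributions for the I2 statistic of a
# future meta-analysis, indexed by outcome type, treatment-comparator type
# and average study size, plus a single general-healthcare-setting entry.
threshold_table <- local({
  out <- c("all-cause mortality", "semi-objective", "subjective")
  cmpr <- c("pharm vs placebo/control", "pharm vs pharm", "non-pharmacological")
  size <- c("<50", "50-200", ">200")
  g <- expand.grid(outcome = out, comparator = cmpr, size_bucket = size,
                   stringsAsFactors = FALSE)
  med <- c(
    # size <50:          pvp,      pvph,     non-pharm   (by outcome rows)
    0.0007, 0.06, 0.25,  0.0004, 0.04, 0.16,  0.0007, 0.06, 0.24,
    # size 50-200
    0.0007, 0.06, 0.25,  0.0004, 0.04, 0.16,  0.0007, 0.06, 0.23,
    # size >200
    0.0008, 0.07, 0.28,  0.0005, 0.04, 0.18,  0.0007, 0.06, 0.26
  )
  lo <- c(
    1e-7, 8e-5, 0.006,  1e-7, 9e-5, 0.01,  1e-7, 6e-5, 0.003,
    1e-7, 8e-5, 0.005,  1e-7, 7e-5, 0.01,  1e-7, 5e-5, 0.003,
    1e-7, 1e-4, 0.0006, 1e-7, 9e-5, 0.01,  1e-7, 6e-5, 0.003
  )
  hi <- c(
    0.91, 0.97, 0.94,  0.76, 0.89, 0.80,  0.87, 0.98, 0.97,
    0.89, 0.97, 0.94,  0.74, 0.90, 0.79,  0.86, 0.98, 0.97,
    0.91, 0.97, 0.95,  0.75, 0.91, 0.82,  0.88, 0.98, 0.97
  )
  g$median <- med; g$lo <- lo; g$hi <- hi
  rbind(g, data.frame(outcome = "general", comparator = "general",
                      size_bucket = "general", median = 0.13,
                      lo = 0.0002, hi = 0.99))
})

#' Threshold of low dissimilarity
#'
#' Looks up the median of the predictive distribution for the statistical
#' inconsistency (I-squared) expected in a future meta-analysis matching the
#' three design factors; dissimilarities below this median are classified as
#' "low", otherwise "likely concerning". Passing `"general"` for all three
#' factors returns the general-healthcare-setting threshold 0.13.
#'
#' @param outcome `"all-cause mortality"`, `"semi-objective"`, `"subjective"`
#'   or `"general"`.
#' @param comparator `"pharm vs placebo/control"`, `"pharm vs pharm"`,
#'   `"non-pharmacological"` or `"general"`.
#' @param size_bucket `"<50"`, `"50-200"`, `">200"` or `"general"`; see
#'   [size_bucket()] to derive it from the study sample sizes.
#' @return The threshold (median), with the 95% interval of the predictive
#'   distribution as attribute `interval`.
#' @export
#' @examples
#' lookup_threshold("general", "general", "general")         # 0.13
#' lookup_threshold("subjective", "pharm vs placebo/control", ">200")  # 0.28
lookup_threshold <- function(outcome, comparator, size_bucket) {
  chk <- function(v, valid, what) {
    if (!is.character(v) || length(v) != 1L || !(v %in% valid))
      stop("unknown ", what, " '", v, "'; options: ",
           paste(valid, collapse = ", "), call. = FALSE)
  }
  chk(outcome, c("all-cause mortality", "semi-objective", "subjective",
                 "general"), "outcome")
  chk(comparator, c("pharm vs placebo/control", "pharm vs pharm",
                    "non-pharmacological", "general"), "comparator")
  chk(size_bucket, c("<50", "50-200", ">200", "general"), "size bucket")
  gen <- c(outcome, comparator, size_bucket) == "general"
  if (any(gen) && !all(gen))
    stop("'general' must be used for all three design factors or none",
         call. = FALSE)
  row <- threshold_table[threshold_table$outcome == outcome &
                           threshold_table$comparator == comparator &
                           threshold_table$size_bucket == size_bucket, ]
  structure(row$median, interval = c(row$lo, row$hi))
}

#' Average-study-size bucket
#'
#' Buckets the unweighted mean of the study total sample sizes into the three
#' average-size classes used by the threshold table.
#'
#' @param sample_sizes Numeric vector of study total sample sizes.
#' @return `"<50"`, `"50-200"` or `">200"`.
#' @export
size_bucket <- function(sample_sizes) {
  m <- mean(sample_sizes, na.rm = TRUE)
  if (m < 50) "<50" else if (m <= 200) "50-200" else ">200"
}

#' Classify a comparison dissimilarity matrix against a threshold
#'
#' Each cell is "low" if its dissimilarity falls strictly below the
#' threshold, otherwise "likely concerning".
#'
#' @param cm A [build_comparison_matrix()] result.
#' @param threshold Threshold in (0, 1), typically from [lookup_threshold()].
#' @return Object of class `classified_dissim`: `cm` plus `threshold` and a
#'   character `labels` matrix (`"low"` / `"likely_concerning"`).
#' @export
classify <- function(cm, threshold) {
  stopifnot(inherits(cm, "comparison_dissim"))
  threshold <- as.numeric(threshold)
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  labels <- ifelse(is.na(cm$values), NA_character_,
                   ifelse(cm$values < threshold, "low", "likely_concerning"))
  dimnames(labels) <- dimnames(cm$values)
  structure(c(cm, list(threshold = threshold, labels = labels)),
            class = "classified_dissim")
}

#' @export
print.classified_dissim <- function(x, ...) {
  off <- x$labels[upper.tri(x$labels)]
  cat(sprintf("<classified_dissim> threshold %.4g: %d/%d between-comparison cells 'low', %d/%d diagonal cells 'low'\n",
              x$threshold, sum(off == "low", na.rm = TRUE), length(off),
              sum(diag(x$labels) == "low", na.rm = TRUE), nrow(x$labels)))
  invisible(x)
}
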