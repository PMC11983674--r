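#' Linkage methods available for agglomeration
#'
#' The seven classical Lance-Williams linkages, in the fixed preference order
#' used to break ties in [select_linkage()].
#' @export
linkage_methods <- c("average", "complete", "single", "weighted", "ward",
                     "centroid", "median")

# mapping to the stats::hclust method names
.hclust_method <- c(average = "average", complete = "complete",
                    single = "single", weighted = "mcquitty",
                    ward = "ward.D2", centroid = "centroid",
                    median = "median")

as_dist <- function(dm) {
  if (inherits(dm, "gd_matrix")) {
    if (!all(dm$defined))
      stop("the dissimilarity matrix has undefined pairs (no co-observed ",
           "characteristics); resolve them before clustering", call. = FALSE)
    stats::as.dist(dm$values)
  } else stats::as.dist(dm)
}

#' Hierarchical agglomerative clustering of the Gower matrix
#'
#' Thin wrapper around [stats::hclust()] on the full comparison-level Gower
#' matrix. For `"ward"` the standard form operating on squared
#' dissimilarities is used (the Gower coefficient is not Euclidean, so the
#' variance interpretation is heuristic). Centroid and median linkage can
#' produce inversions (non-monotone merge heights); these are permitted and
#' flagged through the `inversions` attribute, and tree cutting by cluster
#' count is unaffected.
#'
#' @param dm A `gd_matrix` (all pairs defined) or symmetric matrix.
#' @param method One of [linkage_methods].
#' @return An [stats::hclust] tree with attributes `linkage` (the requested
#'   method name) and `inversions` (number of height decreases).
#' @export
agglomerate <- function(dm, method = "average") {
  method <- match.arg(method, linkage_methods)
  hc <- stats::hclust(as_dist(dm), method = .hclust_method[[method]])
  inv <- sum(diff(hc$height) < -1e-12)
  if (inv > 0 && !method %in% c("centroid", "median"))
    warning(inv, " inversion(s) in ", method, " linkage merge heights",
            call. = FALSE)
  attr(hc, "linkage") <- method
  attr(hc, "inversions") <- inv
  hc
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the \eqn{n(n-1)/2} original dissimilarities
#' and the cophenetic distances implied by the dendrogram (the merge height
#' at which each pair first joins one cluster). Values close to 1 indicate
#' that the linkage method faithfully preserves the input dissimilarities.
#'
#' @param dm A `gd_matrix` or symmetric matrix.
#' @param tree An [stats::hclust] tree over the same observations.
#' @return Correlation in \[-1, 1\]; `NA` (with a warning) if either vector
#'   has zero variance.
#' @export
cophenetic_correlation <- function(dm, tree) {
  d0 <- as_dist(dm)
  dc <- stats::cophenetic(tree)
  if (stats::sd(d0) == 0 || stats::sd(dc) == 0) {
    warning("zero variance in dissimilarities; CCC undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(d0, dc)
}

#' Select the linkage method by cophenetic correlation
#'
#' Fits every candidate linkage, computes its cophenetic correlation
#' coefficient, and returns the method with the highest value. Exact ties are
#' broken by the fixed preference order of [linkage_methods] (reproducible
#' default) or uniformly at random when `seed` is given.
#'
#' @param dm A `gd_matrix` or symmetric matrix.
#' @param methods Candidate linkages; default all seven.
#' @param seed Optional integer: break ties randomly under this seed instead
#'   of by preference order.
#' @return List with `method`, `tree` (the fitted tree for the selected
#'   method) and `ccc` (named vector of coefficients).
#' @export
select_linkage <- function(dm, methods = linkage_methods, seed = NULL) {
  methods <- match.arg(methods, linkage_methods, several.ok = TRUE)
  trees <- lapply(methods, function(m) agglomerate(dm, m))
  ccc <- vapply(trees, function(tr) cophenetic_correlation(dm, tr), numeric(1))
  names(ccc) <- methods
  if (all(is.na(ccc)))
    stop("cophenetic correlation undefined for every linkage method",
         call. = FALSE)
  best <- which(!is.na(ccc) & abs(ccc - max(ccc, na.rm = TRUE)) < 1e-12)
  pick <- if (length(best) > 1L && !is.null(seed)) {
    old <- .Random.seed_safe()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
    sample(best, 1L)
  } else {
    # 'methods' is already ordered by the preference order of the caller;
    # the default order is the documented tie-break
    best[1L]
  }
  list(method = methods[pick], tree = trees[[pick]], ccc = ccc)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Silhouette widths for one partition
#'
#' For observation \eqn{i} with mean within-cluster dissimilarity \eqn{a(i)}
#' (to the other members of its cluster) and \eqn{b(i)} the smallest mean
#' dissimilarity to any other cluster,
#' \deqn{s(i) = \frac{b(i) - a(i)}{\max(a(i), b(i))}.}
#' Members of singleton clusters get \eqn{s(i) = 0}, as do observations with
#' \eqn{a(i) = b(i) = 0} (exact duplicates across clusters).
#'
#' @param dm A `gd_matrix` or symmetric matrix.
#' @param labels Integer cluster assignment of length n, with between 2 and
#'   n-1 distinct clusters.
#' @return Numeric vector of silhouette widths in \[-1, 1\].
#' @export
silhouette_widths <- function(dm, labels) {
  v <- if (inherits(dm, "gd_matrix")) dm$values else as.matrix(dm)
  n <- nrow(v)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (length(labels) != n) stop("labels length must match matrix", call. = FALSE)
  if (k < 2L || k > n - 1L)
    stop("number of clusters must lie between 2 and n-1", call. = FALSE)
  sizes <- tabulate(labels, k)
  s <- numeric(n)
  for (i in seq_len(n)) {
    if (sizes[labels[i]] == 1L) { s[i] <- 0; next }
    msum <- vapply(seq_len(k), function(cl) sum(v[i, labels == cl]), numeric(1))
    a <- msum[labels[i]] / (sizes[labels[i]] - 1L)     # excludes v[i,i] = 0
    b <- min(msum[-labels[i]] / sizes[-labels[i]])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Silhouette profile over candidate partitions
#'
#' Cuts the dendrogram at every cluster count `k` in `[k_min, k_max]`,
#' computes the overall average silhouette width of each partition, and
#' reports the best `k` (highest average width; ties go to the smaller
#' partition) together with the leading local optima of the profile, which
#' are worth inspecting as alternative partitions.
#'
#' @param dm A `gd_matrix` or symmetric matrix.
#' @param tree An [stats::hclust] tree from [agglomerate()].
#' @param k_min,k_max Range of cluster counts; default 2 to n-1.
#' @param n_local Number of leading local optima to report (default 3).
#' @return Object of class `silhouette_profile`: list with `k` (scanned
#'   counts), `avg_width`, `widths` (per-k list of per-observation widths),
#'   `labels` (per-k list of cluster assignments), `optimal_k`,
#'   `local_optima`.
#' @export
silhouette_profile <- function(dm, tree, k_min = 2L, k_max = NULL,
                               n_local = 3L) {
  v <- if (inherits(dm, "gd_matrix")) dm$values else as.matrix(dm)
  n <- nrow(v)
  if (is.null(k_max)) k_max <- n - 1L
  k_min <- max(2L, as.integer(k_min))
  k_max <- min(n - 1L, as.integer(k_max))
  ks <- seq(k_min, k_max)
  labels <- lapply(ks, function(k) stats::cutree(tree, k = k))
  widths <- lapply(seq_along(ks), function(j) silhouette_widths(dm, labels[[j]]))
  avg <- vapply(widths, mean, numeric(1))
  opt <- ks[which.max(avg)]
  is_loc <- vapply(seq_along(ks), function(j) {
    left <- if (j == 1L) -Inf else avg[j - 1L]
    right <- if (j == length(ks)) -Inf else avg[j + 1L]
    avg[j] >= left && avg[j] >= right
  }, logical(1))
  loc <- ks[is_loc][order(avg[is_loc], decreasing = TRUE)]
  structure(
    list(k = ks, avg_width = stats::setNames(avg, ks), widths = widths,
         labels = labels, optimal_k = opt,
         local_optima = utils::head(loc, n_local)),
    class = "silhouette_profile"
  )
}

#' @export
print.silhouette_profile <- function(x, ...) {
  cat(sprintf("<silhouette_profile> k in [%d, %d]; optimal k = %d (average width %.2f)\n",
              min(x$k), max(x$k), x$optimal_k,
              x$avg_width[as.character(x$optimal_k)]))
  cat("  leading local optima:",
      paste(sprintf("k=%d (%.2f)", x$local_optima,
                    x$avg_width[as.character(x$local_optima)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Cluster labels for a given partition
#'
#' @param profile A `silhouette_profile`.
#' @param k Cluster count; default the profile's optimal k.
#' @return Integer cluster assignment over the comparison-level rows.
#' @export
partition_labels <- function(profile, k = profile$optimal_k) {
  j <- match(k, profile$k)
  if (is.na(j)) stop("k = ", k, " was not scanned", call. = FALSE)
  profile$labels[[j]]
}

#' Fragmented comparisons
#'
#' A comparison is "fragmented" when its studies are spread over two or more
#' clusters; studies outside the comparison's modal cluster are "eloping".
#' Many fragmented comparisons with sizeable eloping percentages signal
#' imbalanced effect modifiers across the network, i.e., concerns about
#' transitivity. The report also tags the overall pattern with one of four
#' interpretation scenarios:
#' * `"none"` - no fragmented comparison;
#' * `"a"` - 2-3 clusters, isolated fragmentation with eloping percentages at
#'   or below `elope_threshold_pct`: transitivity may still be plausible;
#' * `"b"` - two clusters splitting the network into subnetworks, with at
#'   most isolated fragmentation beyond the eloping threshold;
#' * `"c"` - two clusters but widespread fragmentation;
#' * `"d"` - more than two clusters with widespread fragmentation (loose
#'   partitioning).
#'
#' @param labels Integer cluster assignment over the comparison-table rows.
#' @param ct The `comparison_table`.
#' @param elope_threshold_pct Minimum eloping percentage regarded as
#'   noteworthy (default 5).
#' @return Object of class `fragmentation_report`: list with `per_comparison`
#'   (data frame: comparison, cluster, n, pct), `fragmented` (character
#'   vector), `eloping_pct` (named vector, percentage outside the modal
#'   cluster), `n_clusters`, `scenario`.
#' @export
fragmented_comparisons <- function(labels, ct, elope_threshold_pct = 5) {
  stopifnot(length(labels) == length(ct$comparison))
  tab <- table(comparison = ct$comparison, cluster = labels)
  per <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(per)[3L] <- "n"
  per <- per[per$n > 0L, , drop = FALSE]
  per$cluster <- as.integer(per$cluster)
  tot <- rowSums(tab)
  per$pct <- 100 * per$n / tot[per$comparison]
  per <- per[order(per$comparison, per$cluster), , drop = FALSE]
  rownames(per) <- NULL
  n_cl_per <- rowSums(tab > 0L)
  fragmented <- names(n_cl_per)[n_cl_per >= 2L]
  eloping <- 100 * (1 - apply(tab, 1L, max) / tot)
  k <- length(unique(labels))
  P <- nrow(tab)
  few <- max(1L, ceiling(0.05 * P))
  n_frag <- length(fragmented)
  big_elope <- sum(eloping[fragmented] > elope_threshold_pct)
  scenario <- if (n_frag == 0L) "none"
  else if (k <= 3L && n_frag <= few && big_elope == 0L) "a"
  else if (k == 2L && n_frag <= few) "b"
  else if (k == 2L) "c"
  else "d"
  structure(
    list(per_comparison = per, fragmented = fragmented,
         eloping_pct = eloping, n_clusters = k,
         elope_threshold_pct = elope_threshold_pct, scenario = scenario),
    class = "fragmentation_report"
  )
}

#' @export
print.fragmentation_report <- function(x, ...) {
  cat(sprintf("<fragmentation_report> %d cluster(s), %d fragmented comparison(s) [scenario %s]\n",
              x$n_clusters, length(x$fragmented), x$scenario))
  if (length(x$fragmented))
    cat("  fragmented:",
        paste(sprintf("%s (%.0f%% eloping)", x$fragmented,
                      x$eloping_pct[x$fragmented]), collapse = "; "), "\n")
  invisible(x)
}
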