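#' Per-characteristic dissimilarity between two values
#'
#' Computes the contribution \eqn{d(x,y)_i} of one characteristic to the
#' Gower coefficient, together with the co-observation indicator
#' \eqn{\delta_{xy,i}} (0 when either value is missing, in which case the
#' dissimilarity is undefined and returned as `NA`).
#'
#' Rules by type: quantitative \eqn{|x-y|/R_i}; binary/nominal 0 if equal,
#' 1 otherwise; ordinal \eqn{|rank(x)-rank(y)|/RR_i} with ranks taken from
#' the declared level order.
#'
#' @param x,y Values (or `NA`).
#' @param spec The [characteristic_spec()] of the characteristic.
#' @param range_i Range \eqn{R_i} (quantitative) or rank range \eqn{RR_i}
#'   (ordinal). Ignored for binary/nominal.
#' @return A list with `d` (dissimilarity in \[0,1\], `NA` if undefined) and
#'   `delta` (0 or 1).
#' @export
characteristic_dissimilarity <- function(x, y, spec, range_i = NULL) {
  if (is.na(x) || is.na(y)) return(list(d = NA_real_, delta = 0L))
  d <- switch(spec$type,
    quantitative = {
      x <- as.numeric(x); y <- as.numeric(y)
      if (x == y) 0
      else if (is.null(range_i) || is.na(range_i) || range_i <= 0)
        stop("characteristic '", spec$name,
             "': degenerate range with unequal values", call. = FALSE)
      else abs(x - y) / range_i
    },
    ordinal = {
      rx <- match(as.character(x), spec$levels)
      ry <- match(as.character(y), spec$levels)
      if (is.na(rx) || is.na(ry))
        stop("characteristic '", spec$name, "': value outside declared levels",
             call. = FALSE)
      if (rx == ry) 0
      else if (is.null(range_i) || is.na(range_i) || range_i <= 0)
        stop("characteristic '", spec$name,
             "': degenerate rank range with unequal values", call. = FALSE)
      else abs(rx - ry) / range_i
    },
    # binary and nominal: simple matching
    {
      if (!as.character(x) %in% spec$levels ||
          !as.character(y) %in% spec$levels)
        stop("characteristic '", spec$name, "': value outside declared levels",
             call. = FALSE)
      as.numeric(as.character(x) != as.character(y))
    }
  )
  list(d = d, delta = 1L)
}

#' Weighted Gower dissimilarity between two observations
#'
#' \deqn{d(x,y) = \frac{\sum_i w_i \delta_{xy,i} d(x,y)_i}
#'                     {\sum_i w_i \delta_{xy,i}}}
#' i.e., the weighted mean of the per-characteristic dissimilarities over the
#' characteristics observed in both rows. When no characteristic is
#' co-observed (or all co-observed characteristics carry zero weight) the
#' coefficient is undefined and `NA` is returned.
#'
#' @param row_x,row_y Named lists/vectors (or one-row data frames) of
#'   characteristic values.
#' @param specs Named list of [characteristic_spec()] objects.
#' @param ranges Named numeric vector of ranges per characteristic (as
#'   produced by [characteristic_ranges()]).
#' @return Gower coefficient in \[0,1\], or `NA` if undefined.
#' @export
gower_distance <- function(row_x, row_y, specs, ranges) {
  num <- 0; den <- 0
  for (nm in names(specs)) {
    s <- specs[[nm]]
    cd <- characteristic_dissimilarity(row_x[[nm]], row_y[[nm]], s, ranges[[nm]])
    if (cd$delta == 1L) {
      num <- num + s$weight * cd$d
      den <- den + s$weight
    }
  }
  if (den == 0) NA_real_ else num / den
}

#' Observed ranges of the characteristics
#'
#' For quantitative characteristics the range is the observed min-max spread
#' over the *study* values (multi-arm expansion would merely duplicate
#' values), unless the specification carries a user-supplied `range`. For
#' ordinal characteristics it is the spread of the integer level codes of the
#' levels actually observed. Binary/nominal characteristics get `NA` (their
#' rule needs no range). A quantitative characteristic constant across all
#' studies yields range 0 with a warning; all its pairwise dissimilarities
#' are then 0 by the equal-value rule.
#'
#' @param values Data frame of study-level values.
#' @param specs Named list of `characteristic_spec` objects.
#' @return Named numeric vector of ranges.
#' @export
characteristic_ranges <- function(values, specs) {
  vapply(names(specs), function(nm) {
    s <- specs[[nm]]
    col <- values[[nm]]
    if (s$type == "quantitative") {
      if (!is.null(s$range)) return(s$range)
      obs <- col[!is.na(col)]
      if (!length(obs)) return(NA_real_)
      r <- max(obs) - min(obs)
      if (r == 0)
        warning("quantitative characteristic '", nm,
                "' is constant across studies; it contributes zero ",
                "dissimilarity to all pairs", call. = FALSE)
      r
    } else if (s$type == "ordinal") {
      codes <- match(col[!is.na(col)], s$levels)
      if (!length(codes)) return(NA_real_)
      max(codes) - min(codes)
    } else NA_real_
  }, numeric(1))
}

#' Gower dissimilarity matrix over all comparison-level observations
#'
#' Builds the symmetric matrix \eqn{\{d\}} of weighted Gower coefficients
#' between all expanded rows of a comparison table. Ranges are computed from
#' the study-level values (or taken from range overrides). Pairs of rows
#' belonging to the same multi-arm study are exactly 0 by construction. Pairs
#' with no co-observed characteristic are undefined: they are `NA` in
#' `values`, `FALSE` in `defined`, and never silently zero.
#'
#' @param ct A [expand_comparisons()] table.
#' @return Object of class `gd_matrix`: list with `values` (symmetric numeric
#'   matrix, zero diagonal), `defined` (logical matrix), `labels`,
#'   `study_id`, `comparison`, `ranges`.
#' @export
build_dissimilarity_matrix <- function(ct) {
  stopifnot(inherits(ct, "comparison_table"))
  n <- length(ct$study_id)
  if (n < 2L) stop("need at least two comparison-level rows", call. = FALSE)
  specs <- ct$specs
  ranges <- characteristic_ranges(ct$study_values, specs)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (nm in names(specs)) {
    s <- specs[[nm]]
    col <- ct$values[[nm]]
    obs <- !is.na(col)
    delta <- outer(obs, obs, `&`)
    dij <- matrix(0, n, n)
    if (s$type == "quantitative") {
      x <- as.numeric(col)
      diff <- abs(outer(x, x, `-`))
      r <- ranges[[nm]]
      if (is.na(r)) next                       # never observed
      if (r > 0) dij <- diff / r               # r == 0: all equal, dij stays 0
    } else if (s$type == "ordinal") {
      codes <- match(col, s$levels)
      diff <- abs(outer(codes, codes, `-`))
      r <- ranges[[nm]]
      if (is.na(r)) next
      if (r > 0) dij <- diff / r
    } else {
      dij <- outer(col, col, `!=`) * 1
    }
    dij[!delta] <- 0
    num <- num + s$weight * delta * dij
    den <- den + s$weight * delta
  }
  values <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), NA_real_)
  defined <- den > 0
  # rows of the same study are identical observations: force exact zeros
  same_study <- outer(ct$study_id, ct$study_id, `==`)
  values[same_study] <- 0
  defined[same_study] <- TRUE
  diag(values) <- 0
  diag(defined) <- TRUE
  labels <- row_labels(ct)
  dimnames(values) <- list(labels, labels)
  dimnames(defined) <- list(labels, labels)
  n_undef <- sum(!defined[upper.tri(defined)])
  if (n_undef > 0)
    message(n_undef, " pair(s) share no co-observed characteristic; ",
            "their Gower dissimilarity is undefined")
  structure(
    list(values = values, defined = defined, labels = labels,
         study_id = ct$study_id, comparison = ct$comparison, ranges = ranges),
    class = "gd_matrix"
  )
}

#' @export
print.gd_matrix <- function(x, ...) {
  n <- nrow(x$values)
  def <- x$defined[upper.tri(x$defined)]
  vals <- x$values[upper.tri(x$values)][def]
  cat(sprintf("<gd_matrix> %d x %d, Gower dissimilarities in [%.2f, %.2f]\n",
              n, n, min(vals), max(vals)))
  if (any(!def)) cat("  undefined pairs:", sum(!def), "\n")
  invisible(x)
}

#' Write a square dissimilarity matrix as labelled CSV
#'
#' @param m A `gd_matrix`, `comparison_dissim` or plain matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  if (inherits(m, c("gd_matrix", "comparison_dissim", "classified_dissim")))
    m <- m$values
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
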