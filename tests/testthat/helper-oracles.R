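# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from first principles (plain double loops over the
# defining formulas) without going through the package's vectorized paths.

# Plain per-characteristic dissimilarity + co-observation indicator.
oracle_char_d <- function(x, y, spec, range_i) {
  if (is.na(x) || is.na(y)) return(c(d = NA_real_, delta = 0))
  if (spec$type == "quantitative") {
    x <- as.numeric(x); y <- as.numeric(y)
    d <- if (x == y) 0 else abs(x - y) / range_i
  } else if (spec$type == "ordinal") {
    rx <- match(x, spec$levels); ry <- match(y, spec$levels)
    d <- if (rx == ry) 0 else abs(rx - ry) / range_i
  } else {
    d <- as.numeric(x != y)
  }
  c(d = d, delta = 1)
}

# Weighted Gower matrix by naive double loop over rows and characteristics.
oracle_gower_matrix <- function(values, specs, study_values) {
  ranges <- sapply(names(specs), function(nm) {
    s <- specs[[nm]]
    col <- study_values[[nm]]
    if (s$type == "quantitative") {
      if (!is.null(s$range)) s$range
      else diff(range(col, na.rm = TRUE))
    } else if (s$type == "ordinal") {
      codes <- match(col[!is.na(col)], s$levels)
      max(codes) - min(codes)
    } else NA_real_
  })
  n <- nrow(values)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; den <- 0
    for (nm in names(specs)) {
      cd <- oracle_char_d(values[[nm]][i], values[[nm]][j], specs[[nm]],
                          ranges[[nm]])
      if (cd[["delta"]] == 1) {
        num <- num + specs[[nm]]$weight * cd[["d"]]
        den <- den + specs[[nm]]$weight
      }
    }
    out[i, j] <- if (den == 0) NA_real_ else num / den
  }
  out
}

# RMS over a vector of dissimilarities, zero-centered.
oracle_rms <- function(d) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  sqrt(sum(d^2) / length(d))
}

# Naive agglomeration for single/complete linkage: merge heights only.
oracle_linkage_heights <- function(d, type = c("single", "complete")) {
  type <- match.arg(type)
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  link <- function(a, b) {
    cross <- d[a, b, drop = FALSE]
    if (type == "single") min(cross) else max(cross)
  }
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      h <- link(clusters[[i]], clusters[[j]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[3]]] <- c(clusters[[best[3]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Silhouette widths straight from the definition.
oracle_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  sapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(sapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl])))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  })
}

# All set partitions of n elements (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(m + 1L)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(0), 0L)
  out
}

# Random mixed-type dataset for property tests (two-arm star network).
random_dataset <- function(n = 8, n_quant = 2, n_ord = 1, n_nom = 2,
                           missing_rate = 0.2) {
  specs <- list()
  values <- list()
  for (j in seq_len(n_quant)) {
    nm <- paste0("q", j)
    specs[[nm]] <- characteristic_spec(nm, "quantitative")
    values[[nm]] <- round(runif(n, 0, 100), 1)
  }
  for (j in seq_len(n_ord)) {
    nm <- paste0("o", j)
    lev <- c("lo", "mid", "hi", "vhi")
    specs[[nm]] <- characteristic_spec(nm, "ordinal", levels = lev)
    values[[nm]] <- sample(lev, n, replace = TRUE)
  }
  for (j in seq_len(n_nom)) {
    nm <- paste0("m", j)
    lev <- c("a", "b", "c")
    specs[[nm]] <- characteristic_spec(nm, "nominal", levels = lev,
                                       weight = sample(c(0.5, 1, 2), 1))
    values[[nm]] <- sample(lev, n, replace = TRUE)
  }
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (missing_rate > 0)
    for (j in seq_len(ncol(values)))
      values[[j]][runif(n) < missing_rate] <- NA
  arms <- lapply(seq_len(n), function(i)
    c("CTRL", paste0("T", (i - 1) %% 3 + 1)))
  suppressMessages(suppressWarnings(
    study_dataset(paste0("s", seq_len(n)), arms, values, specs)))
}

# Random symmetric dissimilarity matrix with zero diagonal.
random_dissim <- function(n, max_d = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.01, max_d)
  m <- m + t(m)
  dimnames(m) <- list(paste0("x", seq_len(n)), paste0("x", seq_len(n)))
  m
}
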