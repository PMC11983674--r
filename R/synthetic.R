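#' Configuration for the synthetic network generator
#'
#' Describes a connected treatment network with planted clustering structure.
#' Studies are assigned to `planted_clusters` groups; quantitative
#' characteristics are drawn per cluster from normal distributions whose
#' means are `shift` within-cluster standard deviations apart, and
#' qualitative characteristics from cluster-specific category distributions
#' whose concentration on a cluster-modal level grows with `shift`
#' (`shift = 0` gives identical distributions in every cluster, i.e., no
#' signal). Missingness is applied completely at random.
#'
#' @param n_studies Number of studies.
#' @param treatments Treatment labels; default `LETTERS` prefix of length
#'   `n_treatments`.
#' @param n_treatments Number of treatments if `treatments` is `NULL`
#'   (default 4, star network around the first treatment).
#' @param comparison_design Optional data frame with columns `arms`
#'   (`";"`-delimited treatment labels per study design, e.g. `"A;B;C"` for a
#'   three-arm design) and `n_studies`. When omitted, two-arm studies are
#'   spread evenly over the star comparisons with the first treatment.
#' @param n_quant,n_qual Numbers of quantitative and qualitative (3-level
#'   nominal) characteristics.
#' @param planted_clusters Number of planted clusters `K`.
#' @param shift Between-cluster mean separation in units of the
#'   within-cluster standard deviation (>= 0).
#' @param missing_rate MCAR missingness rate in \[0, 1).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_studies = 24L, treatments = NULL,
                             n_treatments = 4L, comparison_design = NULL,
                             n_quant = 4L, n_qual = 2L, planted_clusters = 2L,
                             shift = 3, missing_rate = 0, seed = 1L) {
  if (is.null(treatments)) treatments <- LETTERS[seq_len(n_treatments)]
  stopifnot(n_studies >= 2L, length(treatments) >= 2L,
            n_quant + n_qual >= 1L, planted_clusters >= 1L,
            shift >= 0, missing_rate >= 0, missing_rate < 1)
  if (!is.null(comparison_design)) {
    stopifnot(is.data.frame(comparison_design),
              all(c("arms", "n_studies") %in% names(comparison_design)))
    if (sum(comparison_design$n_studies) != n_studies)
      stop("comparison_design study counts must sum to n_studies",
           call. = FALSE)
  }
  structure(
    list(n_studies = as.integer(n_studies), treatments = treatments,
         comparison_design = comparison_design, n_quant = as.integer(n_quant),
         n_qual = as.integer(n_qual),
         planted_clusters = as.integer(planted_clusters), shift = shift,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic network with planted clusters
#'
#' @param cfg A [generator_config()].
#' @return List with `dataset` (a [study_dataset()]) and `planted_labels`
#'   (integer cluster per study).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_studies
  K <- cfg$planted_clusters
  trts <- cfg$treatments
  # arms per study
  arms <- if (!is.null(cfg$comparison_design)) {
    designs <- strsplit(cfg$comparison_design$arms, ";", fixed = TRUE)
    rep(lapply(designs, trimws), times = cfg$comparison_design$n_studies)
  } else {
    others <- trts[-1L]
    lapply(seq_len(n), function(i)
      c(trts[1L], others[(i - 1L) %% length(others) + 1L]))
  }
  clusters <- rep(seq_len(K), length.out = n)
  # qualitative levels: at least 3, and enough for each cluster to own a
  # distinct modal level (the categorical analogue of the mean shift)
  qlev <- paste0("cat", seq_len(max(3L, K)))
  values <- list()
  specs <- list()
  for (j in seq_len(cfg$n_quant)) {
    nm <- sprintf("quant_%02d", j)
    mu <- cfg$shift * sample(seq_len(K) - 1L)   # permuted cluster centres
    values[[nm]] <- stats::rnorm(n, mean = mu[clusters], sd = 1)
    specs[[nm]] <- characteristic_spec(nm, "quantitative")
  }
  for (j in seq_len(cfg$n_qual)) {
    nm <- sprintf("qual_%02d", j)
    modal <- sample(qlev, K)
    values[[nm]] <- vapply(seq_len(n), function(i) {
      w <- exp(cfg$shift * (qlev == modal[clusters[i]]))
      sample(qlev, 1L, prob = w / sum(w))
    }, character(1))
    specs[[nm]] <- characteristic_spec(nm, "nominal", levels = qlev)
  }
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n * ncol(values)) < cfg$missing_rate,
                   n, ncol(values))
    for (j in seq_len(ncol(values))) values[[j]][mask[, j]] <- NA
  }
  names(specs) <- names(values)
  ds <- withCallingHandlers(
    study_dataset(sprintf("study_%02d", seq_len(n)), arms, values, specs),
    warning = function(w) {
      if (grepl("not connected", conditionMessage(w)))
        stop("the configured comparison design yields a disconnected network",
             call. = FALSE)
      invokeRestart("muffleWarning")
    }
  )
  list(dataset = ds, planted_labels = clusters)
}

#' Fictional triangle network
#'
#' A seven-study, two-arm network over three treatments (A, B, C) with three
#' comparisons - B vs A (3 studies), C vs A (2), C vs B (2) - and three
#' characteristics: total sample size, mean age (quantitative) and adequate
#' randomization (binary). The values are this package's own construction:
#' B vs A is investigated in large studies with young participants and
#' adequate randomization, C vs A in small studies with old participants and
#' inadequate randomization, and C vs B lies in between. Consequently every
#' within-comparison dissimilarity is low, every between-comparison
#' dissimilarity is substantial, and the three comparisons form three clean
#' clusters.
#'
#' @return A [study_dataset()].
#' @export
fictional_fixture <- function() {
  study_id <- paste0("S", 1:7)
  arms <- list(c("A", "B"), c("A", "B"), c("A", "B"),
               c("A", "C"), c("A", "C"),
               c("B", "C"), c("B", "C"))
  values <- data.frame(
    sample_size = c(300, 320, 340, 60, 70, 180, 190),
    mean_age    = c(35, 37, 39, 70, 72, 55, 57),
    adequate_randomization = c("yes", "yes", "yes", "no", "no", "no", "no"),
    stringsAsFactors = FALSE
  )
  specs <- list(
    sample_size = characteristic_spec("sample_size", "quantitative"),
    mean_age = characteristic_spec("mean_age", "quantitative"),
    adequate_randomization = characteristic_spec("adequate_randomization",
                                                 "binary",
                                                 levels = c("no", "yes"))
  )
  study_dataset(study_id, arms, values, specs)
}

#' Packaged synthetic stand-in extraction tables
#'
#' Paths to the two packaged fixtures: a rheumatoid-arthritis-like network
#' (27 two-arm placebo-controlled studies of six biologic agents, 10
#' characteristics, no missing values) and a COPD-like network (39 studies -
#' 29 two-arm, 4 three-arm, 6 four-arm - over 8 treatments, 16 comparisons,
#' 11 characteristics with sparse missingness). Both are *synthetic
#' stand-ins*: they reproduce the structure of the corresponding published
#' extraction tables (treatments, comparison design, arm structure,
#' characteristic types and missingness pattern), not their unavailable cell
#' values, and carry `synthetic` in their file names to make that explicit.
#'
#' @param which `"ra"` or `"copd"`.
#' @return Named character vector with elements `table` and `config`.
#' @export
synthetic_fixture_paths <- function(which = c("ra", "copd")) {
  which <- match.arg(which)
  stem <- paste0(which, "_synthetic")
  c(table = system.file("extdata", paste0(stem, ".csv"),
                        package = "nmadissim", mustWork = TRUE),
    config = system.file("extdata", paste0(stem, "_config.yaml"),
                         package = "nmadissim", mustWork = TRUE))
}

#' Load a packaged synthetic stand-in dataset
#'
#' @inheritParams synthetic_fixture_paths
#' @return A [study_dataset()].
#' @seealso [synthetic_fixture_paths()]
#' @export
load_synthetic_fixture <- function(which = c("ra", "copd")) {
  p <- synthetic_fixture_paths(which)
  load_dataset(p[["table"]], p[["config"]])
}
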