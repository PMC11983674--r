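quant <- characteristic_spec("q", "quantitative")
nom <- characteristic_spec("n", "nominal", levels = c("yes", "no"))
ord <- characteristic_spec("o", "ordinal",
                           levels = c("early", "established", "late"))

test_that("per-characteristic dissimilarity follows the type rules", {
  expect_equal(characteristic_dissimilarity(10, 20, quant, 40),
               list(d = 0.25, delta = 1L))
  expect_equal(characteristic_dissimilarity("yes", "no", nom),
               list(d = 1, delta = 1L))
  expect_equal(characteristic_dissimilarity("yes", "yes", nom),
               list(d = 0, delta = 1L))
  expect_equal(characteristic_dissimilarity("early", "late", ord, 2),
               list(d = 1, delta = 1L))
  miss <- characteristic_dissimilarity(NA, 3, quant, 10)
  expect_equal(miss$delta, 0L)
  expect_true(is.na(miss$d))
  expect_error(characteristic_dissimilarity(1, 2, quant, 0),
               "degenerate range")
  expect_error(characteristic_dissimilarity("early", "never", ord, 2),
               "outside declared levels")
})

test_that("the weighted Gower coefficient is the weighted mean over co-observed characteristics", {
  specs <- list(a = characteristic_spec("a", "quantitative"),
                b = characteristic_spec("b", "quantitative"))
  ranges <- c(a = 40, b = 1)
  expect_equal(gower_distance(list(a = 10, b = 0), list(a = 10, b = 0),
                              specs, ranges), 0)
  # d_i = 0.25 and 1.0 with equal weights
  expect_equal(gower_distance(list(a = 10, b = 0), list(a = 20, b = 1),
                              specs, ranges), 0.625)
  # summary group of two statistics (w = 0.5 each) plus one nominal
  specs3 <- normalize_weights(list(
    characteristic_spec("u", "quantitative", summary_group = "g"),
    characteristic_spec("v", "quantitative", summary_group = "g"),
    characteristic_spec("m", "nominal", levels = c("x", "y"))
  ))
  names(specs3) <- c("u", "v", "m")
  # d_i = (0.2, 0.4, 1.0), w_i = (0.5, 0.5, 1.0) -> 1.3 / 2 = 0.65
  expect_equal(
    gower_distance(list(u = 0, v = 0, m = "x"),
                   list(u = 2, v = 4, m = "y"),
                   specs3, c(u = 10, v = 10, m = NA)),
    0.65)
  # no co-observed characteristic -> undefined
  expect_true(is.na(gower_distance(list(a = NA, b = 1), list(a = 1, b = NA),
                                   specs, ranges)))
})

test_that("matrix construction matches the naive double-loop oracle (property)", {
  set.seed(11)
  for (rep in 1:12) {
    ds <- random_dataset(n = sample(4:10, 1), missing_rate = 0.2)
    ct <- expand_comparisons(ds)
    gd <- suppressMessages(build_dissimilarity_matrix(ct))
    oracle <- oracle_gower_matrix(ct$values, ct$specs, ct$study_values)
    comparable <- gd$defined & !diag(TRUE, nrow(oracle))
    expect_lt(max(abs(gd$values[comparable] - oracle[comparable])), 1e-12)
    expect_equal(gd$defined[!diag(TRUE, nrow(oracle))],
                 !is.na(oracle)[!diag(TRUE, nrow(oracle))])
    # Gower bounds and symmetry
    expect_true(all(gd$values[gd$defined] >= 0 & gd$values[gd$defined] <= 1))
    expect_identical(gd$values, t(gd$values))
    expect_true(all(diag(gd$values) == 0))
  }
})

test_that("matrix construction agrees with cluster::daisy on complete data", {
  set.seed(5)
  ds <- random_dataset(n = 9, missing_rate = 0)
  ct <- expand_comparisons(ds)
  gd <- build_dissimilarity_matrix(ct)
  df <- ct$values
  for (nm in names(ct$specs)) {
    s <- ct$specs[[nm]]
    if (s$type == "ordinal") df[[nm]] <- factor(df[[nm]], levels = s$levels,
                                                ordered = TRUE)
    else if (s$type != "quantitative") df[[nm]] <- factor(df[[nm]],
                                                          levels = s$levels)
  }
  w <- vapply(ct$specs, `[[`, numeric(1), "weight")
  ref <- as.matrix(cluster::daisy(df, metric = "gower", weights = w))
  expect_equal(unname(gd$values), unname(ref), tolerance = 1e-10)
})

test_that("Gower is invariant to rescaling all weights (property)", {
  set.seed(23)
  ds <- random_dataset(n = 7, missing_rate = 0.2)
  ct <- expand_comparisons(ds)
  gd1 <- suppressMessages(build_dissimilarity_matrix(ct))
  ct2 <- ct
  for (nm in names(ct2$specs)) ct2$specs[[nm]]$weight <-
      ct2$specs[[nm]]$weight * 7.3
  gd2 <- suppressMessages(build_dissimilarity_matrix(ct2))
  expect_equal(gd1$values, gd2$values, tolerance = 1e-12)
})

test_that("with unit weights and complete data the weighted form reduces to the unweighted mean", {
  set.seed(31)
  ds <- random_dataset(n = 8, missing_rate = 0)
  for (nm in names(ds$specs)) ds$specs[[nm]]$weight <- 1
  ct <- expand_comparisons(ds)
  gd <- build_dissimilarity_matrix(ct)
  # unweighted: plain arithmetic mean of the per-characteristic terms
  Z <- length(ds$specs)
  oracle <- oracle_gower_matrix(ct$values, ct$specs, ct$study_values)
  expect_equal(unname(gd$values[2, 1]), oracle[2, 1], tolerance = 1e-12)
  per_char <- vapply(names(ds$specs), function(nm) {
    r <- characteristic_ranges(ds$values, ds$specs)[[nm]]
    characteristic_dissimilarity(ct$values[[nm]][1], ct$values[[nm]][2],
                                 ds$specs[[nm]], r)$d
  }, numeric(1))
  expect_equal(unname(gd$values[2, 1]), mean(per_char), tolerance = 1e-12)
})

test_that("dropping a characteristic keeps Gower inside [0,1] (property)", {
  set.seed(41)
  for (rep in 1:8) {
    ds <- random_dataset(n = 6, missing_rate = 0.1)
    ct <- expand_comparisons(ds)
    gd <- suppressMessages(build_dissimilarity_matrix(ct))
    drop <- sample(names(ds$specs), 1)
    ds2 <- ds
    ds2$specs[[drop]] <- NULL
    ds2$values[[drop]] <- NULL
    ct2 <- expand_comparisons(ds2)
    gd2 <- suppressMessages(build_dissimilarity_matrix(ct2))
    expect_true(all(gd2$values[gd2$defined] >= 0 &
                      gd2$values[gd2$defined] <= 1))
  }
})

test_that("a constant quantitative characteristic contributes zero with a warning", {
  specs <- list(flat = characteristic_spec("flat", "quantitative"),
                var = characteristic_spec("var", "quantitative"))
  ds <- suppressWarnings(study_dataset(
    c("s1", "s2", "s3"),
    list(c("A", "B"), c("A", "B"), c("A", "C")),
    data.frame(flat = c(4, 4, 4), var = c(0, 1, 2)), specs))
  ct <- expand_comparisons(ds)
  expect_warning(gd <- build_dissimilarity_matrix(ct), "constant")
  # flat contributes d = 0 but still counts in the denominator
  expect_equal(unname(gd$values[2, 1]), (0 + 0.5) / 2)
})

test_that("rows of one multi-arm study are at zero dissimilarity", {
  specs <- list(age = characteristic_spec("age", "quantitative"))
  ds <- study_dataset(c("s1", "s2"), list(c("A", "B", "C"), c("A", "B")),
                      data.frame(age = c(10, 50)), specs)
  ct <- expand_comparisons(ds)
  gd <- build_dissimilarity_matrix(ct)
  i <- which(ct$study_id == "s1")
  expect_true(all(gd$values[i, i] == 0))
  expect_equal(length(i), 3L)
})

test_that("range overrides replace the observed range", {
  specs <- list(age = characteristic_spec("age", "quantitative", range = 50))
  ds <- study_dataset(c("s1", "s2"), list(c("A", "B"), c("A", "C")),
                      data.frame(age = c(60, 65)), specs)
  ct <- expand_comparisons(ds)
  gd <- build_dissimilarity_matrix(ct)
  expect_equal(unname(gd$values[2, 1]), 5 / 50)
})
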