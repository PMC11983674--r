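# small helper: analysis pieces for a dataset
pieces <- function(ds) {
  ct <- expand_comparisons(ds)
  gd <- suppressMessages(build_dissimilarity_matrix(ct))
  list(ct = ct, gd = gd)
}

test_that("within-comparison dissimilarity is the zero-centered RMS of the pairwise GDs", {
  # two studies at GD 0.3 and 0.4 from a third -> direct arithmetic
  expect_equal(nmadissim:::rms_dissim(c(0.3, 0.4)),
               sqrt((0.09 + 0.16) / 2), ignore_attr = TRUE)
  # single-study comparison has zero within-comparison dissimilarity
  specs <- list(age = characteristic_spec("age", "quantitative"))
  ds <- study_dataset(c("s1", "s2", "s3"),
                      list(c("A", "B"), c("A", "B"), c("A", "C")),
                      data.frame(age = c(0, 10, 5)), specs)
  p <- pieces(ds)
  expect_equal(as.numeric(
    within_comparison_dissimilarity(p$gd, p$ct, "A vs C")), 0)
  expect_equal(as.numeric(
    within_comparison_dissimilarity(p$gd, p$ct, "A vs B")), 1)
  expect_error(within_comparison_dissimilarity(p$gd, p$ct, "B vs C"),
               "not observed")
})

test_that("between-comparison dissimilarity covers all cross pairs", {
  specs <- list(x = characteristic_spec("x", "binary",
                                        levels = c("no", "yes")))
  # identical values everywhere -> all cross pairs 0
  ds0 <- study_dataset(c("s1", "s2", "s3", "s4"),
                       list(c("A", "B"), c("A", "B"), c("A", "C"),
                            c("A", "C")),
                       data.frame(x = rep("yes", 4)), specs)
  p0 <- pieces(ds0)
  expect_equal(as.numeric(between_comparison_dissimilarity(
    p0$gd, p0$ct, "A vs B", "A vs C")), 0)
  # opposite values -> all cross pairs 1
  ds1 <- study_dataset(c("s1", "s2", "s3", "s4"),
                       list(c("A", "B"), c("A", "B"), c("A", "C"),
                            c("A", "C")),
                       data.frame(x = c("yes", "yes", "no", "no")), specs)
  p1 <- pieces(ds1)
  expect_equal(as.numeric(between_comparison_dissimilarity(
    p1$gd, p1$ct, "A vs B", "A vs C")), 1)
  expect_error(between_comparison_dissimilarity(p1$gd, p1$ct, "A vs B",
                                                "A vs B"), "different")
})

test_that("within/between values match naive loops on random networks (property)", {
  set.seed(13)
  for (rep in 1:10) {
    ds <- random_dataset(n = sample(5:9, 1), missing_rate = 0.15)
    p <- pieces(ds)
    cm <- build_comparison_matrix(p$gd, p$ct)
    v <- p$gd$values
    v[!p$gd$defined] <- NA
    cmp <- p$ct$comparisons$comparison
    for (a in seq_along(cmp)) {
      ia <- which(p$ct$comparison == cmp[a])
      if (length(ia) > 1) {
        ds_pairs <- utils::combn(ia, 2)
        expected <- oracle_rms(v[t(ds_pairs)])
        expect_equal(cm$values[a, a], expected, tolerance = 1e-12)
      } else {
        expect_equal(cm$values[a, a], 0)
      }
      for (b in seq_along(cmp)) {
        if (a >= b) next
        ib <- which(p$ct$comparison == cmp[b])
        expected <- oracle_rms(as.vector(v[ia, ib]))
        expect_equal(cm$values[a, b], expected, tolerance = 1e-12)
      }
    }
    # symmetry, bounds, and RMS >= arithmetic mean (power-mean inequality)
    expect_identical(cm$values, t(cm$values))
    expect_true(all(cm$values >= 0 & cm$values <= 1, na.rm = TRUE))
    for (a in seq_along(cmp)) for (b in seq_along(cmp)) {
      ia <- which(p$ct$comparison == cmp[a])
      ib <- which(p$ct$comparison == cmp[b])
      dd <- if (a == b) {
        if (length(ia) < 2) next
        v[t(utils::combn(ia, 2))]
      } else as.vector(v[ia, ib])
      if (all(is.na(dd))) next
      expect_gte(cm$values[a, b] + 1e-12, mean(dd, na.rm = TRUE))
    }
  }
})

test_that("cross pairs of one multi-arm study are included as zeros", {
  specs <- list(x = characteristic_spec("x", "quantitative"))
  ds <- study_dataset(c("m", "s2", "s3"),
                      list(c("A", "B", "C"), c("A", "B"), c("A", "C")),
                      data.frame(x = c(0, 10, 10)), specs)
  p <- pieces(ds)
  d <- between_comparison_dissimilarity(p$gd, p$ct, "A vs B", "A vs C")
  expect_equal(attr(d, "n_same_study"), 1L)
  # cross pairs: m(AB)-m(AC) = 0, m(AB)-s3 = 1, s2-m(AC) = 1, s2-s3 = 0
  expect_equal(as.numeric(d), sqrt((0 + 1 + 1 + 0) / 4))
})

test_that("appending an exact copy of a study never increases the within-comparison RMS", {
  set.seed(19)
  for (rep in 1:5) {
    ds <- random_dataset(n = 6, missing_rate = 0.1)
    p <- pieces(ds)
    # provable for small comparisons (h <= 3); an outlier copy in a larger
    # comparison can raise the RMS despite the added zero pair
    small <- p$ct$comparisons$h <= 3
    cmp <- p$ct$comparisons$comparison[small][which.max(p$ct$comparisons$h[small])]
    before <- as.numeric(within_comparison_dissimilarity(p$gd, p$ct, cmp))
    src <- which(p$ct$comparison == cmp)[1]
    src_study <- match(p$ct$study_id[src], ds$study_id)
    ds2 <- suppressWarnings(study_dataset(
      c(ds$study_id, "copy"),
      c(ds$arms, ds$arms[src_study]),
      rbind(ds$values, ds$values[src_study, ]),
      ds$specs))
    p2 <- pieces(ds2)
    after <- as.numeric(within_comparison_dissimilarity(p2$gd, p2$ct, cmp))
    if (is.na(before) || is.na(after)) next
    expect_lte(after, before + 1e-12)
  }
})

test_that("threshold lookup reproduces the published medians", {
  expect_equal(as.numeric(lookup_threshold("general", "general", "general")),
               0.13)
  th <- lookup_threshold("subjective", "pharm vs placebo/control", ">200")
  expect_equal(as.numeric(th), 0.28)
  expect_equal(attr(th, "interval"), c(0.0006, 0.95))
  expect_equal(as.numeric(
    lookup_threshold("all-cause mortality", "pharm vs pharm", "<50")), 0.0004)
  expect_equal(as.numeric(
    lookup_threshold("semi-objective", "non-pharmacological", "50-200")),
    0.06)
  expect_error(lookup_threshold("odd", "general", "general"), "options")
  expect_error(lookup_threshold("general", "pharm vs pharm", ">200"),
               "all three")
})

test_that("size bucket uses the unweighted mean of study sizes", {
  expect_equal(size_bucket(c(10, 20)), "<50")
  expect_equal(size_bucket(c(100, 200)), "50-200")
  expect_equal(size_bucket(c(100, 500)), ">200")
})

test_that("classification uses the strict below-threshold rule", {
  specs <- list(x = characteristic_spec("x", "quantitative"))
  ds <- study_dataset(c("s1", "s2", "s3", "s4"),
                      list(c("A", "B"), c("A", "B"), c("A", "C"),
                           c("A", "C")),
                      data.frame(x = c(0, 1, 4, 5)), specs)
  p <- pieces(ds)
  cm <- build_comparison_matrix(p$gd, p$ct)
  cl <- classify(cm, 0.28)
  expect_true(all(cl$labels %in% c("low", "likely_concerning")))
  # value 0.26 below threshold 0.28 -> low
  expect_equal(unname(cl$labels[cm$values < 0.28]),
               rep("low", sum(cm$values < 0.28)))
  # equality is not 'low'
  cl2 <- classify(cm, cm$values[1, 1])
  expect_equal(unname(cl2$labels[1, 1]), "likely_concerning")
  # all-zero matrix classifies entirely low
  cm0 <- cm; cm0$values[] <- 0
  expect_true(all(classify(cm0, 0.13)$labels == "low"))
  expect_error(classify(cm, 1.2), "threshold")
})
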