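#' Run the full transitivity evaluation pipeline
#'
#' Convenience wrapper chaining expansion, Gower matrix, comparison
#' dissimilarities, threshold classification, linkage selection, silhouette
#' profiling and fragmentation analysis.
#'
#' @param ds A [study_dataset()].
#' @param threshold Numeric threshold in (0,1), or `NULL` to derive it from
#'   the three design factors.
#' @param outcome,comparator,size_bucket Design factors for
#'   [lookup_threshold()] when `threshold` is `NULL`; all default to
#'   `"general"` (threshold 0.13).
#' @param linkage `"auto"` (select by cophenetic correlation) or one of
#'   [linkage_methods].
#' @param k `"auto"` (select by silhouette profile) or an integer cluster
#'   count.
#' @param k_max Upper end of the silhouette scan; default n-1.
#' @param seed Optional seed for randomized linkage tie-breaking.
#' @return Object of class `transitivity_analysis`: list with `dataset`,
#'   `comparison_table`, `gd` (`gd_matrix`), `D` (`classified_dissim`),
#'   `linkage` (list: method, ccc), `tree`, `profile`
#'   (`silhouette_profile`), `k`, `cluster_labels`, `fragmentation`.
#' @export
run_transitivity <- function(ds, threshold = NULL, outcome = "general",
                             comparator = "general", size_bucket = "general",
                             linkage = "auto", k = "auto", k_max = NULL,
                             seed = NULL) {
  stopifnot(inherits(ds, "study_dataset"))
  ct <- expand_comparisons(ds)
  gd <- build_dissimilarity_matrix(ct)
  cm <- build_comparison_matrix(gd, ct)
  if (is.null(threshold))
    threshold <- lookup_threshold(outcome, comparator, size_bucket)
  D <- classify(cm, threshold)
  sel <- if (identical(linkage, "auto")) {
    select_linkage(gd, seed = seed)
  } else {
    tr <- agglomerate(gd, linkage)
    list(method = linkage, tree = tr,
         ccc = stats::setNames(cophenetic_correlation(gd, tr), linkage))
  }
  profile <- silhouette_profile(gd, sel$tree, k_max = k_max)
  k_use <- if (identical(k, "auto")) profile$optimal_k else as.integer(k)
  labels <- partition_labels(profile, k_use)
  frag <- fragmented_comparisons(labels, ct)
  structure(
    list(dataset = ds, comparison_table = ct, gd = gd, D = D,
         linkage = sel[c("method", "ccc")], tree = sel$tree,
         profile = profile, k = k_use, cluster_labels = labels,
         fragmentation = frag),
    class = "transitivity_analysis"
  )
}

#' @export
print.transitivity_analysis <- function(x, ...) {
  cat("<transitivity_analysis>\n")
  print(x$dataset)
  print(x$D)
  cat(sprintf("  linkage: %s (CCC %.2f); partition: %d clusters (average silhouette width %.2f)\n",
              x$linkage$method, x$linkage$ccc[[x$linkage$method]], x$k,
              x$profile$avg_width[[as.character(x$k)]]))
  print(x$fragmentation)
  invisible(x)
}

#' Heatmap of the classified comparison dissimilarity matrix
#'
#' Cells are coloured strictly by their classification: green for "low"
#' (below the threshold), red for "likely concerning"; the dissimilarities
#' are printed at two decimal places.
#'
#' @param D A [classify()] result.
#' @return A ggplot object.
#' @export
plot_comparison_heatmap <- function(D) {
  stopifnot(inherits(D, "classified_dissim"))
  cmp <- rownames(D$values)
  df <- expand.grid(row = cmp, col = cmp, stringsAsFactors = FALSE)
  df$value <- as.vector(D$values)
  df$label <- as.vector(D$labels)
  df$row <- factor(df$row, levels = rev(cmp))
  df$col <- factor(df$col, levels = cmp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_fill_manual(
      values = c(low = "#2e9e4f", likely_concerning = "#d94545"),
      labels = c(low = "low", likely_concerning = "likely concerning"),
      name = sprintf("Dissimilarity\n(threshold %.2g)", D$threshold),
      na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dendrogram with integrated Gower heatmap
#'
#' @param gd A `gd_matrix`.
#' @param tree The [agglomerate()] tree.
#' @param k Cluster count used to gap the heatmap rows.
#' @param filename Optional output file (pheatmap writes it directly).
#' @return The pheatmap object, invisibly.
#' @export
plot_dendrogram_heatmap <- function(gd, tree, k, filename = NA) {
  stopifnot(inherits(gd, "gd_matrix"))
  ann <- data.frame(cluster = factor(stats::cutree(tree, k = k)),
                    row.names = gd$labels)
  ph <- pheatmap::pheatmap(
    gd$values, cluster_rows = tree, cluster_cols = tree,
    annotation_row = ann, cutree_rows = k, cutree_cols = k,
    show_rownames = nrow(gd$values) <= 40,
    show_colnames = FALSE, fontsize_row = 6,
    main = "Gower dissimilarities with dendrogram",
    silent = TRUE, filename = filename
  )
  invisible(ph)
}

#' Silhouette profile plot
#'
#' Overall average silhouette width against the number of clusters, with the
#' optimal partition highlighted.
#'
#' @param profile A `silhouette_profile`.
#' @return A ggplot object.
#' @export
plot_silhouette_profile <- function(profile) {
  df <- data.frame(k = profile$k, avg = as.numeric(profile$avg_width))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$avg)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$k == profile$optimal_k, , drop = FALSE],
                        colour = "#d94545", size = 3) +
    ggplot2::labs(x = "Number of clusters",
                  y = "Overall average silhouette width") +
    ggplot2::theme_minimal()
}

#' Per-observation silhouette width plot
#'
#' @param profile A `silhouette_profile`.
#' @param gd The `gd_matrix` (for labels).
#' @param k Cluster count; default the optimal one.
#' @return A ggplot object.
#' @export
plot_silhouette_widths <- function(profile, gd, k = profile$optimal_k) {
  j <- match(k, profile$k)
  if (is.na(j)) stop("k = ", k, " was not scanned", call. = FALSE)
  df <- data.frame(label = gd$labels, width = profile$widths[[j]],
                   cluster = factor(profile$labels[[j]]))
  df <- df[order(df$cluster, -df$width), , drop = FALSE]
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$width, y = .data$label,
                                   fill = .data$cluster)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("Silhouette width (k = %d)", k), y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Stacked bar plot of fragmented comparisons
#'
#' One bar per observed comparison, segments coloured by cluster and summing
#' to 100%; comparisons with more than one segment are "fragmented".
#'
#' @param frag A `fragmentation_report`.
#' @return A ggplot object.
#' @export
plot_fragmentation <- function(frag) {
  df <- frag$per_comparison
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$pct,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Studies per cluster (%)", fill = "Cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-cluster distribution of the characteristics
#'
#' Box plots (quantitative) and stacked proportion bars (categorical) of each
#' characteristic by cluster, for scrutinizing what separates the clusters.
#'
#' @param ana A `transitivity_analysis`.
#' @return Named list of ggplot objects, one per characteristic.
#' @export
plot_cluster_characteristics <- function(ana) {
  ct <- ana$comparison_table
  cl <- factor(ana$cluster_labels)
  lapply(stats::setNames(nm = names(ct$specs)), function(nm) {
    s <- ct$specs[[nm]]
    df <- data.frame(cluster = cl, value = ct$values[[nm]])
    df <- df[!is.na(df$value), , drop = FALSE]
    if (s$type == "quantitative") {
      ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$value)) +
        ggplot2::geom_boxplot(fill = "grey85") +
        ggplot2::labs(title = nm, x = "Cluster", y = nm) +
        ggplot2::theme_minimal()
    } else {
      df$value <- factor(df$value, levels = s$levels)
      ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster,
                                       fill = .data$value)) +
        ggplot2::geom_bar(position = "fill") +
        ggplot2::labs(title = nm, x = "Cluster", y = "Proportion",
                      fill = nm) +
        ggplot2::theme_minimal()
    }
  })
}

save_plot <- function(p, stem, outdir, width = 7, height = 5) {
  paths <- file.path(outdir, paste0(stem, c(".png", ".svg")))
  ggplot2::ggsave(paths[1], p, width = width, height = height, dpi = 150)
  # cairo-based SVG device from grDevices (svglite not required)
  ggplot2::ggsave(paths[2], p, width = width, height = height,
                  device = grDevices::svg)
  paths
}

#' Render the full report for a transitivity analysis
#'
#' Writes the visualization toolkit (Gower heatmap with dendrogram,
#' classified comparison heatmap, silhouette profile and width plots, stacked
#' fragmentation bars, per-cluster characteristic distributions), the matrix
#' CSVs and a machine-readable JSON summary. Output is deterministic for
#' identical inputs. For networks with more than 40 comparison-level rows the
#' dendrogram-heatmap is still produced but flagged `"appendix-scale"` in the
#' manifest, reflecting that it is better moved to an appendix.
#'
#' @param ana A [run_transitivity()] result.
#' @param outdir Output directory (created if needed).
#' @return The run manifest: named list of output paths (plus
#'   `dendrogram_heatmap_scale`), invisibly checked for existence.
#' @export
render_report <- function(ana, outdir) {
  if (!inherits(ana, "transitivity_analysis"))
    stop("render_report needs a completed transitivity_analysis; run ",
         "run_transitivity() first", call. = FALSE)
  for (part in c("gd", "D", "tree", "profile", "fragmentation"))
    if (is.null(ana[[part]]))
      stop("analysis object lacks stage '", part, "'", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  manifest$d_matrix_csv <- file.path(outdir, "gower_matrix.csv")
  write_matrix_csv(ana$gd, manifest$d_matrix_csv)
  manifest$D_matrix_csv <- file.path(outdir, "comparison_matrix.csv")
  write_matrix_csv(ana$D, manifest$D_matrix_csv)
  manifest$classification_csv <- file.path(outdir, "classification.csv")
  utils::write.csv(as.data.frame(ana$D$labels), manifest$classification_csv,
                   row.names = TRUE)
  manifest$D_heatmap <- save_plot(plot_comparison_heatmap(ana$D),
                                  "comparison_heatmap", outdir)
  dh_png <- file.path(outdir, "dendrogram_heatmap.png")
  plot_dendrogram_heatmap(ana$gd, ana$tree, ana$k, filename = dh_png)
  manifest$dendrogram_heatmap <- dh_png
  manifest$dendrogram_heatmap_scale <-
    if (nrow(ana$gd$values) > 40) "appendix-scale" else "main-text"
  manifest$silhouette_profile <- save_plot(
    plot_silhouette_profile(ana$profile), "silhouette_profile", outdir)
  manifest$silhouette_widths <- save_plot(
    plot_silhouette_widths(ana$profile, ana$gd, ana$k),
    "silhouette_widths", outdir)
  manifest$fragmentation_plot <- save_plot(
    plot_fragmentation(ana$fragmentation), "fragmentation", outdir)
  chars <- plot_cluster_characteristics(ana)
  manifest$cluster_characteristics <- unlist(lapply(names(chars), function(nm)
    save_plot(chars[[nm]], paste0("characteristic_", nm), outdir)))
  manifest$summary_json <- file.path(outdir, "summary.json")
  write_summary_json(ana, manifest$summary_json)
  missing <- !vapply(unlist(manifest[names(manifest) !=
                                       "dendrogram_heatmap_scale"]),
                     file.exists, logical(1))
  if (any(missing))
    warning("report files not produced: ",
            paste(names(missing)[missing], collapse = ", "), call. = FALSE)
  invisible(manifest)
}

#' Machine-readable summary of a transitivity analysis
#'
#' The JSON summary round-trips: [read_summary_json()] reconstructs the
#' comparison dissimilarity matrix and the classification labels exactly.
#'
#' @param ana A `transitivity_analysis`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(ana, path) {
  out <- list(
    comparisons = ana$D$comparisons,
    D_matrix = unname(apply(ana$D$values, 1L, as.numeric, simplify = FALSE)),
    threshold = ana$D$threshold,
    classification = unname(apply(ana$D$labels, 1L, as.character,
                                  simplify = FALSE)),
    linkage = ana$linkage$method,
    ccc = as.list(ana$linkage$ccc),
    optimal_k = ana$profile$optimal_k,
    k_used = ana$k,
    avg_silhouette_width = as.numeric(
      ana$profile$avg_width[[as.character(ana$k)]]),
    cluster_labels = stats::setNames(as.list(as.integer(ana$cluster_labels)),
                                     ana$gd$labels),
    fragmentation = list(
      fragmented = as.list(ana$fragmentation$fragmented),
      eloping_pct = as.list(ana$fragmentation$eloping_pct),
      n_clusters = ana$fragmentation$n_clusters,
      scenario = ana$fragmentation$scenario
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_summary_json
#' @return `read_summary_json`: the parsed summary with `D_matrix` and
#'   `classification` restored as named matrices.
#' @export
read_summary_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cmp <- x$comparisons
  x$D_matrix <- matrix(unlist(x$D_matrix), length(cmp), byrow = TRUE,
                       dimnames = list(cmp, cmp))
  x$classification <- matrix(unlist(x$classification), length(cmp),
                             byrow = TRUE, dimnames = list(cmp, cmp))
  x
}
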