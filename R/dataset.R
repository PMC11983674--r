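#' Assemble a study-level dataset for one treatment network
#'
#' Bundles the per-study treatment arms with the extracted characteristic
#' values and their specifications, validating types, levels and network
#' structure. This is the central input container of the package: one row per
#' study of a connected network, with mixed-type characteristic columns that
#' may contain missing values.
#'
#' @param study_id Character vector of unique study identifiers.
#' @param arms List of character vectors, one per study, each with at least
#'   two distinct treatment labels.
#' @param values Data frame of characteristic values (one row per study, one
#'   column per characteristic); `NA` marks a missing cell. Categorical values
#'   are stored as character and must match the declared levels.
#' @param specs Named list of [characteristic_spec()] objects covering every
#'   column of `values`.
#' @return An object of class `study_dataset` with elements `study_id`,
#'   `arms`, `values`, `specs`.
#' @export
study_dataset <- function(study_id, arms, values, specs) {
  study_id <- as.character(study_id)
  n <- length(study_id)
  if (n < 2L) stop("a network needs at least two studies", call. = FALSE)
  if (anyDuplicated(study_id))
    stop("duplicate study_id: ",
         paste(unique(study_id[duplicated(study_id)]), collapse = ", "),
         call. = FALSE)
  if (!is.list(arms) || length(arms) != n)
    stop("arms must be a list with one entry per study", call. = FALSE)
  arms <- lapply(arms, as.character)
  for (i in seq_len(n)) {
    a <- arms[[i]]
    if (length(a) < 2L)
      stop("study '", study_id[i], "': fewer than two arms", call. = FALSE)
    if (anyDuplicated(a))
      stop("study '", study_id[i], "': duplicated treatment arms",
           call. = FALSE)
  }
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (nrow(values) != n)
    stop("values must have one row per study", call. = FALSE)
  unknown <- setdiff(names(values), names(specs))
  if (length(unknown))
    stop("characteristic column(s) without specification: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing_cols <- setdiff(names(specs), names(values))
  if (length(missing_cols))
    stop("configured characteristic(s) absent from the table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  values <- values[names(specs)]         # fix column order to the specs
  for (nm in names(specs)) {
    s <- specs[[nm]]
    col <- values[[nm]]
    if (s$type == "quantitative") {
      if (is.character(col)) {
        num <- suppressWarnings(as.numeric(col))
        bad <- which(!is.na(col) & nzchar(trimws(col)) & is.na(num))
        if (length(bad))
          stop("characteristic '", nm, "': non-numeric value '", col[bad[1]],
               "' in study '", study_id[bad[1]], "'", call. = FALSE)
        col <- num
      }
      values[[nm]] <- as.numeric(col)
    } else {
      col <- as.character(col)
      bad <- which(!is.na(col) & !(col %in% s$levels))
      if (length(bad))
        stop("characteristic '", nm, "': value '", col[bad[1]],
             "' in study '", study_id[bad[1]], "' outside declared levels (",
             paste(s$levels, collapse = ", "), ")", call. = FALSE)
      values[[nm]] <- col
    }
  }
  rownames(values) <- study_id
  ds <- structure(
    list(study_id = study_id, arms = arms, values = values, specs = specs),
    class = "study_dataset"
  )
  if (!network_is_connected(ds))
    warning("the treatment network implied by the arms is not connected",
            call. = FALSE)
  ds
}

#' @export
print.study_dataset <- function(x, ...) {
  trts <- sort(unique(unlist(x$arms)))
  cat(sprintf("<study_dataset> %d studies, %d treatments, %d characteristics\n",
              length(x$study_id), length(trts), length(x$specs)))
  cat("  treatments:", paste(trts, collapse = ", "), "\n")
  mf <- missing_fraction(x)
  cat(sprintf("  missing cells: %.2f%%\n", 100 * mf))
  invisible(x)
}

#' Number of studies, characteristics and treatments
#'
#' @param ds A `study_dataset`.
#' @return Named integer vector with `studies`, `treatments`,
#'   `characteristics`, `comparisons` (distinct observed treatment pairs).
#' @export
network_size <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  pairs <- unique(unlist(lapply(ds$arms, function(a) {
    a <- sort(a)
    utils::combn(a, 2L, paste, collapse = " vs ")
  })))
  c(studies = length(ds$study_id),
    treatments = length(unique(unlist(ds$arms))),
    characteristics = length(ds$specs),
    comparisons = length(pairs))
}

#' Fraction of missing characteristic cells
#'
#' @param ds A `study_dataset` or `comparison_table`. For a comparison table
#'   the fraction is computed over the expanded rows, so a multi-arm study
#'   with a missing cell counts once per contributed comparison.
#' @return Proportion of missing cells in \[0, 1\].
#' @export
missing_fraction <- function(ds) {
  v <- ds$values
  mean(is.na(as.matrix(v)))
}

# Breadth-first search over the treatment graph defined by the study arms.
network_is_connected <- function(ds) {
  trts <- unique(unlist(ds$arms))
  if (length(trts) <= 1L) return(TRUE)
  adj <- stats::setNames(vector("list", length(trts)), trts)
  for (a in ds$arms)
    for (t in a) adj[[t]] <- union(adj[[t]], setdiff(a, t))
  seen <- trts[1L]
  frontier <- trts[1L]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(trts)
}

#' Read an extraction table and its characteristic configuration
#'
#' The table is a CSV (UTF-8, header row) with a `study_id` column, the
#' treatment arms either wide (`arm1`, `arm2`, ...) or as a single `arms`
#' column with `;`-delimited labels, and one column per configured
#' characteristic. Cells equal to one of `na_tokens` (after trimming) are
#' read as missing.
#'
#' @param table_path Path to the CSV extraction table.
#' @param config_path Path to the YAML characteristic configuration
#'   (see [read_char_config()]).
#' @param na_tokens Strings parsed as missing; default `""`, `"NA"`, `"NaN"`.
#' @return A validated [study_dataset()].
#' @export
load_dataset <- function(table_path, config_path,
                         na_tokens = c("", "NA", "NaN")) {
  specs <- read_char_config(config_path)
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!"study_id" %in% names(tab))
    stop("table has no 'study_id' column", call. = FALSE)
  for (nm in names(tab))
    tab[[nm]][trimws(tab[[nm]]) %in% na_tokens] <- NA_character_
  arm_cols <- grep("^arm[0-9]+$", names(tab), value = TRUE)
  if ("arms" %in% names(tab)) {
    arms <- lapply(strsplit(tab$arms, ";", fixed = TRUE),
                   function(a) trimws(a[nzchar(trimws(a))]))
    used <- c("study_id", "arms")
  } else if (length(arm_cols)) {
    arm_cols <- arm_cols[order(as.integer(sub("^arm", "", arm_cols)))]
    arms <- lapply(seq_len(nrow(tab)), function(i) {
      a <- unlist(tab[i, arm_cols], use.names = FALSE)
      a[!is.na(a)]
    })
    used <- c("study_id", arm_cols)
  } else {
    stop("table needs either an 'arms' column or wide arm1..armK columns",
         call. = FALSE)
  }
  extra <- setdiff(names(tab), c(used, names(specs)))
  if (length(extra))
    stop("unknown column(s) in table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  study_dataset(tab$study_id, arms, tab[setdiff(names(tab), used)], specs)
}

#' Write a study dataset back to CSV + YAML
#'
#' Writes the extraction table (wide arm columns) and the characteristic
#' configuration so that [load_dataset()] on the two files reproduces the
#' dataset.
#'
#' @param ds A `study_dataset`.
#' @param table_path,config_path Output paths.
#' @return `table_path`, invisibly.
#' @export
write_dataset <- function(ds, table_path, config_path) {
  k <- max(lengths(ds$arms))
  armmat <- t(vapply(ds$arms, function(a) c(a, rep(NA_character_, k - length(a))),
                     character(k)))
  colnames(armmat) <- paste0("arm", seq_len(k))
  out <- cbind(data.frame(study_id = ds$study_id, stringsAsFactors = FALSE),
               as.data.frame(armmat, stringsAsFactors = FALSE), ds$values)
  utils::write.csv(out, table_path, row.names = FALSE, na = "")
  write_char_config(ds$specs, config_path)
  invisible(table_path)
}
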