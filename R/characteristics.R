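#' Declare a study-level characteristic
#'
#' A characteristic specification describes one column of the extraction
#' table: its measurement type, the weight it carries in the weighted Gower
#' coefficient, the ordered level set (for categorical types) and an optional
#' user-supplied range replacing the observed one (for quantitative types).
#'
#' Several summary statistics of one underlying quantity (e.g., the minimum
#' and maximum of a mean lung-function measure) can be tied together through
#' `summary_group`; [normalize_weights()] then rescales their weights to sum
#' to 1 so the underlying characteristic contributes once to the Gower
#' coefficient.
#'
#' @param name Column name in the extraction table.
#' @param type One of `"quantitative"`, `"binary"`, `"nominal"`, `"ordinal"`.
#' @param weight Nonnegative weight \eqn{w_i}; default 1.
#' @param levels Character vector of category labels. Required for nominal and
#'   ordinal characteristics (at least two); for ordinal characteristics the
#'   order given here defines the ranks.
#' @param range Optional positive value replacing the observed range
#'   \eqn{R_i} of a quantitative characteristic (e.g., a range taken from the
#'   review's inclusion criteria rather than the collected studies).
#' @param summary_group Optional tag shared by the specifications of several
#'   summary statistics of one underlying characteristic.
#'
#' @return An object of class `characteristic_spec`.
#' @seealso [read_char_config()], [gower_distance()]
#' @export
#' @examples
#' characteristic_spec("mean_age", "quantitative")
#' characteristic_spec("ra_duration", "ordinal",
#'                     levels = c("early", "established", "late"))
characteristic_spec <- function(name, type, weight = 1, levels = NULL,
                                range = NULL, summary_group = NULL) {
  type <- match.arg(type, c("quantitative", "binary", "nominal", "ordinal"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) || weight < 0)
    stop("characteristic '", name, "': weight must be a nonnegative number",
         call. = FALSE)
  if (type %in% c("nominal", "ordinal", "binary")) {
    if (type == "binary" && is.null(levels)) levels <- c("no", "yes")
    if (is.null(levels) || length(levels) < 2L)
      stop("characteristic '", name, "': ", type,
           " type needs at least 2 declared levels", call. = FALSE)
    levels <- as.character(levels)
    if (anyDuplicated(levels))
      stop("characteristic '", name, "': duplicated levels", call. = FALSE)
  } else if (!is.null(levels)) {
    stop("characteristic '", name, "': levels are only meaningful for ",
         "categorical types", call. = FALSE)
  }
  if (!is.null(range)) {
    if (type != "quantitative")
      stop("characteristic '", name,
           "': range override applies to quantitative type only", call. = FALSE)
    if (!is.numeric(range) || length(range) != 1L || is.na(range) || range <= 0)
      stop("characteristic '", name, "': range override must be > 0",
           call. = FALSE)
  }
  structure(
    list(name = name, type = type, weight = weight, levels = levels,
         range = range, summary_group = summary_group),
    class = "characteristic_spec"
  )
}

#' @export
print.characteristic_spec <- function(x, ...) {
  cat(sprintf("<characteristic_spec> %s (%s), weight %g", x$name, x$type,
              x$weight))
  if (!is.null(x$levels))
    cat(": ", paste(x$levels, collapse = if (x$type == "ordinal") " < " else ", "),
        sep = "")
  if (!is.null(x$range)) cat(", range ", x$range, sep = "")
  if (!is.null(x$summary_group))
    cat(" [group ", x$summary_group, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Normalize weights within summary groups
#'
#' Within each `summary_group` the member weights are rescaled so that they
#' sum to 1: a characteristic reported through several summary statistics then
#' contributes to the Gower coefficient with the same total weight as a
#' characteristic reported once.
#'
#' @param specs List of [characteristic_spec()] objects.
#' @return The list with rescaled weights.
#' @export
normalize_weights <- function(specs) {
  groups <- vapply(specs, function(s)
    if (is.null(s$summary_group)) NA_character_ else s$summary_group,
    character(1))
  for (g in unique(groups[!is.na(groups)])) {
    idx <- which(groups == g)
    tot <- sum(vapply(specs[idx], function(s) s$weight, numeric(1)))
    if (tot <= 0)
      stop("summary group '", g, "': member weights sum to 0", call. = FALSE)
    for (i in idx) specs[[i]]$weight <- specs[[i]]$weight / tot
  }
  specs
}

#' Read a characteristic configuration file
#'
#' The configuration is a YAML file with a top-level `characteristics` list;
#' each entry has keys `name`, `type` and optionally `weight`, `levels`,
#' `range`, `summary_group`. Weights within a `summary_group` are normalized
#' to sum to 1 on loading.
#'
#' @param path Path to the YAML file.
#' @return A named list of `characteristic_spec` objects.
#' @export
read_char_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$characteristics)) cfg$characteristics else cfg
  if (!length(entries)) stop("empty characteristic configuration", call. = FALSE)
  specs <- lapply(entries, function(e) {
    if (is.null(e$name) || is.null(e$type))
      stop("each characteristic entry needs 'name' and 'type'", call. = FALSE)
    characteristic_spec(
      name = e$name, type = e$type,
      weight = if (is.null(e$weight)) 1 else e$weight,
      levels = if (is.null(e$levels)) NULL else as.character(e$levels),
      range = e$range,
      summary_group = e$summary_group
    )
  })
  specs <- normalize_weights(specs)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs)))
    stop("duplicated characteristic names in configuration", call. = FALSE)
  specs
}

#' Write a characteristic configuration file
#'
#' Inverse of [read_char_config()] (weights are written as normalized).
#'
#' @param specs Named list of `characteristic_spec` objects.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_char_config <- function(specs, path) {
  entries <- lapply(specs, function(s) {
    e <- list(name = s$name, type = s$type, weight = s$weight)
    if (!is.null(s$levels)) e$levels <- s$levels
    if (!is.null(s$range)) e$range <- s$range
    if (!is.null(s$summary_group)) e$summary_group <- s$summary_group
    e
  })
  yaml::write_yaml(list(characteristics = unname(entries)), path)
  invisible(path)
}
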