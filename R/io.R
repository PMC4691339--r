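#' Read an item table from TSV
#'
#' Reads a tab-separated item table with header columns `id`, `est_value`,
#' `est_time` and optionally `duplicate_key`, `true_value`, `p_tp`,
#' `gold_label`, `redundant`. Every row is validated; violations are
#' reported with the offending row number and column name.
#'
#' @param path Path to the TSV file.
#' @return A validated [item_table()] data frame.
#' @export
read_items <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""),
                           colClasses = "character")
  req <- c("id", "est_value", "est_time")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    stop(path, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(col) {
    if (is.null(raw[[col]])) return(NULL)
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(x))
    if (length(bad) > 0) {
      stop(sprintf("%s: row %s, column %s: not a number ('%s')", path,
                   paste(bad, collapse = ","), col,
                   raw[[col]][bad[1]]), call. = FALSE)
    }
    x
  }
  items <- data.frame(id = raw$id, stringsAsFactors = FALSE)
  items$duplicate_key <- if (!is.null(raw$duplicate_key)) raw$duplicate_key
  for (col in c("true_value", "est_value", "p_tp", "est_time")) {
    v <- parse_num(col)
    if (!is.null(v)) items[[col]] <- v
  }
  if (!is.null(raw$gold_label)) items$gold_label <- raw$gold_label
  if (!is.null(raw$redundant)) {
    items$redundant <- toupper(raw$redundant) %in% c("TRUE", "T", "1")
  }
  check_col <- function(col, bad, what) {
    if (length(bad) > 0) {
      stop(sprintf("%s: row %s, column %s: %s", path,
                   paste(bad, collapse = ","), col, what), call. = FALSE)
    }
  }
  check_col("id", which(is.na(items$id) | !nzchar(items$id)), "empty id")
  check_col("id", which(duplicated(items$id)), "duplicate id")
  check_col("est_time",
            which(is.na(items$est_time) | items$est_time <= 0),
            "must be a positive time")
  if (!is.null(items$p_tp)) {
    check_col("p_tp",
              which(!is.na(items$p_tp) &
                      (items$p_tp < 0 | items$p_tp > 1)),
              "probability outside [0, 1]")
  }
  if (!is.null(items$gold_label)) {
    check_col("gold_label",
              which(!is.na(items$gold_label) &
                      !items$gold_label %in% c("TP", "FP")),
              "must be TP or FP")
  }
  item_table(items)
}

#' Write an item table to TSV
#'
#' Inverse of [read_items()]: the write-then-read round trip is lossless
#' for every field.
#'
#' @param items An [item_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_items <- function(items, path) {
  items <- item_table(items)
  out <- items
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 17, scientific = FALSE,
                                trim = TRUE))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

json_field_error <- function(path, field, what) {
  stop(sprintf("%s: field '%s': %s", path, field, what), call. = FALSE)
}

#' Read a toolbox of strategies from JSON
#'
#' Expected schema:
#' `{"fixed": [{"name", "precision", "recall", "cost"}, ...],
#'   "adjustable": [{"name", "curve": [[recall, precision], ...], "cost"},
#'   ...]}`. Both lists are optional; `cost` defaults to 0. Violations are
#' reported with the offending field.
#'
#' @param path Path to the JSON file.
#' @return A [toolbox()].
#' @export
read_toolbox <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  strategies <- list()
  for (i in seq_along(spec$fixed)) {
    s <- spec$fixed[[i]]
    field <- sprintf("fixed[%d]", i)
    for (f in c("name", "precision", "recall")) {
      if (is.null(s[[f]])) json_field_error(path, paste0(field, ".", f),
                                            "missing")
    }
    strategies[[length(strategies) + 1L]] <- tryCatch(
      strategy_point(s$name, s$precision, s$recall,
                     cost = if (is.null(s$cost)) 0 else s$cost),
      error = function(e) json_field_error(path, field, conditionMessage(e)))
  }
  for (i in seq_along(spec$adjustable)) {
    s <- spec$adjustable[[i]]
    field <- sprintf("adjustable[%d]", i)
    if (is.null(s$name)) json_field_error(path, paste0(field, ".name"),
                                          "missing")
    if (is.null(s$curve)) json_field_error(path, paste0(field, ".curve"),
                                           "missing")
    curve <- do.call(rbind, lapply(s$curve, unlist))
    strategies[[length(strategies) + 1L]] <- tryCatch(
      adjustable_strategy(s$name, curve,
                          cost = if (is.null(s$cost)) 0 else s$cost),
      error = function(e) json_field_error(path, field, conditionMessage(e)))
  }
  if (length(strategies) == 0) {
    stop(path, ": toolbox defines no strategies", call. = FALSE)
  }
  do.call(toolbox, strategies)
}

#' Read a curation project from JSON + TSV
#'
#' Expected schema: `{"name", "t_max", "speed" (optional),
#' "scale": {"w_min", "w_max"}, "items": "<path to item TSV>"}`. A relative
#' item path is resolved against the JSON file's directory.
#'
#' @param path Path to the project JSON file.
#' @return A [curation_project()].
#' @export
read_project <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("name", "t_max", "items")) {
    if (is.null(spec[[f]])) json_field_error(path, f, "missing")
  }
  sc <- if (is.null(spec$scale)) value_scale() else {
    if (is.null(spec$scale$w_min) || is.null(spec$scale$w_max)) {
      json_field_error(path, "scale", "needs w_min and w_max")
    }
    value_scale(spec$scale$w_min, spec$scale$w_max)
  }
  items_path <- spec$items
  if (!file.exists(items_path)) {
    items_path <- file.path(dirname(path), spec$items)
  }
  curation_project(spec$name, read_items(items_path), t_max = spec$t_max,
                   speed = spec$speed, scale = sc)
}

#' Build a machine-readable report
#'
#' Packages a computation's results as a schema-stable report: a `metrics`
#' block holding full-precision fractions, a `display` block with the same
#' quantities rendered as whole percentages (rounded half away from zero,
#' so 0.3888... displays as 39), a `decisions` block for chosen strategies,
#' schedules or allocations, and a provenance block.
#'
#' @param metrics Named list of metric fractions.
#' @param decisions Named list describing decisions taken (optional).
#' @param inputs Named list describing inputs (optional).
#' @param seed Seed used, if any.
#' @return An object of class `rocur_report`.
#' @export
build_report <- function(metrics, decisions = NULL, inputs = NULL,
                         seed = NULL) {
  stopifnot(is.list(metrics))
  num <- vapply(metrics, function(x) is.numeric(x) && length(x) == 1L, TRUE)
  # rates are per-time quantities, not fractions: display them unscaled
  is_rate <- grepl("rate", names(metrics), fixed = TRUE)
  display <- mapply(function(x, rate) {
    if (rate) format(signif(x, 4), scientific = FALSE)
    else if (is.finite(x)) paste0(percent_value(x), "%")
    else "Inf%"
  }, metrics[num], is_rate[num], SIMPLIFY = FALSE)
  structure(list(
    inputs = inputs,
    metrics = metrics,
    display = display,
    decisions = decisions,
    provenance = list(
      package = "rocur",
      version = as.character(utils::packageVersion("rocur")),
      seed = seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "rocur_report")
}

#' Write a report as JSON
#'
#' @param report A [build_report()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "rocur_report"))
  payload <- unclass(report)
  # JSON has no Inf: encode infinite overheads as the string "Inf"
  payload$metrics <- lapply(payload$metrics, function(x) {
    if (is.numeric(x) && length(x) == 1L && is.infinite(x)) "Inf" else x
  })
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.rocur_report <- function(x, ...) {
  cat("<rocur_report>\n")
  for (nm in names(x$display)) {
    cat(sprintf("  %s: %s\n", nm, x$display[[nm]]))
  }
  invisible(x)
}
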