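#' Assemble a validation-study dataset
#'
#' Builds the canonical long-format container for an in-house validation
#' study: one row per measurement, identified by block (factor-level
#' combination), known concentration, and replicate.  Each block must map to
#' exactly one combination of the design factors (a crossed two-level table
#' is the typical case), and every (block, concentration, replicate) key
#' must be unique.
#'
#' @param data data.frame with columns `block`, `known_x`, `y`, optionally
#'   `replicate` (defaults to 1), plus one column per design factor.
#' @param factors character vector naming the design-factor columns.  When
#'   `NULL`, every column other than `block`, `known_x`, `replicate`, `y`
#'   is treated as a factor.
#' @param units free-text concentration unit label, e.g. `"ug/kg"`; carried
#'   through unchanged, never converted.
#' @return A `validation_data` object (a data.frame with attributes
#'   `factors` and `units`).
#' @seealso [study_dims()], [read_validation_csv()], [validation_example()]
#' @export
#' @examples
#' d <- data.frame(block = rep(1:4, each = 2),
#'                 oper  = rep(c("a", "b"), each = 4),
#'                 known_x = rep(c(1, 10), 4),
#'                 y = c(1.1, 9.8, 0.9, 10.4, 1.0, 10.1, 1.2, 9.7))
#' vd <- validation_data(d, factors = "oper", units = "ug/kg")
#' study_dims(vd)
validation_data <- function(data, factors = NULL, units = "") {
  if (!is.data.frame(data)) stop("`data` must be a data.frame")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(data) == 0L) stop("no records")
  core <- c("block", "known_x", "replicate", "y")
  missing_cols <- setdiff(c("block", "known_x", "y"), names(data))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(data$replicate)) data$replicate <- 1L
  if (is.null(factors)) factors <- setdiff(names(data), core)
  absent <- setdiff(factors, names(data))
  if (length(absent))
    stop("factor column(s) not found: ", paste(absent, collapse = ", "))

  data$block <- as.character(data$block)
  for (f in factors) data[[f]] <- as.character(data[[f]])
  if (!is.numeric(data$known_x)) stop("`known_x` must be numeric")
  if (!is.numeric(data$y)) stop("`y` (response) must be numeric")
  if (anyNA(data$y) || anyNA(data$known_x))
    stop("missing values in `known_x` or `y`")
  if (any(data$known_x <= 0)) stop("all `known_x` values must be > 0")
  data$replicate <- as.integer(data$replicate)
  if (any(data$replicate < 1L)) stop("`replicate` must be a positive integer")

  key <- paste(data$block, data$known_x, data$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (block, known_x, replicate) key: ",
         gsub("\r", " / ", dup))
  }
  # each block carries exactly one factor-level combination
  if (length(factors)) {
    combo <- do.call(paste, c(data[factors], sep = "\r"))
    bad <- tapply(combo, data$block, function(z) length(unique(z)) > 1L)
    if (any(bad))
      stop("block(s) mapped to more than one factor-level combination: ",
           paste(names(bad)[bad], collapse = ", "))
  }

  data <- data[c("block", factors, "known_x", "replicate", "y")]
  structure(data, factors = factors, units = units,
            class = c("validation_data", "data.frame"))
}

#' Design dimensions of a validation study
#'
#' @param x a [validation_data()] object.
#' @return list with `m` (concentration levels), `n` (blocks / factor-level
#'   combinations), `p` (replicates per cell), `q` (number of factors) and
#'   `n_obs` (total records).
#' @export
study_dims <- function(x) {
  stopifnot(inherits(x, "validation_data"))
  cell <- paste(x$block, x$known_x)
  list(m = length(unique(x$known_x)),
       n = length(unique(x$block)),
       p = max(table(cell)),
       q = length(attr(x, "factors")),
       n_obs = nrow(x))
}

#' @export
print.validation_data <- function(x, ...) {
  d <- study_dims(x)
  u <- attr(x, "units")
  cat(sprintf(
    "Validation study: %d records (m = %d levels, n = %d blocks, p = %d)\n",
    d$n_obs, d$m, d$n, d$p))
  cat("Factors:", if (d$q) paste(attr(x, "factors"), collapse = ", ")
      else "(none)", "\n")
  if (nzchar(u)) cat("Units:", u, "\n")
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read a validation study from CSV
#'
#' Accepts the canonical long layout (one row per measurement) or the wide
#' layout in which each known concentration occupies its own column, as
#' validation reports usually print it.  Wide level columns are identified
#' either through `level_cols` or by a concentration given in parentheses
#' in the column name (e.g. `"CL 01 (25)"`) or by a purely numeric column
#' name.  Files are UTF-8, comma-separated, decimal point, header required.
#'
#' @param path file path.
#' @param format `"long"` or `"wide"`.
#' @param block_col,x_col,y_col,replicate_col column names in the file.
#' @param factor_cols design-factor columns; default: all unclaimed columns.
#' @param level_cols for wide input, a named numeric vector mapping column
#'   name to concentration; `NULL` for auto-detection.
#' @param units unit label stored on the result.
#' @return a [validation_data()] object.
#' @export
read_validation_csv <- function(path, format = c("long", "wide"),
                                block_col = "block", x_col = "known_x",
                                y_col = "y", replicate_col = "replicate",
                                factor_cols = NULL, level_cols = NULL,
                                units = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  # block labels are identifiers: read as character so "01" survives
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = setNames("character", block_col))
  if (nrow(raw) == 0L) stop("no records in ", path)

  if (format == "long") {
    need <- c(block_col, x_col, y_col)
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
    if (!is.numeric(raw[[y_col]]))
      stop("response column `", y_col, "` is not numeric")
    d <- data.frame(block = raw[[block_col]], known_x = raw[[x_col]],
                    y = raw[[y_col]], stringsAsFactors = FALSE)
    d$replicate <- if (replicate_col %in% names(raw))
      raw[[replicate_col]] else 1L
    if (is.null(factor_cols))
      factor_cols <- setdiff(names(raw),
                             c(block_col, x_col, y_col, replicate_col))
    for (f in factor_cols) d[[f]] <- raw[[f]]
    return(validation_data(d, factors = factor_cols, units = units))
  }

  # wide: melt level columns
  if (!block_col %in% names(raw))
    stop("missing column(s) in ", path, ": ", block_col)
  if (is.null(level_cols)) {
    cand <- setdiff(names(raw), c(block_col, factor_cols))
    xs <- vapply(cand, function(nm) {
      inpar <- regmatches(nm, regexpr("\\(([0-9.eE+-]+)\\)", nm))
      if (length(inpar)) as.numeric(gsub("[()]", "", inpar))
      else suppressWarnings(as.numeric(nm))
    }, numeric(1))
    level_cols <- xs[!is.na(xs)]
    if (!length(level_cols))
      stop("could not identify concentration level columns in ", path)
  }
  if (is.null(factor_cols))
    factor_cols <- setdiff(names(raw), c(block_col, names(level_cols)))
  long <- do.call(rbind, lapply(names(level_cols), function(nm) {
    if (!is.numeric(raw[[nm]]))
      stop("response column `", nm, "` is not numeric")
    d <- data.frame(block = raw[[block_col]], known_x = level_cols[[nm]],
                    replicate = 1L, y = raw[[nm]], stringsAsFactors = FALSE)
    for (f in factor_cols) d[[f]] <- raw[[f]]
    d
  }))
  validation_data(long, factors = factor_cols, units = units)
}

#' Write a validation study to CSV (canonical long layout)
#'
#' @param x a [validation_data()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_validation_csv <- function(x, path) {
  stopifnot(inherits(x, "validation_data"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Bundled example validation studies
#'
#' Two published in-house validation studies shipped with the package:
#' `"thiamphenicol_milk"` (4 concentration levels x 8 blocks, factors batch,
#' storage, technician, mixer) and `"clopidol_egg"` (6 levels x 8 blocks,
#' factors breeding, operator, HPLC batch, extract storage).  Both use a
#' crossed two-level factorial design with one replicate per cell and
#' concentrations in ug/kg.
#'
#' @param name `"thiamphenicol_milk"` or `"clopidol_egg"`.
#' @return a [validation_data()] object.
#' @export
#' @examples
#' vd <- validation_example("thiamphenicol_milk")
#' study_dims(vd)
validation_example <- function(name = c("thiamphenicol_milk",
                                        "clopidol_egg")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "asymuncert", mustWork = TRUE)
  fac <- switch(name,
    thiamphenicol_milk = c("batch", "storage", "technician", "mixer"),
    clopidol_egg = c("breeding", "operator", "hplc", "extract_storage"))
  read_validation_csv(path, format = "wide", factor_cols = fac,
                      units = "ug/kg")
}

#' Published variance-component estimates for the example studies
#'
#' The variance-component tables published alongside the two example
#' studies, for use as reference inputs to the precision arithmetic without
#' refitting (refitting with [fit_uncertainty_model()] reproduces them to
#' within estimator ambiguity).
#'
#' @inheritParams validation_example
#' @return a [variance_components()] object.
#' @export
published_components <- function(name = c("thiamphenicol_milk",
                                          "clopidol_egg")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_components.csv"),
                      package = "asymuncert", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  variance_components(tab$term, tab$const_var, tab$prop_var)
}
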