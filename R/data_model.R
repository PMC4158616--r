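#' Variable metadata
#'
#' Describes one data variable of a case table: its scale of measurement,
#' its (ordered) domain and the number of distinct non-missing values.
#' The scale and distinct-value count are the two pieces of meta information
#' the mapping validator compares against a visual slot's capabilities.
#'
#' @param name Variable name (single string).
#' @param scale One of `"nominal"`, `"ordinal"`, `"interval"`,
#'   `"continuous"`.
#' @param domain For nominal/ordinal scales a character vector of category
#'   tokens (order is meaningful and total for ordinal); for
#'   interval/continuous a numeric `c(min, max)` range.
#' @param distinct_count Number of distinct observed non-missing values.
#' @param missing_count Number of missing values observed.
#' @return An object of class `variable_meta`.
#' @export
variable_meta <- function(name, scale, domain, distinct_count,
                          missing_count = 0L) {
  scale <- match.arg(scale, c("nominal", "ordinal", "interval", "continuous"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            distinct_count >= 0, missing_count >= 0)
  if (scale %in% c("nominal", "ordinal")) {
    domain <- as.character(domain)
    if (anyDuplicated(domain))
      stop("domain of '", name, "' contains duplicated categories")
  } else {
    domain <- as.numeric(domain)
    if (length(domain) != 2L || any(is.na(domain)) || domain[1] > domain[2])
      stop("numeric domain of '", name, "' must be c(min, max)")
  }
  structure(
    list(name = name, scale = scale, domain = domain,
         distinct_count = as.integer(distinct_count),
         missing_count = as.integer(missing_count)),
    class = "variable_meta")
}

#' @export
print.variable_meta <- function(x, ...) {
  dom <- if (x$scale %in% c("nominal", "ordinal"))
    paste0("{", paste(utils::head(x$domain, 6), collapse = ", "),
           if (length(x$domain) > 6) ", ..." else "", "}")
  else sprintf("[%g, %g]", x$domain[1], x$domain[2])
  cat(sprintf("<variable_meta> %s: %s %s, %d distinct, %d missing\n",
              x$name, x$scale, dom, x$distinct_count, x$missing_count))
  invisible(x)
}

#' Case dataset container
#'
#' A dataset is an ordered table of case records plus per-variable metadata.
#' Record order is significant and preserved throughout: the database order
#' of the cases is itself used as a layout in the mass (pixel-level) view.
#' Missing values are represented as `NA` in every column.
#'
#' @param records A data.frame; character or numeric columns, `NA` = missing.
#' @param variables Optional named list of [variable_meta()] objects, one per
#'   column; inferred with [infer_variable_meta()] when omitted.
#' @param declared_scales Optional named character vector of scales used when
#'   inferring metadata.
#' @param declared_orders Optional named list of ordered category vectors for
#'   ordinal variables (ordinal scales are never inferred, only declared).
#' @param provenance Free-text source tag.
#' @return An object of class `glyph_dataset`.
#' @export
glyph_dataset <- function(records, variables = NULL, declared_scales = NULL,
                          declared_orders = NULL, provenance = "") {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(names(records)))
    stop("duplicate variable names: ",
         paste(unique(names(records)[duplicated(names(records))]),
               collapse = ", "))
  ds <- structure(
    list(records = records, variables = list(), provenance = provenance),
    class = "glyph_dataset")
  pick <- function(decl, v)
    if (!is.null(names(decl)) && v %in% names(decl)) decl[[v]] else NULL
  if (is.null(variables)) {
    variables <- lapply(names(records), function(v)
      infer_variable_meta(ds, v,
                          declared_scale = pick(declared_scales, v),
                          declared_order = pick(declared_orders, v)))
    names(variables) <- names(records)
  } else {
    if (!setequal(names(variables), names(records)))
      stop("metadata must cover exactly the record variables")
    variables <- variables[names(records)]
  }
  ds$variables <- variables
  ds
}

#' @export
print.glyph_dataset <- function(x, ...) {
  cat(sprintf("<glyph_dataset> %d records x %d variables%s\n",
              nrow(x$records), length(x$variables),
              if (nzchar(x$provenance)) paste0("  [", x$provenance, "]")
              else ""))
  for (v in x$variables) print(v)
  invisible(x)
}

#' @export
dim.glyph_dataset <- function(x) dim(x$records)

#' Infer (or apply declared) metadata for one variable
#'
#' Inference rules: a declared scale always wins; otherwise a column whose
#' non-missing values are all numeric is `continuous`, anything else is
#' `nominal`. Ordinal scales are never inferred from lexical order -- silent
#' ordinal inference is exactly the misinterpretation hazard the mapping
#' validator exists to catch -- so an ordinal variable requires both
#' `declared_scale = "ordinal"` and a total `declared_order`.
#'
#' @param dataset A [glyph_dataset()].
#' @param name Variable name.
#' @param declared_scale Optional scale override.
#' @param declared_order Optional ordered category vector (required for
#'   ordinal); must contain every observed non-missing value.
#' @return A [variable_meta()] object.
#' @export
infer_variable_meta <- function(dataset, name, declared_scale = NULL,
                                declared_order = NULL) {
  col <- dataset$records[[name]]
  if (is.null(col)) stop("variable '", name, "' not present in dataset")
  obs <- col[!is.na(col)]
  distinct <- unique(obs)
  n_missing <- sum(is.na(col))
  numericish <- function(x) {
    if (is.numeric(x)) return(TRUE)
    length(x) > 0 && !anyNA(suppressWarnings(as.numeric(x)))
  }
  scale <- declared_scale
  if (is.null(scale)) scale <- if (numericish(obs)) "continuous" else "nominal"
  scale <- match.arg(scale, c("nominal", "ordinal", "interval", "continuous"))

  if (scale == "ordinal") {
    if (is.null(declared_order))
      stop("ordinal scale for '", name, "' requires a declared order")
    missing_cats <- setdiff(as.character(distinct), declared_order)
    if (length(missing_cats) > 0)
      stop("declared order for '", name, "' lacks observed value(s): ",
           paste(missing_cats, collapse = ", "))
    domain <- as.character(declared_order)
  } else if (scale == "nominal") {
    domain <- if (!is.null(declared_order)) as.character(declared_order)
              else sort(as.character(distinct))
  } else {
    num <- suppressWarnings(as.numeric(obs))
    if (anyNA(num) && length(obs) > 0)
      stop("variable '", name, "' declared ", scale,
           " but has non-numeric values")
    domain <- if (length(num)) range(num) else c(0, 0)
  }
  variable_meta(name, scale, domain,
                distinct_count = length(distinct),
                missing_count = n_missing)
}

#' Read case records from a delimited text file
#'
#' Reads a header-carrying CSV/TSV export into a [glyph_dataset()]. Empty
#' cells and the `na` sentinel (default `"NA"`, the common registry-export
#' convention) become missing values. An optional sidecar metadata file
#' (YAML or JSON) may declare scales and ordinal orders, e.g.
#' `t_stage: {scale: ordinal, order: [T1, T2, T3, T4]}`.
#'
#' @param path File path.
#' @param delim Field delimiter (default `","`; use `"\t"` for TSV).
#' @param quote Quote character.
#' @param na Sentinel string(s) read as missing, in addition to empty cells.
#' @param declared_scales Named character vector of scale declarations.
#' @param declared_orders Named list of ordinal category orders.
#' @param meta Optional path to a YAML/JSON sidecar declaring
#'   `scale`/`order` per variable (overridden by the explicit arguments).
#' @return A [glyph_dataset()] with one record per data row, in file order.
#' @export
read_cases <- function(path, delim = ",", quote = "\"", na = "NA",
                       declared_scales = NULL, declared_orders = NULL,
                       meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  arity <- utils::count.fields(path, sep = delim, quote = quote,
                               comment.char = "")
  if (length(arity) == 0) stop("empty file: ", path)
  bad <- which(arity != arity[1])
  if (length(bad) > 0)
    stop("row arity mismatch at line ", bad[1] + 0L, ": expected ",
         arity[1], " fields, found ", arity[bad[1]])
  raw <- utils::read.table(path, header = FALSE, sep = delim, quote = quote,
                           colClasses = "character", comment.char = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           encoding = "UTF-8")
  header <- as.character(raw[1, ])
  if (anyDuplicated(header))
    stop("duplicate header names: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  body <- raw[-1, , drop = FALSE]
  rownames(body) <- NULL
  names(body) <- header
  for (v in header) {
    col <- body[[v]]
    col[col %in% c("", na)] <- NA_character_
    obs <- col[!is.na(col)]
    decl <- if (!is.null(names(declared_scales)) &&
                v %in% names(declared_scales)) declared_scales[[v]] else NULL
    to_num <- (length(obs) > 0 &&
                 !anyNA(suppressWarnings(as.numeric(obs))) &&
                 (is.null(decl) || decl %in% c("continuous", "interval")))
    body[[v]] <- if (to_num) as.numeric(col) else col
  }
  if (!is.null(meta)) {
    side <- read_variable_meta_file(meta)
    for (v in names(side$scales))
      if (is.null(declared_scales[[v]]))
        declared_scales[[v]] <- side$scales[[v]]
    for (v in names(side$orders))
      if (is.null(declared_orders[[v]]))
        declared_orders[[v]] <- side$orders[[v]]
  }
  glyph_dataset(body, declared_scales = declared_scales,
                declared_orders = declared_orders, provenance = path)
}

read_variable_meta_file <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  decl <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  scales <- list(); orders <- list()
  for (v in names(decl)) {
    if (!is.null(decl[[v]]$scale)) scales[[v]] <- decl[[v]]$scale
    if (!is.null(decl[[v]]$order)) orders[[v]] <- as.character(decl[[v]]$order)
  }
  list(scales = scales, orders = orders)
}

#' Write a dataset to delimited text
#'
#' Missing values are written as empty cells so that
#' `read_cases(write_cases(ds))` round-trips records, order and missing
#' positions exactly.
#'
#' @param dataset A [glyph_dataset()].
#' @param path Output file path.
#' @param delim Field delimiter.
#' @param meta Optional path for a YAML sidecar carrying the scale and
#'   ordinal-order declarations needed to re-read with identical metadata.
#' @return `path`, invisibly.
#' @export
write_cases <- function(dataset, path, delim = ",", meta = NULL) {
  rec <- dataset$records
  num_str <- function(x) {
    # shortest decimal representation that round-trips the double exactly
    s <- vapply(x, function(v) {
      if (is.na(v)) return(NA_character_)
      t <- formatC(v, format = "g", digits = 15, width = 1)
      if (suppressWarnings(as.numeric(t)) == v) t
      else formatC(v, format = "g", digits = 17, width = 1)
    }, character(1))
    s
  }
  out <- lapply(rec, function(col) {
    s <- if (is.numeric(col)) num_str(col) else as.character(col)
    s[is.na(col)] <- ""
    s
  })
  tab <- do.call(cbind, out)
  lines <- c(paste(names(rec), collapse = delim),
             apply(tab, 1L, paste, collapse = delim))
  if (nrow(rec) == 0) lines <- lines[1]
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(meta)) {
    decl <- list()
    for (v in names(dataset$variables)) {
      m <- dataset$variables[[v]]
      decl[[v]] <- if (m$scale == "ordinal")
        list(scale = m$scale, order = as.list(m$domain))
      else list(scale = m$scale)
    }
    yaml::write_yaml(decl, meta)
  }
  invisible(path)
}

#' Metadata declarations needed to re-read a dataset faithfully
#'
#' @param dataset A [glyph_dataset()].
#' @return A list with `declared_scales` and `declared_orders` suitable to
#'   pass to [read_cases()].
#' @export
meta_declarations <- function(dataset) {
  scales <- vapply(dataset$variables, `[[`, character(1), "scale")
  ords <- lapply(dataset$variables[scales == "ordinal"], `[[`, "domain")
  list(declared_scales = scales, declared_orders = ords)
}
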