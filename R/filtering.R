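# Conjunctive per-variable range filters and overall-versus-selected
# histograms: the model behind the linked-histogram subgroup view, where
# the analyst drags per-attribute range sliders and every histogram shows
# the selected subgroup (green) against the full cohort (blue).

#' Construct a filter state
#'
#' Each entry filters one variable: a numeric `c(lo, hi)` range (closed on
#' both ends) for numeric variables, or a character vector of category
#' tokens for nominal/ordinal variables. Filters combine conjunctively --
#' a record must pass every one. Missing values fail a filter unless the
#' variable is listed in `include_missing`.
#'
#' @param ... Named filter entries, e.g. `age = c(50, 60), sex = "F"`.
#' @param ranges Alternatively, a named list of entries.
#' @param include_missing Character vector of variable names whose missing
#'   values pass their filter.
#' @return An object of class `filter_state`.
#' @export
filter_state <- function(..., ranges = NULL, include_missing = character()) {
  entries <- if (is.null(ranges)) list(...) else ranges
  if (length(entries) > 0 &&
      (is.null(names(entries)) || any(!nzchar(names(entries)))))
    stop("filter entries must be named by variable")
  for (v in names(entries)) {
    e <- entries[[v]]
    if (is.numeric(e)) {
      if (length(e) != 2L || anyNA(e) || e[1] > e[2])
        stop("numeric filter on '", v, "' must be c(lo, hi) with lo <= hi")
    } else if (!is.character(e)) {
      stop("filter on '", v, "' must be a numeric range or category subset")
    }
  }
  structure(list(ranges = entries,
                 include_missing = as.character(include_missing)),
            class = "filter_state")
}

#' Apply a filter state to a dataset
#'
#' @param dataset A [glyph_dataset()].
#' @param state A [filter_state()]; an empty state selects everything.
#' @return Logical selection mask of length `nrow(dataset$records)`.
#' @export
apply_filter <- function(dataset, state = filter_state()) {
  rec <- dataset$records
  mask <- rep(TRUE, nrow(rec))
  for (v in names(state$ranges)) {
    meta <- dataset$variables[[v]]
    if (is.null(meta)) stop("filtered variable '", v, "' not in dataset")
    e <- state$ranges[[v]]
    col <- rec[[v]]
    if (is.numeric(e)) {
      if (meta$scale == "nominal")
        stop("numeric range filter on nominal variable '", v,
             "' (no declared order)")
      x <- if (meta$scale == "ordinal") match(as.character(col), meta$domain)
           else as.numeric(col)
      pass <- x >= e[1] & x <= e[2]
    } else {
      bad <- setdiff(e, meta$domain)
      if (meta$scale %in% c("nominal", "ordinal") && length(bad) > 0)
        stop("filter categories not in domain of '", v, "': ",
             paste(bad, collapse = ", "))
      pass <- as.character(col) %in% e
    }
    pass[is.na(col)] <- v %in% state$include_missing
    mask <- mask & pass
  }
  mask
}

#' Compute an overall-versus-selected histogram
#'
#' Overall counts ignore the mask; selected counts apply it. Numeric bins
#' are half-open `[lo, hi)` with the last bin closed. Missing values get a
#' dedicated bin (on by default) so that e.g. a missing-staging population
#' stays visible in the panel.
#'
#' @param dataset A [glyph_dataset()].
#' @param variable Variable name.
#' @param binning `NULL` for defaults (categories for nominal/ordinal, 10
#'   equal-width bins for numeric), or a list with one of `width`
#'   (numeric bin width), `edges` (explicit strictly increasing edges) or
#'   `categories` (explicit category list).
#' @param mask Logical selection mask (default: all selected).
#' @param missing_bin Keep a dedicated bin for missing values?
#' @return An object of class `glyph_histogram`: `variable`, `kind`
#'   (`"numeric"` or `"categorical"`), `edges` or `categories`, `labels`,
#'   `overall_counts`, `selected_counts`, `missing_overall`,
#'   `missing_selected`.
#' @export
compute_histogram <- function(dataset, variable, binning = NULL,
                              mask = NULL, missing_bin = TRUE) {
  meta <- dataset$variables[[variable]]
  if (is.null(meta)) stop("unknown variable: ", variable)
  col <- dataset$records[[variable]]
  n <- length(col)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  is_cat <- meta$scale %in% c("nominal", "ordinal")
  if (!is.null(binning$categories)) is_cat <- TRUE

  if (is_cat) {
    cats <- if (!is.null(binning$categories))
      as.character(binning$categories) else meta$domain
    obs <- unique(as.character(col[!is.na(col)]))
    if (length(setdiff(obs, cats)) > 0)
      stop("binning categories do not cover observed values of '",
           variable, "'")
    f <- factor(as.character(col), levels = cats)
    overall <- as.integer(table(f))
    selected <- as.integer(table(f[mask]))
    res <- list(variable = variable, kind = "categorical",
                categories = cats, labels = cats,
                overall_counts = overall, selected_counts = selected)
  } else {
    x <- as.numeric(col)
    obs <- x[!is.na(x)]
    if (!is.null(binning$edges)) {
      edges <- as.numeric(binning$edges)
      if (is.unsorted(edges, strictly = TRUE))
        stop("explicit edges must be strictly increasing (overlapping bins)")
      if (length(obs) > 0 && (min(obs) < edges[1] ||
                              max(obs) > edges[length(edges)]))
        stop("explicit edges do not cover the observed range of '",
             variable, "'")
    } else {
      rng <- if (length(obs) > 0) range(obs) else c(0, 1)
      width <- if (!is.null(binning$width)) binning$width
               else diff(rng) / 10
      if (width <= 0) width <- 1
      lo <- floor(rng[1] / width) * width
      hi <- ceiling(rng[2] / width) * width
      if (hi <= lo) hi <- lo + width
      edges <- seq(lo, hi, by = width)
      if (edges[length(edges)] < rng[2]) edges <- c(edges, hi + width)
    }
    bin <- findInterval(x, edges, rightmost.closed = TRUE)
    k <- length(edges) - 1L
    f <- factor(bin, levels = seq_len(k))
    overall <- as.integer(table(f))
    selected <- as.integer(table(f[mask]))
    labels <- sprintf("[%g,%g%s", edges[-length(edges)], edges[-1],
                      c(rep(")", k - 1L), "]"))
    res <- list(variable = variable, kind = "numeric", edges = edges,
                labels = labels, overall_counts = overall,
                selected_counts = selected)
  }
  if (missing_bin) {
    res$missing_overall <- sum(is.na(col))
    res$missing_selected <- sum(is.na(col) & mask)
  } else {
    res$missing_overall <- NA_integer_
    res$missing_selected <- NA_integer_
  }
  structure(res, class = "glyph_histogram")
}

#' @export
print.glyph_histogram <- function(x, ...) {
  cat(sprintf("<glyph_histogram> %s (%s)\n", x$variable, x$kind))
  df <- data.frame(bin = x$labels, overall = x$overall_counts,
                   selected = x$selected_counts)
  print(df, row.names = FALSE)
  if (!is.na(x$missing_overall))
    cat(sprintf("  missing: %d overall / %d selected\n",
                x$missing_overall, x$missing_selected))
  invisible(x)
}

#' Side-by-side subgroup summary
#'
#' Parallel per-variable count tables for two subgroups (e.g. two organ
#' cohorts about to be compared as back-to-back age pyramids).
#'
#' @param dataset A [glyph_dataset()].
#' @param mask_a,mask_b Logical masks of length `nrow(dataset$records)`.
#' @param variables Variables to tabulate.
#' @param binning Optional named list of binning specs per variable (see
#'   [compute_histogram()]).
#' @return An object of class `subgroup_summary`: named list of
#'   data.frames (`bin`, `count_a`, `count_b`) plus `totals`.
#' @export
subgroup_summary <- function(dataset, mask_a, mask_b, variables,
                             binning = list()) {
  n <- nrow(dataset$records)
  stopifnot(length(mask_a) == n, length(mask_b) == n)
  tables <- lapply(variables, function(v) {
    ha <- compute_histogram(dataset, v, binning = binning[[v]],
                            mask = mask_a)
    hb <- compute_histogram(dataset, v, binning = binning[[v]],
                            mask = mask_b)
    data.frame(bin = ha$labels, count_a = ha$selected_counts,
               count_b = hb$selected_counts, stringsAsFactors = FALSE)
  })
  names(tables) <- variables
  structure(list(tables = tables,
                 totals = c(a = sum(mask_a), b = sum(mask_b), n = n)),
            class = "subgroup_summary")
}
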