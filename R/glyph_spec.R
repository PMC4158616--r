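# The cubic glyph: a 3D composite glyph drawn on a dimetric grid with three
# levels of detail. Level 1 is a single colored cell (pixel level); level 2
# (iconic) adds the main cube with its cap and base; level 3 (detail) adds
# three sub-elements on the west, east and south faces of the plinth. Each
# geometric/color channel is a "slot" a data variable can be mapped to, and
# each slot has a Bertin-style scale capability (nominal and/or ordinal) and
# a length class (how many states a viewer can reliably distinguish).

#' Construct a visual slot descriptor
#'
#' @param id Slot id, 1..16.
#' @param name Slot name, e.g. `"height main cube"`.
#' @param level Level of detail that introduces the slot: 1, 2 or 3.
#' @param vtype `"color"`, `"geometry-size"` or `"geometry-shape"`.
#' @param scale_capability `"nominal"`, `"ordinal"` or `"nom/ord"`.
#' @param length_class `"short"`, `"medium"` or `"long"`.
#' @return An object of class `visual_slot`.
#' @export
visual_slot <- function(id, name, level, vtype, scale_capability,
                        length_class) {
  stopifnot(id >= 1, level %in% 1:3)
  vtype <- match.arg(vtype, c("color", "geometry-size", "geometry-shape"))
  scale_capability <- match.arg(scale_capability,
                                c("nominal", "ordinal", "nom/ord"))
  length_class <- match.arg(length_class, c("short", "medium", "long"))
  structure(list(id = as.integer(id), name = name, level = as.integer(level),
                 vtype = vtype, scale_capability = scale_capability,
                 length_class = length_class),
            class = "visual_slot")
}

#' Level-of-detail switching policy
#'
#' A glyph whose on-screen footprint edge is strictly below `pixel_max_px`
#' is drawn at the pixel level; strictly above `detail_min_px` at the detail
#' level; in between (both boundaries included) at the iconic level.
#'
#' @param pixel_max_px Pixel-level threshold in pixels (default 2).
#' @param detail_min_px Detail-level threshold in pixels (default 64).
#' @return An object of class `lod_policy`.
#' @export
lod_policy <- function(pixel_max_px = 2, detail_min_px = 64) {
  stopifnot(pixel_max_px > 0, pixel_max_px < detail_min_px)
  structure(list(pixel_max_px = pixel_max_px, detail_min_px = detail_min_px),
            class = "lod_policy")
}

# Slot table of the cubic glyph. The "size cap" slot is typed geometry-shape
# and "shape cap" geometry-size: the cap's size steps read as silhouette
# changes while its shape family is realized as discrete size-steps of the
# cap profile, and the operative slot table keeps that typing.
cubic_slot_table <- function() {
  rows <- list(
    list( 1L, "primary color",            1L, "color",          "nom/ord", "short"),
    list( 2L, "height main cube",         2L, "geometry-size",  "ordinal", "long"),
    list( 3L, "color cap",                2L, "color",          "nom/ord", "short"),
    list( 4L, "color base",               2L, "color",          "nom/ord", "short"),
    list( 5L, "size cap",                 2L, "geometry-shape", "ordinal", "medium"),
    list( 6L, "height cap",               2L, "geometry-size",  "ordinal", "long"),
    list( 7L, "shape cap",                2L, "geometry-size",  "ordinal", "short"),
    list( 8L, "height west-element",      3L, "geometry-size",  "ordinal", "long"),
    list( 9L, "color west-element base",  3L, "color",          "nom/ord", "short"),
    list(10L, "color cap west-element",   3L, "color",          "nom/ord", "short"),
    list(11L, "height east-element",      3L, "geometry-size",  "ordinal", "long"),
    list(12L, "color east-element base",  3L, "color",          "nom/ord", "short"),
    list(13L, "color cap east-element",   3L, "color",          "nom/ord", "short"),
    list(14L, "height south-element",     3L, "geometry-size",  "ordinal", "long"),
    list(15L, "color south-element base", 3L, "color",          "nom/ord", "short"),
    list(16L, "color cap south-element",  3L, "color",          "nom/ord", "short"))
  lapply(rows, function(r) visual_slot(r[[1]], r[[2]], r[[3]], r[[4]],
                                       r[[5]], r[[6]]))
}

#' The cubic glyph specification
#'
#' Returns the 16 mappable visual-variable slots of the cubic glyph: one
#' level-1 slot (the primary color, which stays the dominant color at every
#' level), six level-2 slots (main-cube height, cap/base colors, cap size,
#' height and shape) and nine level-3 slots (height, base color and cap
#' color for each of the west, east and south sub-elements).
#'
#' @param capacities Named numeric vector giving the number of
#'   distinguishable states per length class. Defaults: short = 10 (roughly
#'   ten values can be told apart on a short channel such as hue or value),
#'   medium = 25, long = 256. These are configuration keys, not perceptual
#'   constants.
#' @param lod A [lod_policy()].
#' @return An object of class `glyph_spec` with fields `slots`,
#'   `capacities`, `lod_policy`.
#' @export
cubic_glyph_spec <- function(capacities = c(short = 10, medium = 25,
                                            long = 256),
                             lod = lod_policy()) {
  stopifnot(all(c("short", "medium", "long") %in% names(capacities)),
            capacities["short"] < capacities["medium"],
            capacities["medium"] < capacities["long"])
  slots <- cubic_slot_table()
  structure(list(slots = slots, capacities = capacities, lod_policy = lod),
            class = "glyph_spec")
}

#' @export
print.glyph_spec <- function(x, ...) {
  cat(sprintf("<glyph_spec> %d slots (levels: %s)\n", length(x$slots),
              paste(table(vapply(x$slots, `[[`, 1L, "level")),
                    collapse = "/")))
  for (s in x$slots)
    cat(sprintf("  %2d %-24s L%d %-14s %-7s %s\n", s$id, s$name, s$level,
                s$vtype, s$scale_capability, s$length_class))
  invisible(x)
}

spec_slot <- function(spec, id) {
  for (s in spec$slots) if (s$id == id) return(s)
  stop("no slot with id ", id, " in glyph spec")
}

#' Number of distinguishable states of a length class
#'
#' @param length_class `"short"`, `"medium"` or `"long"`.
#' @param spec A [cubic_glyph_spec()] carrying the configured capacities.
#' @return A positive integer.
#' @export
capacity <- function(length_class, spec = cubic_glyph_spec()) {
  if (!length_class %in% names(spec$capacities))
    stop("unknown length class: ", length_class)
  as.integer(spec$capacities[[length_class]])
}

#' Can a data scale be mapped onto a visual slot?
#'
#' Nominal data fits any slot that accepts nominal values. Ordinal,
#' interval and continuous data require an ordinal-capable slot: shape-like
#' purely nominal channels carry no order, so mapping ordered data onto
#' them invites misreading. Continuous and interval variables are treated
#' as ordinal after quantization (see [quantize()]).
#'
#' @param data_scale `"nominal"`, `"ordinal"`, `"interval"` or
#'   `"continuous"`.
#' @param slot A [visual_slot()].
#' @return Logical.
#' @export
scale_compatible <- function(data_scale, slot) {
  data_scale <- match.arg(data_scale,
                          c("nominal", "ordinal", "interval", "continuous"))
  cap <- slot$scale_capability
  if (data_scale == "nominal") cap %in% c("nominal", "nom/ord")
  else cap %in% c("ordinal", "nom/ord")
}

#' Construct a glyph mapping
#'
#' Assigns data variables to glyph slots. Each entry is either a bare
#' variable name or a list with fields `var`, optional `colormap` (a
#' [colormap()]; color slots default to a direct categorical map for
#' nominal variables and a sequential gradient otherwise) and optional
#' `steps` (quantization steps used when a continuous/interval variable
#' feeds an ordered slot; default 10).
#'
#' @param ... Entries named by slot id, e.g.
#'   `glyph_mapping("1" = "t_stage", "2" = list(var = "age", steps = 10))`.
#' @param assignments Alternatively, a named list of entries.
#' @return An object of class `glyph_mapping`.
#' @export
glyph_mapping <- function(..., assignments = NULL) {
  entries <- if (is.null(assignments)) list(...) else assignments
  if (length(entries) == 0) stop("empty mapping")
  ids <- suppressWarnings(as.integer(names(entries)))
  if (anyNA(ids)) stop("mapping entries must be named by integer slot id")
  norm <- lapply(entries, function(e) {
    if (is.character(e)) e <- list(var = e)
    stopifnot(is.list(e), is.character(e$var), length(e$var) == 1L)
    if (is.null(e$steps)) e$steps <- 10L
    e[c("var", "colormap", "steps")]
  })
  names(norm) <- as.character(ids)
  norm <- norm[order(ids)]
  structure(list(assignments = norm), class = "glyph_mapping")
}

mapping_slot_ids <- function(mapping) as.integer(names(mapping$assignments))

# Default colormap for a slot/variable pair when the mapping declares none.
slot_colormap <- function(mapping, id, meta) {
  e <- mapping$assignments[[as.character(id)]]
  if (!is.null(e$colormap)) return(e$colormap)
  if (meta$scale == "nominal") colormap_direct() else colormap_gradient()
}

status_rank <- c(green = 1L, yellow = 2L, red = 3L)

#' Validate a variable-to-slot mapping (traffic light)
#'
#' Per slot: red when the variable's scale does not fit the slot's scale
#' capability; yellow when the scales fit but the slot's length (its number
#' of distinguishable states) is smaller than the variable's distinct-value
#' count; green otherwise. Ordinal data on a nominal-or-ordinal color slot
#' is fully valid only under a sequential gradient colormap -- with a
#' categorical map the ordering is not representable and the slot is
#' flagged yellow. For continuous/interval variables on ordered slots the
#' length check uses the configured quantization step count rather than the
#' raw distinct-value count. The overall verdict is the worst per-slot
#' verdict (red > yellow > green).
#'
#' @param mapping A [glyph_mapping()].
#' @param metas Named list of [variable_meta()], covering every mapped
#'   variable (a mapped variable without metadata is an error, not a red
#'   verdict).
#' @param spec A [cubic_glyph_spec()].
#' @return An object of class `validation_report` with `per_slot`
#'   (data.frame: slot, name, variable, status, reason) and `overall`.
#' @export
validate_mapping <- function(mapping, metas, spec = cubic_glyph_spec()) {
  ids <- mapping_slot_ids(mapping)
  known <- vapply(spec$slots, `[[`, 1L, "id")
  if (!all(ids %in% known))
    stop("mapping refers to unknown slot id(s): ",
         paste(setdiff(ids, known), collapse = ", "))
  rows <- lapply(ids, function(id) {
    e <- mapping$assignments[[as.character(id)]]
    slot <- spec_slot(spec, id)
    meta <- metas[[e$var]]
    if (is.null(meta))
      stop("mapped variable '", e$var, "' has no metadata")
    cap_n <- capacity(slot$length_class, spec)
    if (!scale_compatible(meta$scale, slot)) {
      status <- "red"
      reason <- sprintf("scale mismatch: %s data cannot be mapped to a %s %s slot",
                        meta$scale, slot$scale_capability, slot$vtype)
    } else {
      eff <- if (meta$scale %in% c("continuous", "interval"))
        min(meta$distinct_count, e$steps) else meta$distinct_count
      if (eff > cap_n) {
        status <- "yellow"
        reason <- sprintf("length exceeded: %d distinct values > %s capacity %d",
                          eff, slot$length_class, cap_n)
      } else if (meta$scale != "nominal" && slot$vtype == "color" &&
                 slot$scale_capability == "nom/ord" &&
                 !colormap_is_sequential(slot_colormap(mapping, id, meta))) {
        status <- "yellow"
        reason <- "ordered data on a color slot needs a sequential gradient colormap to keep its order readable"
      } else {
        status <- "green"
        reason <- "scale fits and slot length covers the distinct values"
      }
    }
    data.frame(slot = id, name = slot$name, variable = e$var,
               status = status, reason = reason,
               stringsAsFactors = FALSE)
  })
  per_slot <- do.call(rbind, rows)
  overall <- names(status_rank)[max(status_rank[per_slot$status])]
  structure(list(per_slot = per_slot, overall = overall),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  lamp <- c(green = "[G]", yellow = "[Y]", red = "[R]")
  cat("<validation_report> overall:", toupper(x$overall), "\n")
  for (i in seq_len(nrow(x$per_slot))) {
    r <- x$per_slot[i, ]
    cat(sprintf("  %s slot %2d %-24s <- %-12s %s\n", lamp[[r$status]],
                r$slot, r$name, r$variable, r$reason))
  }
  invisible(x)
}
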