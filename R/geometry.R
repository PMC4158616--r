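# Cubic glyph geometry. Polygons are built in a glyph-local frame:
# u is measured in half cell widths (screen x = anchor + u * cell_w/2),
# v in half cell heights on the ground plane, and z in grid height units
# (screen y = anchor + v * cell_h/2 - z * z_scale). Everything is a planar
# polygon in that frame, so projection to screen space stays a pure affine
# map and sprites are reusable at a fixed zoom.
#
# Geometry table (glyph-local units; the source of the fixed primitive
# counts):
#   plinth       footprint 1.00, z 0 .. 0.10, neutral; 3 faces (W, E, top)
#   base band    footprint 0.80, z 0.10 .. 0.25, base color; 2 faces
#   main body    footprint 0.80, z 0.25 .. 0.10 + cube height; 3 faces
#   cap          footprint 0.30..0.70, height 0.15..0.50 on the cube top;
#                flat = 3 faces, bevel = 3, pyramid = 2
#   sub-elements footprint 0.22 at the west/east/south plinth corners,
#                body 2 faces + cap slab 3 faces each (detail level only)
# Cube height spans 0.40..2.00 units; total glyph height is clamped to
# max_height_units (default 2.5, i.e. 1.25 cell heights at the default
# z-scale) so no glyph can fully bury the cap of the row behind it.

#' Quantize a value into ordered steps
#'
#' Ordinal values are spread evenly over the steps with order preserved
#' (first category to step 0, last to `steps - 1`); continuous and
#' interval values fall into equal-width bins over the declared range.
#' Missing passes through as `NA`. Values outside the declared domain are
#' clamped to the nearest step and a warning (class
#' `glyphscape_clamp`) is signalled so callers can count them.
#'
#' @param value A single value (`NA` = missing).
#' @param meta The variable's [variable_meta()].
#' @param steps Number of steps (>= 2 unless the mapping is constant).
#' @return Integer step index in `0..steps-1`, or `NA`.
#' @export
quantize <- function(value, meta, steps) {
  steps <- as.integer(steps)
  stopifnot(steps >= 1)
  if (length(value) != 1L || is.na(value)) return(NA_integer_)
  if (meta$scale %in% c("nominal", "ordinal")) {
    i <- match(as.character(value), meta$domain)
    if (is.na(i)) {
      warning(warningCondition(
        paste0("value '", value, "' outside domain of ", meta$name,
               "; clamped"),
        class = "glyphscape_clamp"))
      return(0L)
    }
    k <- length(meta$domain)
    if (k <= 1L || steps == 1L) return(0L)
    return(as.integer(round((i - 1) / (k - 1) * (steps - 1))))
  }
  x <- as.numeric(value)
  lo <- meta$domain[1]; hi <- meta$domain[2]
  if (x < lo || x > hi) {
    warning(warningCondition(
      paste0("value ", x, " outside [", lo, ", ", hi, "] of ", meta$name,
             "; clamped"),
      class = "glyphscape_clamp"))
    x <- min(max(x, lo), hi)
  }
  if (hi <= lo || steps == 1L) return(0L)
  as.integer(min(floor((x - lo) / (hi - lo) * steps), steps - 1))
}

# --- primitive builders (glyph-local frame) --------------------------------

prim <- function(u, v, z, fill, outline = NA_character_)
  list(u = u, v = v, z = z, fill = fill, outline = outline)

shade <- function(hex, f) {
  rgb <- grDevices::col2rgb(hex)
  grDevices::rgb(rgb[1] * f, rgb[2] * f, rgb[3] * f, maxColorValue = 255)
}

diamond_top <- function(cu, cv, s, z, fill, outline = NA_character_)
  prim(u = cu + c(0, s, 0, -s), v = cv + c(-s, 0, s, 0),
       z = rep(z, 4), fill = fill, outline = outline)

# west (SW-facing) and east (SE-facing) side faces of a cuboid
cuboid_sides <- function(cu, cv, s, z0, z1, fill, shade_w = 0.72,
                         outline = NA_character_) {
  list(
    prim(u = cu + c(-s, 0, 0, -s), v = cv + c(0, s, s, 0),
         z = c(z1, z1, z0, z0), fill = shade(fill, shade_w),
         outline = outline),
    prim(u = cu + c(0, s, s, 0), v = cv + c(s, 0, 0, s),
         z = c(z1, z1, z0, z0), fill = fill, outline = outline))
}

cuboid <- function(cu, cv, s, z0, z1, fill, top_fill = fill,
                   outline = NA_character_)
  c(cuboid_sides(cu, cv, s, z0, z1, fill, outline = outline),
    list(diamond_top(cu, cv, s, z1, top_fill, outline = outline)))

# cap silhouettes: a 3-step family (flat slab / beveled slab / pyramid)
cap_primitives <- function(s, z0, h, shape_step, fill) {
  z1 <- z0 + h
  if (shape_step <= 0) {                       # flat
    cuboid(0, 0, s, z0, z1, fill)
  } else if (shape_step == 1L) {               # bevel: top face half-size
    st <- s / 2
    list(
      prim(u = c(-s, 0, 0, -st), v = c(0, s, st, 0),
           z = c(z0, z0, z1, z1), fill = shade(fill, 0.72)),
      prim(u = c(0, s, st, 0), v = c(s, 0, 0, st),
           z = c(z0, z0, z1, z1), fill = fill),
      diamond_top(0, 0, st, z1, shade(fill, 1.0)))
  } else {                                     # pyramid: apex point
    list(
      prim(u = c(-s, 0, 0), v = c(0, s, 0), z = c(z0, z0, z1),
           fill = shade(fill, 0.72)),
      prim(u = c(0, s, 0), v = c(s, 0, 0), z = c(z0, z0, z1),
           fill = fill))
  }
}

PLINTH_COLOR <- "#C8C8C8"
MISSING_FILL <- "#FFFFFF"
MISSING_OUTLINE <- "#AAAAAA"

geom_defaults <- list(
  plinth_h = 0.1, cube_s = 0.8, cube_h_min = 0.4, cube_h_max = 2.0,
  cube_h_default = 1.0, base_band_h = 0.15,
  cap_s_min = 0.3, cap_s_max = 0.7, cap_s_default = 0.5,
  cap_h_min = 0.15, cap_h_max = 0.5, cap_h_default = 0.25,
  elem_s = 0.22, elem_h_min = 0.15, elem_h_max = 0.8,
  elem_h_default = 0.3, elem_cap_h = 0.1,
  max_height_units = 2.5)

# value of the variable mapped to a slot, or NULL when the slot is unmapped
slot_value <- function(record, mapping, id) {
  e <- mapping$assignments[[as.character(id)]]
  if (is.null(e)) return(NULL)
  if (!e$var %in% names(record))
    stop("slot ", id, " maps variable '", e$var,
         "' which is absent from the record")
  list(entry = e, value = record[[e$var]])
}

# normalized position in [0, 1] for a geometry-size slot, via quantized steps
slot_t <- function(record, mapping, id, metas, default = NULL,
                   .cache = NULL) {
  sv <- slot_value(record, mapping, id)
  if (is.null(sv)) return(default)
  key <- if (is.null(.cache)) NULL
         else paste0("t", id, ":", as.character(sv$value))
  if (!is.null(key) && !is.null(.cache[[key]])) return(.cache[[key]])
  meta <- metas[[sv$entry$var]]
  if (is.null(meta)) stop("no metadata for variable '", sv$entry$var, "'")
  steps <- max(2L, as.integer(sv$entry$steps))
  q <- suppressWarnings(quantize(sv$value, meta, steps))
  res <- if (is.na(q)) NA_real_ else q / (steps - 1)
  if (!is.null(key)) .cache[[key]] <- res
  res
}

slot_color <- function(record, mapping, id, metas, default = NULL,
                       .cache = NULL) {
  sv <- slot_value(record, mapping, id)
  if (is.null(sv)) return(default)
  key <- if (is.null(.cache)) NULL
         else paste0("c", id, ":", as.character(sv$value))
  if (!is.null(key) && !is.null(.cache[[key]])) return(.cache[[key]])
  meta <- metas[[sv$entry$var]]
  if (is.null(meta)) stop("no metadata for variable '", sv$entry$var, "'")
  cm <- slot_colormap(mapping, id, meta)
  res <- resolve_color(cm, sv$value, meta)
  if (!is.null(key)) .cache[[key]] <- res
  res
}

#' Build the geometry of one glyph
#'
#' Produces the ordered primitive list (back-to-front within the glyph)
#' for a record at the requested level of detail. At the pixel level a
#' single cell is filled with the primary (slot 1) color; the iconic level
#' draws plinth, base band, main cube and cap (slots 1-7); the detail
#' level adds the west, east and south sub-elements (slots 8-16). The
#' primary color stays the dominant color at every level: the main cube
#' body and top carry exactly the pixel-level fill. A record whose primary
#' variable is missing renders white at every level (plinth excepted), so
#' staging gaps stay visible as white glyphs.
#'
#' @param record A single record as a named list / one-row data.frame.
#' @param mapping A [glyph_mapping()] (validated; red mappings should be
#'   rejected before rendering).
#' @param level `"pixel"`, `"iconic"` or `"detail"`.
#' @param spec A [cubic_glyph_spec()].
#' @param metas Named list of [variable_meta()] for the mapped variables.
#' @param geom Geometry constants; see `geom_defaults` in the package
#'   source.
#' @return An object of class `glyph_geometry`: `level`, `primitives`,
#'   `height_units`.
#' @export
build_geometry <- function(record, mapping, level, spec = cubic_glyph_spec(),
                           metas, geom = geom_defaults, .cache = NULL) {
  level <- match.arg(level, c("pixel", "iconic", "detail"))
  record <- as.list(record)
  pv <- slot_value(record, mapping, 1L)
  if (is.null(pv)) stop("slot 1 (primary color) must be mapped")
  primary_missing <- is.na(pv$value)
  primary <- slot_color(record, mapping, 1L, metas, .cache = .cache)

  if (level == "pixel") {
    g <- list(diamond_top(0, 0, 1, 0, primary,
                          outline = if (primary_missing) MISSING_OUTLINE
                                    else NA_character_))
    return(structure(list(level = level, primitives = g, height_units = 0),
                     class = "glyph_geometry"))
  }

  wash <- function(col) if (primary_missing) MISSING_FILL else col
  out_col <- if (primary_missing) MISSING_OUTLINE else NA_character_

  t_cube <- slot_t(record, mapping, 2L, metas, default = NULL, .cache = .cache)
  h_cube <- if (is.null(t_cube)) geom$cube_h_default
            else if (is.na(t_cube)) geom$cube_h_min
            else geom$cube_h_min + t_cube * (geom$cube_h_max - geom$cube_h_min)
  cap_color <- wash(slot_color(record, mapping, 3L, metas, default = primary,
                                .cache = .cache))
  base_color <- wash(slot_color(record, mapping, 4L, metas,
                                default = shade(primary, 0.6),
                                .cache = .cache))
  t_cs <- slot_t(record, mapping, 5L, metas, default = NULL, .cache = .cache)
  cap_s <- if (is.null(t_cs)) geom$cap_s_default
           else if (is.na(t_cs)) geom$cap_s_min
           else geom$cap_s_min + t_cs * (geom$cap_s_max - geom$cap_s_min)
  t_ch <- slot_t(record, mapping, 6L, metas, default = NULL, .cache = .cache)
  cap_h <- if (is.null(t_ch)) geom$cap_h_default
           else if (is.na(t_ch)) geom$cap_h_min
           else geom$cap_h_min + t_ch * (geom$cap_h_max - geom$cap_h_min)
  sv7 <- slot_value(record, mapping, 7L)
  cap_shape <- if (is.null(sv7) || is.na(sv7$value)) 0L else {
    q <- suppressWarnings(quantize(sv7$value, metas[[sv7$entry$var]], 3L))
    if (is.na(q)) 0L else q
  }

  # clamp the stack so the cap of the glyph behind stays visible
  z_plinth <- geom$plinth_h
  h_cube <- min(h_cube, geom$max_height_units - z_plinth - cap_h)
  z_band <- z_plinth + geom$base_band_h
  z_top <- z_plinth + h_cube

  prims <- c(
    cuboid(0, 0, 1, 0, z_plinth, PLINTH_COLOR, outline = NA_character_),
    cuboid_sides(0, 0, geom$cube_s, z_plinth, z_band, wash(base_color),
                 outline = out_col),
    cuboid_sides(0, 0, geom$cube_s, z_band, z_top, wash(primary),
                 shade_w = if (primary_missing) 1 else 0.72,
                 outline = out_col),
    list(diamond_top(0, 0, geom$cube_s, z_top, wash(primary),
                     outline = out_col)),
    cap_primitives(cap_s, z_top, cap_h, cap_shape, wash(cap_color)))
  height <- z_top + cap_h

  if (level == "detail") {
    elems <- list(west = c(-0.5, 0.5), east = c(0.5, 0.5),
                  south = c(0, 0.72))
    slot_ids <- list(west = c(8L, 9L, 10L), east = c(11L, 12L, 13L),
                     south = c(14L, 15L, 16L))
    for (side in c("west", "east", "south")) {
      ids <- slot_ids[[side]]
      ctr <- elems[[side]]
      t_e <- slot_t(record, mapping, ids[1], metas, default = NULL,
                    .cache = .cache)
      h_e <- if (is.null(t_e)) geom$elem_h_default
             else if (is.na(t_e)) geom$elem_h_min
             else geom$elem_h_min + t_e * (geom$elem_h_max - geom$elem_h_min)
      b_col <- wash(slot_color(record, mapping, ids[2], metas,
                               default = shade(primary, 0.75),
                               .cache = .cache))
      c_col <- wash(slot_color(record, mapping, ids[3], metas,
                               default = cap_color, .cache = .cache))
      z0 <- z_plinth; z1 <- z0 + h_e
      prims <- c(prims,
                 cuboid_sides(ctr[1], ctr[2], geom$elem_s, z0, z1, b_col,
                              outline = out_col),
                 cuboid(ctr[1], ctr[2], geom$elem_s, z1,
                        z1 + geom$elem_cap_h, c_col, outline = out_col))
      height <- max(height, z1 + geom$elem_cap_h)
    }
  }
  if (primary_missing) {
    plinth_fills <- c(PLINTH_COLOR, shade(PLINTH_COLOR, 0.72))
    prims <- lapply(prims, function(p) {
      if (!p$fill %in% plinth_fills) p$fill <- MISSING_FILL
      p$outline <- MISSING_OUTLINE
      p
    })
  }
  structure(list(level = level, primitives = prims,
                 height_units = min(height, geom$max_height_units)),
            class = "glyph_geometry")
}

#' Build geometries for every placed record
#'
#' @param dataset A [glyph_dataset()].
#' @param placements A `glyph_placements` data.frame.
#' @param mapping A [glyph_mapping()].
#' @param level Level of detail for all glyphs.
#' @param spec A [cubic_glyph_spec()].
#' @return List of [build_geometry()] results, parallel to the placement
#'   rows.
#' @export
build_geometries <- function(dataset, placements, mapping, level,
                             spec = cubic_glyph_spec()) {
  metas <- dataset$variables
  rec <- dataset$records
  cache <- new.env(parent = emptyenv())
  vars <- vapply(mapping$assignments, `[[`, character(1), "var")
  cols <- lapply(rec[unique(vars)], identity)
  lapply(placements$record_index, function(i) {
    record <- lapply(cols, `[[`, i)
    build_geometry(record, mapping, level, spec, metas,
                   .cache = cache)
  })
}
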