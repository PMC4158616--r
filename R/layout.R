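# Placement of glyphs on a dimetric (near-isometric, 2:1) projection grid.
# The projection is strictly parallel: a glyph keeps its screen size
# wherever it is moved, so sprites can be cached and no re-rendering is
# needed when panning. Layouts are pure functions of (dataset, params); all
# jittering is deterministic.

#' Dimetric projection grid
#'
#' Classic 2:1 dimetric grid (cell twice as wide as tall), the familiar
#' three-quarter view of 1990s simulation games. `style = "cavalier"` and
#' `"military"` give the alternative parallel projections used when glyphs
#' should be seen from a higher viewpoint; all share the same affine
#' contract.
#'
#' @param cell_w_px Cell width in pixels (even, default 32).
#' @param cell_h_px Cell height in pixels (default `cell_w_px / 2`).
#' @param z_scale_px Pixels per height unit (default `cell_h_px / 2`).
#' @param origin_px Screen offset `c(x, y)` of grid cell (0, 0).
#' @param style `"dimetric"`, `"cavalier"` or `"military"`.
#' @return An object of class `dimetric_grid`.
#' @export
dimetric_grid <- function(cell_w_px = 32L, cell_h_px = cell_w_px / 2,
                          z_scale_px = cell_h_px / 2, origin_px = c(0, 0),
                          style = c("dimetric", "cavalier", "military")) {
  style <- match.arg(style)
  stopifnot(cell_w_px > 0, cell_w_px %% 2 == 0, cell_h_px > 0,
            z_scale_px > 0, length(origin_px) == 2L)
  structure(list(cell_w_px = cell_w_px, cell_h_px = cell_h_px,
                 z_scale_px = z_scale_px, origin_px = as.numeric(origin_px),
                 style = style),
            class = "dimetric_grid")
}

#' Select the level of detail for a glyph footprint
#'
#' A glyph strictly smaller than `pixel_max_px` (2 px) on screen is drawn
#' at the pixel level; strictly larger than `detail_min_px` (64 px) at the
#' detail level; everything in between, boundaries included, at the iconic
#' level. The rule is monotone: growing a glyph never moves it to a
#' coarser level.
#'
#' @param footprint_px Glyph footprint edge in pixels
#'   (`min(cell_w_px, cell_h_px) * zoom`); must be positive.
#' @param policy A [lod_policy()].
#' @return `"pixel"`, `"iconic"` or `"detail"`.
#' @export
select_lod <- function(footprint_px, policy = lod_policy()) {
  stopifnot(all(footprint_px > 0))
  ifelse(footprint_px < policy$pixel_max_px, "pixel",
         ifelse(footprint_px > policy$detail_min_px, "detail", "iconic"))
}

#' Project grid coordinates to screen space
#'
#' Pure parallel projection: `sx = ox + (gx - gy) * cell_w/2`,
#' `sy = oy + (gx + gy) * cell_h/2 - gz * z_scale` for the dimetric style
#' (cavalier/military shear instead of rotating). Affine by construction,
#' so projected glyph size is translation-invariant.
#'
#' @param gx,gy Integer grid cell (vectors allowed).
#' @param gz Height in grid height units.
#' @param grid A [dimetric_grid()].
#' @return A two-column matrix `cbind(sx, sy)`.
#' @export
project <- function(gx, gy, gz = 0, grid = dimetric_grid()) {
  ox <- grid$origin_px[1]; oy <- grid$origin_px[2]
  if (grid$style == "dimetric") {
    sx <- ox + (gx - gy) * grid$cell_w_px / 2
    sy <- oy + (gx + gy) * grid$cell_h_px / 2 - gz * grid$z_scale_px
  } else {
    # oblique projections: ground plane axis-aligned, depth sheared
    shear <- if (grid$style == "cavalier") 0.5 else 1.0
    sx <- ox + gx * grid$cell_w_px / 2 + gy * grid$cell_w_px / 2 * shear * 0.5
    sy <- oy + gy * grid$cell_h_px / 2 - gz * grid$z_scale_px
  }
  cbind(sx = sx, sy = sy)
}

new_placements <- function(record_index, gx, gy, gz = 0, group_key = NA,
                           selected = FALSE, flip_rows = FALSE,
                           warnings = character()) {
  df <- data.frame(record_index = as.integer(record_index),
                   gx = as.integer(gx), gy = as.integer(gy),
                   gz = as.numeric(gz),
                   group_key = as.character(group_key),
                   selected = selected, stringsAsFactors = FALSE)
  structure(df, class = c("glyph_placements", "data.frame"),
            flip_rows = flip_rows, warnings = warnings)
}

# find the first free column >= col0 on one side of a pyramid row
stack_outward <- function(col0, taken) {
  c0 <- col0
  while (c0 %in% taken) c0 <- c0 + 1L
  c0
}

#' Age-pyramid placement
#'
#' Rows are age classes (`bin_years` wide, default 5); males grow leftward
#' (`gx <= -1`), females rightward (`gx >= +1`). The column magnitude is
#' the T-stage rank plus one, so more advanced tumors sit further from the
#' axis; records with missing stage occupy column 1, right next to the
#' axis, where gaps in the staging stay conspicuous. Colliding records are
#' stacked one column further outward, which turns equal (sex, age-bin,
#' stage) counts into bar lengths. Rows are flipped at render time so age 0
#' sits at the base of the pyramid.
#'
#' @param dataset A [glyph_dataset()].
#' @param sex_var Nominal variable with tokens `male_token`/`female_token`.
#' @param age_var Numeric age variable (years).
#' @param stage_var Ordinal stage variable, or `NULL` to place everything
#'   in column 1.
#' @param bin_years Age-class width in years.
#' @param male_token,female_token Sex category tokens.
#' @return A `glyph_placements` data.frame (record_index, gx, gy, gz,
#'   group_key, selected) with attributes `flip_rows = TRUE` and
#'   `warnings` (records skipped for unknown sex tokens or missing age).
#' @export
layout_age_pyramid <- function(dataset, sex_var = "sex", age_var = "age",
                               stage_var = "t_stage", bin_years = 5,
                               male_token = "M", female_token = "F") {
  rec <- dataset$records
  sex <- as.character(rec[[sex_var]])
  age <- as.numeric(rec[[age_var]])
  stage <- if (is.null(stage_var)) rep(NA_character_, nrow(rec))
           else as.character(rec[[stage_var]])
  smeta <- if (is.null(stage_var)) NULL else dataset$variables[[stage_var]]
  if (!is.null(smeta) && smeta$scale != "ordinal")
    stop("stage variable '", stage_var, "' must be ordinal")
  rank <- if (is.null(smeta)) rep(NA_integer_, nrow(rec))
          else match(stage, smeta$domain)

  warnings <- character()
  keep <- rep(TRUE, nrow(rec))
  bad_sex <- !(sex %in% c(male_token, female_token))
  if (any(bad_sex)) {
    keep[bad_sex] <- FALSE
    warnings <- c(warnings, sprintf("skipped %d record(s) with unknown sex token",
                                    sum(bad_sex)))
  }
  bad_age <- is.na(age) & keep
  if (any(bad_age)) {
    keep[bad_age] <- FALSE
    warnings <- c(warnings, sprintf("skipped %d record(s) with missing age",
                                    sum(bad_age)))
  }
  idx <- which(keep)
  row <- as.integer(floor(age[idx] / bin_years))
  side <- ifelse(sex[idx] == male_token, -1L, 1L)
  col0 <- ifelse(is.na(rank[idx]), 1L, rank[idx] + 1L)

  gx <- integer(length(idx))
  taken <- new.env(parent = emptyenv())
  for (k in seq_along(idx)) {
    key <- paste(side[k], row[k], sep = ":")
    cols <- if (is.null(taken[[key]])) integer() else taken[[key]]
    col <- stack_outward(col0[k], cols)
    taken[[key]] <- c(cols, col)
    gx[k] <- side[k] * col
  }
  new_placements(idx, gx, row, gz = 0, flip_rows = TRUE,
                 warnings = warnings)
}

#' Grouped small-multiples placement
#'
#' Partitions the records by a grouping variable (optionally binned into
#' fixed-width periods, e.g. 5-year examination periods), lays each group
#' out with `inner`, and offsets the sub-layouts left-to-right in ascending
#' key order so their bounding boxes cannot overlap. Empty groups yield an
#' empty, still-labeled sub-layout.
#'
#' @param dataset A [glyph_dataset()].
#' @param group_var Grouping variable name.
#' @param inner Layout function `(dataset, ...) -> glyph_placements`
#'   applied per group.
#' @param group_bin Optional numeric width: numeric keys are binned into
#'   `[k, k + group_bin)` periods labeled `"lo-hi"`.
#' @param gap Empty columns inserted between consecutive groups.
#' @param ... Passed to `inner`.
#' @return A `glyph_placements` data.frame with `group_key` filled in.
#' @export
layout_grouped <- function(dataset, group_var, inner = layout_age_pyramid,
                           group_bin = NULL, gap = 2L, ...) {
  rec <- dataset$records
  gval <- rec[[group_var]]
  if (is.null(gval)) stop("unknown grouping variable: ", group_var)
  if (!is.null(group_bin)) {
    lo <- floor(as.numeric(gval) / group_bin) * group_bin
    key <- sprintf("%d-%d", as.integer(lo), as.integer(lo + group_bin - 1))
    ord_keys <- unique(key[order(lo)])
  } else {
    key <- as.character(gval)
    ord_keys <- if (is.numeric(gval)) unique(key[order(as.numeric(gval))])
                else sort(unique(key))
  }
  decl <- meta_declarations(dataset)
  parts <- list()
  all_warn <- character()
  flip <- FALSE
  for (k in ord_keys) {
    sel <- which(key == k & !is.na(gval))
    sub_rec <- rec[sel, , drop = FALSE]
    rownames(sub_rec) <- NULL
    if (nrow(sub_rec) == 0) {
      parts[[k]] <- new_placements(integer(), integer(), integer())
      next
    }
    sub <- glyph_dataset(sub_rec, declared_scales = decl$declared_scales,
                         declared_orders = decl$declared_orders)
    pl <- inner(sub, ...)
    flip <- flip || isTRUE(attr(pl, "flip_rows"))
    all_warn <- c(all_warn, attr(pl, "warnings"))
    pl$record_index <- sel[pl$record_index]
    if (nrow(pl) > 0) pl$group_key <- k
    parts[[k]] <- pl
  }
  # inner row flips (age 0 at the base) are materialized here on a shared
  # row scale so the group baselines align
  if (flip) {
    max_row <- max(vapply(parts, function(p)
      if (nrow(p) > 0) max(p$gy) else -Inf, numeric(1)))
    parts <- lapply(parts, function(p) {
      if (nrow(p) > 0) p$gy <- as.integer(max_row) - p$gy
      p
    })
  }
  # groups are separated along screen x; in the dimetric view that axis is
  # gx - gy, so each sub-layout is shifted diagonally in gx until the
  # (gx - gy) ranges are disjoint, then moved back up-screen by adding the
  # same correction to gx and gy (which leaves screen x untouched)
  right_edge <- NULL
  for (k in names(parts)) {
    pl <- parts[[k]]
    if (nrow(pl) == 0) next
    d <- pl$gx - pl$gy
    shift <- if (is.null(right_edge)) -min(d)
             else right_edge + gap + 1L - min(d)
    pl$gx <- pl$gx + shift
    right_edge <- max(pl$gx - pl$gy)
    v <- -as.integer(round(shift / 2))
    pl$gx <- pl$gx + v
    pl$gy <- pl$gy + v
    parts[[k]] <- pl
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, class = c("glyph_placements", "data.frame"),
            flip_rows = FALSE, warnings = all_warn,
            group_keys = ord_keys)
}

# deterministic spiral walk over grid offsets, nearest-first
spiral_offsets <- function(radius) {
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  d <- abs(offs$dx) + abs(offs$dy)
  offs <- offs[order(d, offs$dx, offs$dy), ]
  as.matrix(offs)
}

#' Discretized scatter placement
#'
#' Places each record at the grid cell given by binning two variables;
#' nominal/ordinal variables use their domain rank, numeric variables
#' equal-width bins over the observed range. Cell collisions are resolved
#' by a deterministic spiral search (in dataset order) for the nearest free
#' cell — reproducible by construction, no randomness involved.
#'
#' @param dataset A [glyph_dataset()].
#' @param x_var,y_var Variable names.
#' @param x_bins,y_bins Bin counts for numeric variables.
#' @param max_jitter_radius Spiral search radius; running out of free cells
#'   within it is an error reporting the overflow count.
#' @return A `glyph_placements` data.frame.
#' @export
layout_scatter_discrete <- function(dataset, x_var, y_var, x_bins = 20L,
                                    y_bins = 20L, max_jitter_radius = 8L) {
  rec <- dataset$records
  bin_of <- function(v, meta, bins) {
    if (meta$scale %in% c("nominal", "ordinal")) match(as.character(v), meta$domain) - 1L
    else vapply(as.numeric(v), function(x)
      if (is.na(x)) NA_integer_ else quantize(x, meta, bins), integer(1))
  }
  xm <- dataset$variables[[x_var]]; ym <- dataset$variables[[y_var]]
  if (is.null(xm) || is.null(ym)) stop("unknown scatter variable")
  bx <- bin_of(rec[[x_var]], xm, x_bins)
  by <- bin_of(rec[[y_var]], ym, y_bins)
  keep <- which(!is.na(bx) & !is.na(by))

  offs <- spiral_offsets(max_jitter_radius)
  taken <- new.env(parent = emptyenv())
  gx <- integer(length(keep)); gy <- integer(length(keep))
  overflow <- 0L
  for (k in seq_along(keep)) {
    i <- keep[k]
    placed <- FALSE
    for (j in seq_len(nrow(offs))) {
      cx <- bx[i] + offs[j, 1]; cy <- by[i] + offs[j, 2]
      key <- paste(cx, cy, sep = ":")
      if (is.null(taken[[key]])) {
        taken[[key]] <- TRUE
        gx[k] <- cx; gy[k] <- cy
        placed <- TRUE
        break
      }
    }
    if (!placed) overflow <- overflow + 1L
  }
  if (overflow > 0)
    stop("grid saturated: ", overflow,
         " record(s) found no free cell within radius ", max_jitter_radius)
  new_placements(keep, gx, gy,
                 warnings = if (length(keep) < nrow(rec))
                   sprintf("skipped %d record(s) with missing coordinates",
                           nrow(rec) - length(keep)) else character())
}

#' Painter's (back-to-front) draw order
#'
#' Returns the permutation of placement rows that draws glyphs back to
#' front for the standard dimetric camera: ascending depth `gx + gy`, ties
#' broken by `gx`, then by record index. A glyph is never overdrawn by one
#' behind it.
#'
#' @param placements A `glyph_placements` data.frame.
#' @return An integer permutation of `seq_len(nrow(placements))`.
#' @export
paint_order <- function(placements) {
  order(placements$gx + placements$gy, placements$gx,
        placements$record_index)
}
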