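# Scene and histogram-panel rendering. SVG is the reference output: a
# scene is a deterministic text file, byte-identical across runs for
# identical inputs. The PNG path rasterizes the same polygons with the
# deterministic software rasterizer and a sprite cache keyed by the
# glyph's resolved polygon set and zoom.

mix_colors <- function(c1, c2, w) {
  a <- grDevices::col2rgb(c1); b <- grDevices::col2rgb(c2)
  m <- a * (1 - w) + b * w
  toupper(grDevices::rgb(m[1], m[2], m[3], maxColorValue = 255))
}

# geometry -> screen-local polygons at a zoom level (pixel offsets from the
# glyph anchor)
local_polys <- function(geometry, grid, zoom = 1) {
  hw <- grid$cell_w_px / 2 * zoom
  hh <- grid$cell_h_px / 2 * zoom
  zs <- grid$z_scale_px * zoom
  lapply(geometry$primitives, function(p)
    list(x = p$u * hw, y = p$v * hh - p$z * zs,
         fill = p$fill, outline = p$outline))
}

apply_row_flip <- function(placements) {
  if (isTRUE(attr(placements, "flip_rows")) && nrow(placements) > 0) {
    placements$gy <- max(placements$gy) - placements$gy
  }
  placements
}

scene_bounds <- function(anchors, polysets) {
  xr <- c(Inf, -Inf); yr <- c(Inf, -Inf)
  for (i in seq_along(polysets)) {
    for (p in polysets[[i]]) {
      xr[1] <- min(xr[1], anchors[i, 1] + min(p$x))
      xr[2] <- max(xr[2], anchors[i, 1] + max(p$x))
      yr[1] <- min(yr[1], anchors[i, 2] + min(p$y))
      yr[2] <- max(yr[2], anchors[i, 2] + max(p$y))
    }
  }
  list(x = xr, y = yr)
}

#' Render a glyph scene
#'
#' Draws the placed glyphs back-to-front (painter's order) onto a canvas
#' and writes SVG (reference output, byte-identical for identical inputs)
#' or PNG (deterministic rasterization; `.png` output uses a sprite cache
#' keyed by resolved glyph polygons and zoom whose result is
#' pixel-identical to uncached rasterization). When a highlight selection
#' is present, selected glyphs get a black outline and unselected glyph
#' fills are dimmed 40% toward the background.
#'
#' @param placements A `glyph_placements` data.frame.
#' @param geometries List of [build_geometry()] results parallel to the
#'   placement rows.
#' @param grid A [dimetric_grid()].
#' @param out Output path; `.svg` or `.png` decides the format.
#' @param canvas `NULL` to auto-size (bounds plus `margin`), or
#'   `list(width =, height =, background =)`; a canvas too small for the
#'   layout bounds is an error stating the required size.
#' @param highlight Optional logical selection vector (length = placement
#'   rows); defaults to the placements' `selected` column when any is set.
#' @param zoom Scale factor applied to the whole scene.
#' @param margin Auto-canvas margin in pixels.
#' @param background Canvas fill for the auto-sized canvas.
#' @param use_cache Use the sprite cache on the PNG path?
#' @return `out`, invisibly.
#' @export
render_scene <- function(placements, geometries, grid = dimetric_grid(),
                         out = "scene.svg", canvas = NULL, highlight = NULL,
                         zoom = 1, margin = 16, background = "#FFFFFF",
                         use_cache = TRUE) {
  stopifnot(nrow(placements) == length(geometries))
  placements <- apply_row_flip(placements)
  if (is.null(highlight)) {
    highlight <- if (any(placements$selected)) placements$selected else NULL
  }
  png_out <- grepl("\\.png$", out, ignore.case = TRUE)

  polysets <- lapply(geometries, local_polys, grid = grid, zoom = zoom)
  # dim / highlight resolved into the polygon fills before drawing
  bg <- if (!is.null(canvas) && !is.null(canvas$background))
    canvas$background else background
  if (!is.null(highlight)) {
    stopifnot(length(highlight) == length(polysets))
    for (i in seq_along(polysets)) {
      if (highlight[i]) {
        polysets[[i]] <- lapply(polysets[[i]], function(p) {
          p$outline <- "#000000"; p
        })
      } else {
        polysets[[i]] <- lapply(polysets[[i]], function(p) {
          p$fill <- mix_colors(p$fill, bg, 0.4); p
        })
      }
    }
  }

  anch <- project(placements$gx, placements$gy, 0, grid) * zoom
  b <- scene_bounds(anch, polysets)
  if (nrow(placements) == 0) b <- list(x = c(0, 0), y = c(0, 0))
  if (is.null(canvas)) {
    shift <- c(margin - b$x[1], margin - b$y[1])
    width <- ceiling(b$x[2] - b$x[1] + 2 * margin)
    height <- ceiling(b$y[2] - b$y[1] + 2 * margin)
  } else {
    width <- canvas$width; height <- canvas$height
    shift <- c(0, 0)
    need_w <- ceiling(b$x[2]); need_h <- ceiling(b$y[2])
    if (nrow(placements) > 0 &&
        (b$x[1] < 0 || b$y[1] < 0 || need_w > width || need_h > height))
      stop(sprintf(
        "canvas %dx%d too small for layout bounds; required at least %dx%d with a non-negative origin",
        width, height, need_w, need_h))
  }
  anch <- sweep(anch, 2, -shift)
  anch <- round(anch)   # integer anchors keep raster blits exact
  ord <- paint_order(placements)

  if (!png_out) {
    sw <- max(0.5, zoom * 0.5)
    chunks <- lapply(ord, function(i)
      vapply(polysets[[i]], function(p)
        svg_polygon(anch[i, 1] + p$x, anch[i, 2] + p$y, p$fill,
                    p$outline, stroke_width = sw),
        character(1)))
    lines <- c(svg_open(width, height, bg), unlist(chunks), svg_close())
    return(write_svg(lines, out))
  }

  ras <- new_raster(width, height, bg)
  cache <- new.env(parent = emptyenv())
  for (i in ord) {
    if (use_cache) {
      key <- paste(vapply(polysets[[i]], function(p)
        paste(c(format(p$x, digits = 10), format(p$y, digits = 10),
                p$fill), collapse = ","), character(1)), collapse = ";")
      sprite <- cache[[key]]
      if (is.null(sprite)) {
        sprite <- rasterize_sprite(polysets[[i]])
        cache[[key]] <- sprite
      }
      blit_sprite(ras, sprite, anch[i, 1], anch[i, 2])
    } else {
      for (p in polysets[[i]])
        raster_fill_polygon(ras, anch[i, 1] + p$x, anch[i, 2] + p$y,
                            p$fill)
    }
  }
  write_raster_png(ras, out)
  invisible(out)
}

HIST_BLUE <- "#6BAED6"
HIST_GREEN <- "#74C476"
HIST_RED <- "#D62728"
HIST_MISSING <- "#BDBDBD"

#' Render a linked-histogram panel
#'
#' One bar sub-panel per histogram: the overall distribution in blue, the
#' selected subgroup overlaid in green (bar-wise never taller than the
#' blue, by construction), active filter ranges drawn as red range
#' markers, and -- when present -- a separate gray-framed bar for missing
#' values. Output is deterministic SVG.
#'
#' @param histograms List of [compute_histogram()] results.
#' @param state Optional [filter_state()] whose ranges are drawn in red.
#' @param out Output SVG path.
#' @param panel_w,panel_h Sub-panel size in pixels.
#' @param per_row Sub-panels per row.
#' @return `out`, invisibly.
#' @export
render_histogram_panel <- function(histograms, state = NULL,
                                   out = "panel.svg", panel_w = 240,
                                   panel_h = 130, per_row = 4) {
  n <- length(histograms)
  stopifnot(n > 0)
  rows <- ceiling(n / per_row)
  pad <- 12
  width <- per_row * (panel_w + pad) + pad
  height <- rows * (panel_h + pad) + pad
  lines <- svg_open(width, height, "#FFFFFF")
  for (k in seq_len(n)) {
    h <- histograms[[k]]
    px <- pad + ((k - 1) %% per_row) * (panel_w + pad)
    py <- pad + ((k - 1) %/% per_row) * (panel_h + pad)
    lines <- c(lines,
               svg_rect(px, py, panel_w, panel_h, "#FAFAFA",
                        outline = "#CCCCCC"),
               svg_text(px + 4, py + 12, h$variable, size = 10))
    has_missing <- !is.na(h$missing_overall) && h$missing_overall > 0
    nb <- length(h$overall_counts) + has_missing
    plot_x <- px + 4; plot_y <- py + 18
    plot_w <- panel_w - 8; plot_h <- panel_h - 30
    bw <- plot_w / nb
    maxc <- max(c(h$overall_counts,
                  if (has_missing) h$missing_overall else 0L, 1L))
    bar <- function(j, count, fill, outline = NA_character_, frac = 1) {
      bh <- count / maxc * plot_h
      svg_rect(plot_x + (j - 1) * bw + bw * (1 - frac) / 2,
               plot_y + plot_h - bh, bw * frac, bh, fill, outline)
    }
    for (j in seq_along(h$overall_counts)) {
      if (h$overall_counts[j] > 0)
        lines <- c(lines, bar(j, h$overall_counts[j], HIST_BLUE))
      if (h$selected_counts[j] > 0)
        lines <- c(lines, bar(j, h$selected_counts[j], HIST_GREEN,
                              frac = 0.6))
    }
    if (has_missing) {
      j <- nb
      lines <- c(lines, bar(j, h$missing_overall, HIST_MISSING,
                            outline = "#888888"))
      if (h$missing_selected > 0)
        lines <- c(lines, bar(j, h$missing_selected, HIST_GREEN,
                              frac = 0.6))
    }
    # red range markers for the active filter on this variable
    e <- if (!is.null(state)) state$ranges[[h$variable]] else NULL
    if (!is.null(e)) {
      marker <- function(x) svg_line(x, plot_y, x, plot_y + plot_h,
                                     HIST_RED, width = 1.5)
      if (is.numeric(e) && h$kind == "numeric") {
        pos <- function(v) {
          edges <- h$edges
          t <- (v - edges[1]) / (edges[length(edges)] - edges[1])
          plot_x + min(max(t, 0), 1) * (length(h$overall_counts) /
                                          nb) * plot_w
        }
        lines <- c(lines, marker(pos(e[1])), marker(pos(e[2])))
      } else {
        idx <- if (is.numeric(e)) seq(e[1], e[2])
               else match(e, h$categories)
        for (j in idx[!is.na(idx)])
          lines <- c(lines,
                     svg_line(plot_x + (j - 1) * bw, plot_y + plot_h + 3,
                              plot_x + j * bw, plot_y + plot_h + 3,
                              HIST_RED, width = 2.5))
      }
    }
    lines <- c(lines,
               svg_line(plot_x, plot_y + plot_h, plot_x + plot_w,
                        plot_y + plot_h, "#888888", width = 1))
  }
  lines <- c(lines, svg_close())
  write_svg(lines, out)
}
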