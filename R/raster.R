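# Deterministic software rasterizer for the PNG output path. Pixels are
# sampled at their centers with an even-odd point-in-polygon test and no
# antialiasing, so coverage is translation-invariant under integer shifts;
# this is what makes the sprite cache exactly transparent (cached and
# direct rasterization are pixel-identical) and PNG output reproducible
# across machines.

# even-odd point-in-polygon, vectorized over points
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# canvas: integer matrix of palette indices (0 = untouched) + color table
new_raster <- function(width, height, background = "#FFFFFF") {
  env <- new.env(parent = emptyenv())
  env$width <- as.integer(width); env$height <- as.integer(height)
  env$pix <- matrix(1L, nrow = height, ncol = width)
  env$colors <- background
  env
}

raster_color_index <- function(ras, col) {
  i <- match(col, ras$colors)
  if (is.na(i)) {
    ras$colors <- c(ras$colors, col)
    i <- length(ras$colors)
  }
  i
}

# fill one polygon (screen coords) into the canvas
raster_fill_polygon <- function(ras, xs, ys, fill) {
  x0 <- max(floor(min(xs)), 0); x1 <- min(ceiling(max(xs)), ras$width - 1)
  y0 <- max(floor(min(ys)), 0); y1 <- min(ceiling(max(ys)), ras$height - 1)
  if (x1 < x0 || y1 < y0) return(invisible(NULL))
  gx <- seq.int(x0, x1); gy <- seq.int(y0, y1)
  px <- rep(gx, times = length(gy)) + 0.5
  py <- rep(gy, each = length(gx)) + 0.5
  inside <- points_in_polygon(px, py, xs, ys)
  if (!any(inside)) return(invisible(NULL))
  ci <- raster_color_index(ras, fill)
  cols <- rep(gx, times = length(gy))[inside] + 1L
  rows <- rep(gy, each = length(gx))[inside] + 1L
  ras$pix[cbind(rows, cols)] <- ci
  invisible(NULL)
}

raster_to_rgba <- function(ras) {
  rgb <- grDevices::col2rgb(ras$colors) / 255
  arr <- array(0, dim = c(ras$height, ras$width, 3))
  arr[, , 1] <- matrix(rgb[1, ras$pix], nrow = ras$height)
  arr[, , 2] <- matrix(rgb[2, ras$pix], nrow = ras$height)
  arr[, , 3] <- matrix(rgb[3, ras$pix], nrow = ras$height)
  arr
}

# --- sprites ---------------------------------------------------------------

# rasterize a glyph's screen-local polygons once; the sprite records, per
# pixel, the palette index to stamp (0 = leave canvas untouched)
rasterize_sprite <- function(polys) {
  if (length(polys) == 0)
    return(list(ox = 0L, oy = 0L, w = 0L, h = 0L,
                idx = matrix(0L, 0, 0), colors = character()))
  all_x <- unlist(lapply(polys, `[[`, "x"))
  all_y <- unlist(lapply(polys, `[[`, "y"))
  ox <- floor(min(all_x)); oy <- floor(min(all_y))
  w <- ceiling(max(all_x)) - ox + 1L
  h <- ceiling(max(all_y)) - oy + 1L
  idx <- matrix(0L, nrow = h, ncol = w)
  colors <- character()
  for (p in polys) {
    i <- match(p$fill, colors)
    if (is.na(i)) { colors <- c(colors, p$fill); i <- length(colors) }
    xs <- p$x - ox; ys <- p$y - oy
    x0 <- max(floor(min(xs)), 0); x1 <- min(ceiling(max(xs)), w - 1)
    y0 <- max(floor(min(ys)), 0); y1 <- min(ceiling(max(ys)), h - 1)
    if (x1 < x0 || y1 < y0) next
    gx <- seq.int(x0, x1); gy <- seq.int(y0, y1)
    px <- rep(gx, times = length(gy)) + 0.5
    py <- rep(gy, each = length(gx)) + 0.5
    inside <- points_in_polygon(px, py, xs, ys)
    if (!any(inside))
      next
    idx[cbind(rep(gy, each = length(gx))[inside] + 1L,
              rep(gx, times = length(gy))[inside] + 1L)] <- i
  }
  list(ox = as.integer(ox), oy = as.integer(oy), w = as.integer(w),
       h = as.integer(h), idx = idx, colors = colors)
}

# stamp a sprite onto the canvas at integer anchor (ax, ay)
blit_sprite <- function(ras, sprite, ax, ay) {
  if (sprite$w == 0) return(invisible(NULL))
  x0 <- ax + sprite$ox; y0 <- ay + sprite$oy
  sub_x <- seq_len(sprite$w); sub_y <- seq_len(sprite$h)
  dst_x <- x0 + sub_x - 1L; dst_y <- y0 + sub_y - 1L
  keep_x <- dst_x >= 0 & dst_x < ras$width
  keep_y <- dst_y >= 0 & dst_y < ras$height
  if (!any(keep_x) || !any(keep_y)) return(invisible(NULL))
  idx <- sprite$idx[sub_y[keep_y], sub_x[keep_x], drop = FALSE]
  ci_map <- vapply(sprite$colors, function(col)
    raster_color_index(ras, col), integer(1))
  sel <- idx > 0L
  if (any(sel)) {
    block <- ras$pix[dst_y[keep_y] + 1L, dst_x[keep_x] + 1L, drop = FALSE]
    block[sel] <- ci_map[idx[sel]]
    ras$pix[dst_y[keep_y] + 1L, dst_x[keep_x] + 1L] <- block
  }
  invisible(NULL)
}

write_raster_png <- function(ras, path) {
  png::writePNG(raster_to_rgba(ras), target = path)
  invisible(path)
}
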