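# Color mapping between data values and glyph fills.
#
# Three kinds, matching the ways a primary attribute can drive glyph color:
# direct (categorical palette over the domain), gradient (sequential
# interpolation between two endpoint colors; the only kind that preserves
# order), and custom (an explicit value -> color table, total on the domain).
# Missing values always map to missing_color (white by default): missing
# staging renders as white glyphs so data gaps stay visible.

#' Construct a color map
#'
#' @param kind `"direct"`, `"gradient"` or `"custom"`.
#' @param palette For `direct`: vector of colors cycled over the domain
#'   (default: Okabe-Ito, colorblind-safe, 9 classes max by default).
#' @param low,high For `gradient`: distinct endpoint colors.
#' @param table For `custom`: named vector, value token -> color; must be
#'   total on the variable's domain at resolve time.
#' @param missing_color Fill for missing values (default white).
#' @return An object of class `colormap`.
#' @export
colormap <- function(kind = c("direct", "gradient", "custom"),
                     palette = NULL, low = "#DEEBF7", high = "#08306B",
                     table = NULL, missing_color = "#FFFFFF") {
  kind <- match.arg(kind)
  if (kind == "gradient" && identical(low, high))
    stop("gradient endpoints must be distinct")
  if (kind == "custom" && (is.null(table) || is.null(names(table))))
    stop("custom colormap requires a named value -> color table")
  if (kind == "direct" && is.null(palette))
    palette <- grDevices::palette.colors(9, palette = "Okabe-Ito")
  structure(list(kind = kind, palette = unname(palette),
                 low = low, high = high, table = table,
                 missing_color = missing_color),
            class = "colormap")
}

#' @rdname colormap
#' @export
colormap_direct <- function(palette = NULL, missing_color = "#FFFFFF")
  colormap("direct", palette = palette, missing_color = missing_color)

#' @rdname colormap
#' @export
colormap_gradient <- function(low = "#DEEBF7", high = "#08306B",
                              missing_color = "#FFFFFF")
  colormap("gradient", low = low, high = high,
           missing_color = missing_color)

#' @rdname colormap
#' @export
colormap_custom <- function(table, missing_color = "#FFFFFF")
  colormap("custom", table = table, missing_color = missing_color)

#' Does a colormap preserve order?
#'
#' Hue alone is a nominal channel; only a sequential gradient restores an
#' ordering, so ordinal data on a color slot is fully valid only with a
#' gradient map.
#'
#' @param cm A [colormap()].
#' @return Logical.
#' @export
colormap_is_sequential <- function(cm) cm$kind == "gradient"

hex_upper <- function(col) toupper(substr(col, 1, 7))

#' Resolve a value to a fill color
#'
#' Direct maps index the palette by the value's domain position; gradients
#' interpolate between `low` and `high` by normalized rank (ordinal) or
#' normalized position in the numeric range (continuous/interval); custom
#' tables are looked up and must be total on the domain.
#'
#' @param cm A [colormap()].
#' @param value A single value (`NA` = missing).
#' @param meta The variable's [variable_meta()].
#' @return A hex color string `"#RRGGBB"`.
#' @export
resolve_color <- function(cm, value, meta) {
  if (length(value) != 1L || is.na(value)) return(hex_upper(cm$missing_color))
  if (cm$kind == "custom") {
    col <- cm$table[[as.character(value)]]
    if (is.null(col))
      stop("custom colormap not total: no color for value '", value,
           "' of ", meta$name)
    return(hex_upper(col))
  }
  if (cm$kind == "direct") {
    if (meta$scale %in% c("nominal", "ordinal")) {
      i <- match(as.character(value), meta$domain)
      if (is.na(i)) i <- 1L
    } else {
      i <- quantize(value, meta, steps = length(cm$palette)) + 1L
    }
    return(hex_upper(cm$palette[((i - 1L) %% length(cm$palette)) + 1L]))
  }
  # gradient
  t <- if (meta$scale %in% c("nominal", "ordinal")) {
    i <- match(as.character(value), meta$domain)
    if (is.na(i)) i <- 1L
    if (length(meta$domain) > 1L) (i - 1) / (length(meta$domain) - 1) else 0
  } else {
    lo <- meta$domain[1]; hi <- meta$domain[2]
    if (hi > lo) min(max((as.numeric(value) - lo) / (hi - lo), 0), 1) else 0
  }
  rgb <- grDevices::colorRamp(c(cm$low, cm$high))(t)
  hex_upper(grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255))
}
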