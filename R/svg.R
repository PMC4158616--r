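# Minimal deterministic SVG 1.1 emission. Coordinates are printed with a
# fixed two-decimal format so that identical scenes are byte-identical
# files, which is the reference output contract of the renderer.

svg_num <- function(x) {
  s <- sprintf("%.2f", x)
  s <- sub("\\.00$", "", s)
  sub("(\\.\\d)0$", "\\1", s)
}

svg_open <- function(width, height, background = "#FFFFFF") {
  c(sprintf(
      paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
             "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
      svg_num(width), svg_num(height), svg_num(width), svg_num(height)),
    sprintf("<rect x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"%s\"/>",
            svg_num(width), svg_num(height), background))
}

svg_polygon <- function(xs, ys, fill, outline = NA_character_,
                        stroke_width = 1) {
  pts <- paste(paste0(svg_num(xs), ",", svg_num(ys)), collapse = " ")
  stroke <- if (is.na(outline)) "" else
    sprintf(" stroke=\"%s\" stroke-width=\"%s\"", outline,
            svg_num(stroke_width))
  sprintf("<polygon points=\"%s\" fill=\"%s\"%s/>", pts, fill, stroke)
}

svg_rect <- function(x, y, w, h, fill, outline = NA_character_) {
  stroke <- if (is.na(outline)) "" else sprintf(" stroke=\"%s\"", outline)
  sprintf("<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"%s/>",
          svg_num(x), svg_num(y), svg_num(w), svg_num(h), fill, stroke)
}

svg_line <- function(x1, y1, x2, y2, stroke, width = 1) {
  sprintf("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"%s\"/>",
          svg_num(x1), svg_num(y1), svg_num(x2), svg_num(y2), stroke,
          svg_num(width))
}

svg_text <- function(x, y, text, size = 10, fill = "#333333",
                     anchor = "start") {
  sprintf("<text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"%s\" fill=\"%s\" text-anchor=\"%s\">%s</text>",
          svg_num(x), svg_num(y), svg_num(size), fill, anchor,
          xml_escape(text))
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_close <- function() "</svg>"

write_svg <- function(lines, path) {
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}
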