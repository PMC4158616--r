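# Config-driven pipeline: generate or load cases, validate the mapping,
# lay out, render the scene and the histogram panel, and write a manifest
# with content hashes. (config, seed) fully determines every output byte.

#' Construct a run configuration
#'
#' @param source Either `list(path = "cases.csv", meta = "cases.meta.yaml")`
#'   to load records, or `list(preset = "colon", n = , seed = )` /
#'   `list(preset = "mixed", seed = )` for synthetic data (a seed is
#'   required for synthetic sources).
#' @param mapping A [glyph_mapping()] or a path to a mapping YAML/JSON file
#'   (`slots: {1: {var: t_stage}, ...}`).
#' @param layout A list: `kind` (`"age_pyramid"`, `"grouped"` or
#'   `"scatter"`) plus the layout's parameters (`bin_years`, `group_var`,
#'   `group_bin`, `x_var`, `y_var`, ...).
#' @param filters Optional [filter_state()] or a named list of filter
#'   entries (`include_missing` taken from an `include_missing` element).
#' @param render Render options: `zoom`, `lod` (`"auto"` or a fixed
#'   level), `scene` and `panel` output paths, `png` (also write a PNG
#'   scene), `hist_vars` (variables for the panel; defaults to the mapped
#'   variables).
#' @param force Proceed even when the mapping validates red?
#' @return An object of class `run_config`.
#' @export
run_config <- function(source, mapping, layout = list(kind = "age_pyramid"),
                       filters = NULL, render = list(), force = FALSE) {
  stopifnot(is.list(source))
  if (!is.null(source$preset)) {
    if (is.null(source$seed))
      stop("synthetic source requires a seed")
  } else if (is.null(source$path)) {
    stop("source must give either a preset or a path")
  } else if (!file.exists(source$path)) {
    stop("source file does not exist: ", source$path)
  }
  if (is.character(mapping)) mapping <- read_mapping(mapping)
  stopifnot(inherits(mapping, "glyph_mapping"))
  if (!is.null(filters) && !inherits(filters, "filter_state")) {
    inc <- as.character(filters$include_missing)
    filters$include_missing <- NULL
    ranges <- lapply(filters, function(e)
      if (is.list(e)) unlist(e) else e)
    filters <- filter_state(ranges = ranges, include_missing = inc)
  }
  render <- utils::modifyList(
    list(zoom = 1, lod = "auto", scene = "scene.svg", panel = "panel.svg",
         png = FALSE, hist_vars = NULL, background = "#FFFFFF"),
    render)
  structure(list(source = source, mapping = mapping, layout = layout,
                 filters = filters, render = render, force = force),
            class = "run_config")
}

#' Read a mapping configuration file
#'
#' YAML/JSON with a `slots` table keyed by slot id:
#' `slots: {1: {var: t_stage, colormap: sequential, low: "#FEE0D2",
#' high: "#A50F15", steps: 10}, 2: {var: age}}`. `colormap` is
#' `"sequential"` (default for non-nominal variables), `"categorical"`, or
#' a named table under `table:`.
#'
#' @param path File path.
#' @return A [glyph_mapping()].
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  slots <- cfg$slots
  if (is.null(slots)) stop("mapping file lacks a 'slots' table")
  entries <- lapply(slots, function(e) {
    if (is.character(e)) return(list(var = e))
    ent <- list(var = e$var)
    if (!is.null(e$steps)) ent$steps <- as.integer(e$steps)
    if (!is.null(e$colormap)) {
      ent$colormap <- if (identical(e$colormap, "sequential")) {
        if (!is.null(e$low)) colormap_gradient(e$low, e$high)
        else colormap_gradient()
      } else if (identical(e$colormap, "categorical")) {
        colormap_direct()
      } else if (identical(e$colormap, "custom")) {
        colormap_custom(unlist(e$table))
      } else stop("unknown colormap kind: ", e$colormap)
    }
    ent
  })
  names(entries) <- names(slots)
  glyph_mapping(assignments = entries)
}

run_layout <- function(dataset, lay) {
  kind <- if (is.null(lay$kind)) "age_pyramid" else lay$kind
  arg <- function(name, default) if (is.null(lay[[name]])) default
                                 else lay[[name]]
  switch(kind,
    age_pyramid = layout_age_pyramid(
      dataset, sex_var = arg("sex_var", "sex"),
      age_var = arg("age_var", "age"),
      stage_var = arg("stage_var", "t_stage"),
      bin_years = arg("bin_years", 5)),
    grouped = layout_grouped(
      dataset, group_var = arg("group_var", "exam_year"),
      group_bin = lay$group_bin, gap = arg("gap", 2L),
      inner = layout_age_pyramid,
      sex_var = arg("sex_var", "sex"), age_var = arg("age_var", "age"),
      stage_var = arg("stage_var", "t_stage"),
      bin_years = arg("bin_years", 5)),
    scatter = layout_scatter_discrete(
      dataset, x_var = lay$x_var, y_var = lay$y_var,
      x_bins = arg("x_bins", 20L), y_bins = arg("y_bins", 20L)),
    stop("unknown layout kind: ", kind))
}

load_run_source <- function(source) {
  if (!is.null(source$preset)) {
    if (identical(source$preset, "mixed")) {
      make_comparison_cohorts(seed = source$seed)
    } else {
      generate_cases(preset_config(source$preset, n = source$n),
                     seed = source$seed)
    }
  } else {
    read_cases(source$path, meta = source$meta)
  }
}

#' Execute a configured run
#'
#' Pipeline: generate or load the dataset, validate the mapping (a red
#' verdict aborts before any image is written unless `force`), apply the
#' filters, lay out, pick the level of detail, render the scene and the
#' histogram panel, and return a manifest of the produced files with
#' their MD5 content hashes plus the validation report and a warning log.
#'
#' @param config A [run_config()].
#' @param out_dir Directory for the output files.
#' @return An object of class `glyph_run_result`: `manifest` (data.frame
#'   file/md5), `report` ([validate_mapping()] result), `lod`, `log`
#'   (character warnings), `n_records`, `n_selected`.
#' @export
glyph_run <- function(config, out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  dataset <- load_run_source(config$source)
  report <- validate_mapping(config$mapping, dataset$variables)
  if (report$overall == "red" && !config$force) {
    cond <- structure(
      class = c("glyphscape_red_mapping", "error", "condition"),
      list(message = paste0(
             "mapping validates red; no images written (use force to override):\n",
             paste(utils::capture.output(print(report)), collapse = "\n")),
           call = sys.call(-1), report = report))
    stop(cond)
  }
  if (report$overall != "green")
    log <- c(log, paste0("mapping validated ", report$overall))

  mask <- if (is.null(config$filters)) rep(TRUE, nrow(dataset$records))
          else apply_filter(dataset, config$filters)
  placements <- run_layout(dataset, config$layout)
  log <- c(log, attr(placements, "warnings"))
  placements$selected <- mask[placements$record_index]

  grid <- dimetric_grid()
  zoom <- config$render$zoom
  lod <- config$render$lod
  if (identical(lod, "auto"))
    lod <- select_lod(min(grid$cell_w_px, grid$cell_h_px) * zoom)
  geoms <- build_geometries(dataset, placements, config$mapping, lod)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scene_path <- file.path(out_dir, config$render$scene)
  highlight <- if (any(!mask)) placements$selected else NULL
  render_scene(placements, geoms, grid, out = scene_path,
               highlight = highlight, zoom = zoom,
               background = config$render$background)
  files <- scene_path
  if (isTRUE(config$render$png)) {
    png_path <- sub("\\.svg$", ".png", scene_path)
    render_scene(placements, geoms, grid, out = png_path,
                 highlight = highlight, zoom = zoom,
                 background = config$render$background)
    files <- c(files, png_path)
  }

  hist_vars <- config$render$hist_vars
  if (is.null(hist_vars)) {
    hist_vars <- unique(vapply(config$mapping$assignments, `[[`,
                               character(1), "var"))
  }
  hists <- lapply(hist_vars, function(v)
    compute_histogram(dataset, v, mask = mask))
  panel_path <- file.path(out_dir, config$render$panel)
  render_histogram_panel(hists, state = config$filters, out = panel_path)
  files <- c(files, panel_path)

  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  structure(list(manifest = manifest, report = report, lod = lod,
                 log = log, n_records = nrow(dataset$records),
                 n_selected = sum(mask)),
            class = "glyph_run_result")
}

#' @export
print.glyph_run_result <- function(x, ...) {
  cat(sprintf("<glyph_run_result> %d records (%d selected), lod=%s, mapping=%s\n",
              x$n_records, x$n_selected, x$lod, x$report$overall))
  print(x$manifest, row.names = FALSE)
  for (w in x$log) cat("  warning:", w, "\n")
  invisible(x)
}

#' Read a full run configuration from YAML
#'
#' Top-level keys `source`, `mapping` (inline `slots:` table or a path
#' string), `layout`, `filters`, `render`, `force`; see [run_config()].
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as boolean; map it back
  if (!is.null(cfg$source) && "FALSE" %in% names(cfg$source) &&
      !"n" %in% names(cfg$source))
    names(cfg$source)[names(cfg$source) == "FALSE"] <- "n"
  mapping <- cfg$mapping
  if (is.list(mapping) && !is.null(mapping$slots)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(mapping, tmp)
    mapping <- read_mapping(tmp)
  }
  run_config(source = cfg$source, mapping = mapping,
             layout = if (is.null(cfg$layout)) list(kind = "age_pyramid")
                      else cfg$layout,
             filters = cfg$filters,
             render = if (is.null(cfg$render)) list() else cfg$render,
             force = isTRUE(cfg$force))
}
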