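stage_meta <- variable_meta("t", "ordinal", c("T1", "T2", "T3", "T4"), 4)
age_meta <- variable_meta("age", "continuous", c(0, 100), 101)

test_that("quantization preserves order and bins evenly", {
  expect_equal(quantize("T1", stage_meta, 10), 0L)
  expect_equal(quantize("T4", stage_meta, 10), 9L)
  expect_equal(quantize("T2", stage_meta, 4), 1L)
  expect_equal(quantize(50, age_meta, 10), 5L)
  expect_equal(quantize(0, age_meta, 10), 0L)
  expect_equal(quantize(100, age_meta, 10), 9L)
  expect_true(is.na(quantize(NA, age_meta, 10)))
  expect_warning(q <- quantize(140, age_meta, 10),
                 class = "glyphscape_clamp")
  expect_equal(q, 9L)
  # order preservation over the whole domain
  qs <- vapply(stage_meta$domain, quantize, integer(1),
               meta = stage_meta, steps = 7)
  expect_true(all(diff(qs) > 0))
})

render_fixture <- function(n = 30, seed = 5) {
  ds <- generate_cases(preset_config("thyroid", n = n), seed = seed)
  list(ds = ds, mapping = demo_mapping(), metas = ds$variables)
}

test_that("pixel geometry is one primitive in the primary color", {
  f <- render_fixture()
  rec <- as.list(f$ds$records[1, ])
  g <- build_geometry(rec, f$mapping, "pixel", metas = f$metas)
  expect_length(g$primitives, 1L)
  cm <- colormap_gradient()
  expect_equal(g$primitives[[1]]$fill,
               resolve_color(cm, rec$t_stage, f$metas$t_stage))
})

test_that("iconic and detail geometry have the documented primitive counts", {
  f <- render_fixture()
  rec <- as.list(f$ds$records[1, ])
  gi <- build_geometry(rec, f$mapping, "iconic", metas = f$metas)
  gd <- build_geometry(rec, f$mapping, "detail", metas = f$metas)
  # plinth 3 + base band 2 + body 2 + body top 1 + flat cap 3
  expect_length(gi$primitives, 11L)
  # + 3 sub-elements x (body 2 + cap 3)
  expect_length(gd$primitives, 26L)
})

test_that("missing primary staging renders white at every level", {
  f <- render_fixture()
  rec <- as.list(f$ds$records[1, ])
  rec$t_stage <- NA_character_
  for (lv in c("pixel", "iconic", "detail")) {
    g <- build_geometry(rec, f$mapping, lv, metas = f$metas)
    fills <- vapply(g$primitives, `[[`, character(1), "fill")
    non_plinth <- setdiff(unique(fills), c("#C8C8C8", "#909090"))
    expect_equal(non_plinth, "#FFFFFF", info = lv)
  }
})

test_that("the primary color dominates every level of detail", {
  f <- render_fixture(n = 25)
  for (i in seq_len(25)) {
    rec <- as.list(f$ds$records[i, ])
    px <- build_geometry(rec, f$mapping, "pixel", metas = f$metas)
    pixel_fill <- px$primitives[[1]]$fill
    for (lv in c("iconic", "detail")) {
      g <- build_geometry(rec, f$mapping, lv, metas = f$metas)
      fills <- vapply(g$primitives, `[[`, character(1), "fill")
      # east body face (index 7) and body top (8) carry the exact primary
      expect_equal(fills[7], pixel_fill, info = paste(i, lv))
      expect_equal(fills[8], pixel_fill, info = paste(i, lv))
    }
  }
})

test_that("no geometry exceeds the configured height limit", {
  f <- render_fixture(n = 40)
  geoms <- build_geometries(f$ds,
                            layout_age_pyramid(f$ds), f$mapping, "detail")
  hmax <- glyphscape:::geom_defaults$max_height_units
  for (g in geoms) {
    expect_lte(g$height_units, hmax)
    expect_lte(max(unlist(lapply(g$primitives, `[[`, "z"))), hmax)
  }
})

test_that("scene SVG output is deterministic and honors canvas bounds", {
  f <- render_fixture()
  pl <- layout_age_pyramid(f$ds)
  geoms <- build_geometries(f$ds, pl, f$mapping, "iconic")
  p1 <- tempfile(fileext = ".svg"); p2 <- tempfile(fileext = ".svg")
  render_scene(pl, geoms, out = p1)
  render_scene(pl, geoms, out = p2)
  expect_identical(readLines(p1), readLines(p2))
  # empty scene: background only
  p0 <- tempfile(fileext = ".svg")
  render_scene(pl[0, ], list(), canvas = list(width = 40, height = 30),
               out = p0)
  svg <- readLines(p0)
  expect_length(svg, 3L)   # svg open, background rect, close
  expect_error(
    render_scene(pl, geoms, canvas = list(width = 20, height = 20),
                 out = tempfile(fileext = ".svg")),
    "required at least")
})

test_that("sprite-cached and direct rasterization are pixel-identical", {
  f <- render_fixture(n = 60, seed = 12)
  pl <- layout_age_pyramid(f$ds)
  geoms <- build_geometries(f$ds, pl, f$mapping, "iconic")
  pa <- tempfile(fileext = ".png"); pb <- tempfile(fileext = ".png")
  render_scene(pl, geoms, out = pa, use_cache = TRUE, zoom = 1.5)
  render_scene(pl, geoms, out = pb, use_cache = FALSE, zoom = 1.5)
  expect_identical(png::readPNG(pa), png::readPNG(pb))
})

test_that("selection highlighting dims unselected glyph fills", {
  f <- render_fixture(n = 4)
  pl <- layout_age_pyramid(f$ds)
  geoms <- build_geometries(f$ds, pl, f$mapping, "iconic")
  sel <- c(TRUE, rep(FALSE, nrow(pl) - 1))
  p <- tempfile(fileext = ".svg")
  render_scene(pl, geoms, out = p, highlight = sel)
  svg <- paste(readLines(p), collapse = "\n")
  expect_match(svg, "stroke=\"#000000\"")   # highlighted outline present
  p_plain <- tempfile(fileext = ".svg")
  render_scene(pl, geoms, out = p_plain)
  expect_false(identical(readLines(p), readLines(p_plain)))
})

test_that("every cap stays partly visible in a packed grid", {
  # worst case for occlusion: a fully packed block with random heights;
  # each glyph gets a unique cap color so its visible pixels are countable
  n <- 25
  set.seed(77)
  rec <- data.frame(id = sprintf("g%02d", seq_len(n)),
                    h = sample(1:8, n, replace = TRUE),
                    k = rep("x", n), stringsAsFactors = FALSE)
  ds <- glyph_dataset(rec, declared_scales = c(
    id = "nominal", h = "continuous", k = "nominal"))
  pal <- toupper(grDevices::rainbow(n))
  cap_cm <- colormap_custom(stats::setNames(substr(pal, 1, 7), rec$id))
  mapping <- glyph_mapping(
    "1" = "k", "2" = "h",
    "3" = list(var = "id", colormap = cap_cm))
  cells <- expand.grid(gx = 0:4, gy = 0:4)
  pl <- data.frame(record_index = seq_len(n), gx = cells$gx, gy = cells$gy,
                   gz = 0, group_key = NA_character_, selected = FALSE)
  geoms <- build_geometries(ds, pl, mapping, "iconic")
  p <- tempfile(fileext = ".png")
  render_scene(pl, geoms, out = p, zoom = 2)
  img <- png::readPNG(p)
  hex <- toupper(grDevices::rgb(img[, , 1], img[, , 2], img[, , 3]))
  for (i in seq_len(n)) {
    visible <- sum(hex == substr(pal[i], 1, 7))
    expect_gte(visible, 3)
  }
})

test_that("histogram panels draw each variable with blue/green/red layers", {
  ds <- generate_cases(preset_config("colon", n = 400), seed = 6)
  vars <- c("exam_year", "sex", "age", "dfs_months", "t_stage", "n_stage",
            "m_stage", "grading")
  state <- filter_state(age = c(50, 60))
  mask <- apply_filter(ds, state)
  hists <- lapply(vars, function(v) compute_histogram(ds, v, mask = mask))
  p <- tempfile(fileext = ".svg")
  render_histogram_panel(hists, state = state, out = p)
  svg <- paste(readLines(p), collapse = "\n")
  for (v in vars) expect_match(svg, paste0(">", v, "</text>"), fixed = TRUE)
  expect_match(svg, "#6BAED6")
  expect_match(svg, "#74C476")
  expect_match(svg, "#D62728")
  expect_equal(length(gregexpr(">(exam_year|sex|age|dfs_months|t_stage|n_stage|m_stage|grading)</text>",
                               svg)[[1]]), 8L)
})
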