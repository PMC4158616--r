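test_that("level of detail switches strictly below 2 px and above 64 px", {
  expect_equal(select_lod(1), "pixel")
  expect_equal(select_lod(1.99), "pixel")
  expect_equal(select_lod(2), "iconic")
  expect_equal(select_lod(32), "iconic")
  expect_equal(select_lod(64), "iconic")
  expect_equal(select_lod(64.01), "detail")
  expect_equal(select_lod(65), "detail")
  # monotone in footprint
  fp <- sort(stats::runif(200, 0.1, 120))
  lv <- match(select_lod(fp), c("pixel", "iconic", "detail"))
  expect_true(all(diff(lv) >= 0))
})

test_that("dimetric projection evaluates the stated formula and is affine", {
  g <- dimetric_grid(cell_w_px = 32, cell_h_px = 16)
  expect_equal(unname(project(0, 0, 0, g)), matrix(c(0, 0), 1))
  expect_equal(unname(project(1, 0, 0, g)), matrix(c(16, 8), 1))
  expect_equal(unname(project(0, 1, 0, g)), matrix(c(-16, 8), 1))
  expect_equal(unname(project(0, 0, 2, g)), matrix(c(0, -16), 1))
  set.seed(3)
  for (k in 1:25) {
    a <- sample(-50:50, 3); b <- sample(-50:50, 3)
    lhs <- project(a[1], a[2], a[3], g) - project(b[1], b[2], b[3], g)
    rhs <- project(a[1] - b[1], a[2] - b[2], a[3] - b[3], g) -
      project(0, 0, 0, g)
    expect_equal(lhs, rhs)
  }
})

test_that("translating a glyph leaves its projected size unchanged", {
  g <- dimetric_grid()
  corners <- expand.grid(du = c(0, 1), dv = c(0, 1))
  size_at <- function(gx, gy) {
    p <- project(gx + corners$du, gy + corners$dv, 0, g)
    c(diff(range(p[, 1])), diff(range(p[, 2])))
  }
  base <- size_at(0, 0)
  expect_equal(size_at(3, 3), base)
  expect_equal(size_at(-7, 12), base)
})

pyramid_fixture <- function() {
  rec <- data.frame(
    sex = c("M", "F", "M", "M", "F", "X"),
    age = c(52, 52, 52, 30, 8, 40),
    t_stage = c("T2", "T1", "T2", NA, "T4", "T1"),
    stringsAsFactors = FALSE)
  glyph_dataset(rec, declared_scales = c(t_stage = "ordinal"),
                declared_orders = list(t_stage = c("T1", "T2", "T3", "T4")))
}

test_that("age pyramid places rows by age bin and columns by stage rank", {
  pl <- layout_age_pyramid(pyramid_fixture(), bin_years = 5)
  by_rec <- split(pl, pl$record_index)
  # male, age 52, T2 (rank 2): row 10, column -(2+1)
  expect_equal(by_rec[["1"]]$gy, 10L)
  expect_equal(by_rec[["1"]]$gx, -3L)
  # female on the right
  expect_gt(by_rec[["2"]]$gx, 0L)
  # identical (sex, bin, stage): stacked one column further out
  expect_equal(by_rec[["3"]]$gx, -4L)
  # missing stage sits in column 1, next to the axis
  expect_equal(abs(by_rec[["4"]]$gx), 1L)
  # unknown sex token skipped with a warning entry
  expect_false("6" %in% names(by_rec))
  expect_match(attr(pl, "warnings"), "unknown sex", all = FALSE)
  # one glyph per cell
  expect_equal(anyDuplicated(pl[, c("gx", "gy")]), 0L)
  expect_true(isTRUE(attr(pl, "flip_rows")))
})

test_that("grouped layout partitions records and separates group bounds", {
  ds <- generate_cases(preset_config("colon", n = 2000), seed = 4)
  pl <- layout_grouped(ds, "exam_year")
  keys <- attr(pl, "group_keys")
  expect_equal(keys, as.character(1984:2004))
  expect_length(keys, 21L)
  # every placed record in exactly one group
  expect_equal(anyDuplicated(pl$record_index), 0L)
  # screen-x extents disjoint in key order
  d <- split(pl$gx - pl$gy, pl$group_key)[keys]
  for (i in seq_len(length(keys) - 1))
    expect_lt(max(d[[i]]), min(d[[i + 1]]))
  # 5-year periods partition the same records
  pl5 <- layout_grouped(ds, "exam_year", group_bin = 5)
  expect_equal(attr(pl5, "group_keys"),
               c("1980-1984", "1985-1989", "1990-1994", "1995-1999",
                 "2000-2004"))
  expect_setequal(pl5$record_index, pl$record_index)
})

test_that("discretized scatter jitters deterministically to free cells", {
  rec <- data.frame(x = c(10, 90, 10, 10), y = c(10, 90, 10, 10))
  ds <- glyph_dataset(rec)
  pl <- layout_scatter_discrete(ds, "x", "y", x_bins = 10, y_bins = 10)
  expect_equal(anyDuplicated(pl[, c("gx", "gy")]), 0L)
  # distinct bins are kept as-is
  expect_equal(pl$gx[2], 9L)
  # colliding records land on an adjacent free cell
  expect_lte(abs(pl$gx[3] - pl$gx[1]) + abs(pl$gy[3] - pl$gy[1]), 1L)
  pl2 <- layout_scatter_discrete(ds, "x", "y", x_bins = 10, y_bins = 10)
  expect_identical(pl, pl2)
  # saturation is an error naming the overflow
  many <- glyph_dataset(data.frame(x = rep(1, 40), y = rep(1, 40)))
  expect_error(
    layout_scatter_discrete(many, "x", "y", x_bins = 2, y_bins = 2,
                            max_jitter_radius = 1L),
    "saturated")
})

test_that("painter order is back-to-front with the documented tie-breaks", {
  p1 <- data.frame(record_index = 1:2, gx = c(1L, 0L), gy = c(1L, 0L),
                   gz = 0, group_key = NA_character_, selected = FALSE)
  expect_equal(paint_order(p1), c(2L, 1L))
  p2 <- data.frame(record_index = 1:2, gx = c(2L, 0L), gy = c(0L, 2L),
                   gz = 0, group_key = NA_character_, selected = FALSE)
  expect_equal(paint_order(p2), c(2L, 1L))   # tie on gx+gy: smaller gx first
  set.seed(9)
  for (rep in 1:5) {
    n <- 50
    p <- data.frame(record_index = seq_len(n),
                    gx = sample(0:9, n, replace = TRUE),
                    gy = sample(0:9, n, replace = TRUE),
                    gz = 0, group_key = NA_character_, selected = FALSE)
    p <- p[!duplicated(p[, c("gx", "gy")]), ]
    expect_true(oracle_occlusion_ok(p, paint_order(p)))
  }
})

test_that("layouts are pure functions of their inputs", {
  ds <- generate_cases(preset_config("thyroid", n = 300), seed = 2)
  expect_identical(layout_age_pyramid(ds), layout_age_pyramid(ds))
  expect_identical(layout_grouped(ds, "exam_year", group_bin = 5),
                   layout_grouped(ds, "exam_year", group_bin = 5))
})
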