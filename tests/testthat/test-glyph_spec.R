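spec <- cubic_glyph_spec()

test_that("the cubic glyph exposes 16 slots split 1/6/9 across levels", {
  expect_length(spec$slots, 16L)
  levels <- vapply(spec$slots, `[[`, 1L, "level")
  expect_equal(sum(levels == 1L), 1L)
  expect_equal(sum(levels == 2L), 6L)
  expect_equal(sum(levels == 3L), 9L)
  expect_equal(spec$slots[[1]]$name, "primary color")
  hm <- spec$slots[[2]]
  expect_equal(hm$name, "height main cube")
  expect_equal(hm$vtype, "geometry-size")
  expect_equal(hm$scale_capability, "ordinal")
  expect_equal(hm$length_class, "long")
})

test_that("length-class capacities default to 10/25/256 and are ordered", {
  expect_equal(capacity("short", spec), 10L)
  expect_equal(capacity("medium", spec), 25L)
  expect_equal(capacity("long", spec), 256L)
  expect_lt(capacity("short", spec), capacity("medium", spec))
  expect_lt(capacity("medium", spec), capacity("long", spec))
  expect_error(capacity("gigantic", spec), "unknown length class")
  custom <- cubic_glyph_spec(capacities = c(short = 8, medium = 20,
                                            long = 100))
  expect_equal(capacity("short", custom), 8L)
})

test_that("scale compatibility separates nominal channels from ordered ones", {
  primary <- spec$slots[[1]]                 # color, nom/ord
  height <- spec$slots[[2]]                  # geometry-size, ordinal
  shape_nom <- visual_slot(1, "shape", 2, "geometry-shape", "nominal",
                           "long")
  expect_true(scale_compatible("nominal", primary))
  expect_true(scale_compatible("ordinal", primary))
  expect_false(scale_compatible("nominal", height))
  expect_true(scale_compatible("continuous", spec$slots[[6]]))  # height cap
  expect_true(scale_compatible("nominal", shape_nom))
  expect_false(scale_compatible("ordinal", shape_nom))
  expect_false(scale_compatible("continuous", shape_nom))
})

test_that("the three traffic-light verdicts reproduce on worked examples", {
  metas <- list(
    t_stage = variable_meta("t_stage", "ordinal", c("T1", "T2", "T3", "T4"),
                            4),
    organ = variable_meta("organ", "nominal", sprintf("o%02d", 1:30), 30))
  # ordinal stage with 4 values on the long ordinal height slot: green
  r1 <- validate_mapping(glyph_mapping("2" = "t_stage"), metas, spec)
  expect_equal(r1$per_slot$status, "green")
  expect_equal(r1$overall, "green")
  # 30-category organ on a short color slot (capacity 10): yellow
  r2 <- validate_mapping(glyph_mapping("3" = "organ"), metas, spec)
  expect_equal(r2$per_slot$status, "yellow")
  expect_match(r2$per_slot$reason, "length exceeded")
  # nominal organ on the ordinal height slot: red, and red dominates
  r3 <- validate_mapping(glyph_mapping("2" = "organ", "1" = "t_stage"),
                         metas, spec)
  expect_equal(r3$per_slot$status[r3$per_slot$slot == 2], "red")
  expect_equal(r3$overall, "red")
})

test_that("validator agrees with the independent rule interpreter exhaustively", {
  scales <- c("nominal", "ordinal", "interval", "continuous")
  for (sc in scales) {
    for (slot in spec$slots) {
      cap_n <- capacity(slot$length_class, spec)
      for (d in c(1L, cap_n, cap_n + 1L)) {
        meta <- oracle_meta(sc, d)
        mapping <- glyph_mapping(assignments =
          stats::setNames(list(list(var = "v")), slot$id))
        got <- validate_mapping(mapping, list(v = meta), spec)
        want <- oracle_slot_status(sc, slot, d, cap_n,
                                   sequential_cm = TRUE, steps = 10)
        expect_equal(got$per_slot$status, want,
                     info = sprintf("scale=%s slot=%d d=%d", sc, slot$id, d))
        expect_equal(got$overall, want)
      }
    }
  }
})

test_that("ordinal data on a color slot needs a sequential colormap", {
  metas <- list(g = variable_meta("g", "ordinal", c("G1", "G2", "G3"), 3))
  seq_map <- glyph_mapping("3" = list(var = "g",
                                      colormap = colormap_gradient()))
  cat_map <- glyph_mapping("3" = list(var = "g",
                                      colormap = colormap_direct()))
  expect_equal(validate_mapping(seq_map, metas, spec)$overall, "green")
  r <- validate_mapping(cat_map, metas, spec)
  expect_equal(r$overall, "yellow")
  expect_match(r$per_slot$reason, "sequential")
})

test_that("verdicts are monotone in distinct count and capacity", {
  set.seed(1)
  for (rep in 1:50) {
    slot <- spec$slots[[sample(16, 1)]]
    sc <- sample(c("nominal", "ordinal"), 1)
    d <- sample(1:300, 1)
    mapping <- glyph_mapping(assignments =
      stats::setNames(list(list(var = "v")), slot$id))
    st <- function(dd, sp) validate_mapping(
      mapping, list(v = oracle_meta(sc, dd)), sp)$per_slot$status
    rank <- c(green = 1, yellow = 2, red = 3)
    expect_lte(rank[[st(max(1L, d - sample(0:5, 1)), spec)]],
               rank[[st(d, spec)]])
    wider <- cubic_glyph_spec(capacities = c(short = 20, medium = 50,
                                             long = 512))
    expect_lte(rank[[st(d, wider)]], rank[[st(d, spec)]])
  }
})

test_that("mapped variables without metadata raise an error, not a verdict", {
  expect_error(validate_mapping(glyph_mapping("1" = "ghost"), list(), spec),
               "no metadata")
  expect_error(validate_mapping(glyph_mapping("99" = "x"),
                                list(x = oracle_meta("nominal", 2)), spec),
               "unknown slot")
})
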