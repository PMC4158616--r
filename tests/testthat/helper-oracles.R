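# Independent brute-force oracles used across the suite. Each is a direct
# transcription of the stated rules, kept structurally separate from the
# package implementation it checks.

# traffic-light rule interpreter: one slot, first principles
oracle_slot_status <- function(data_scale, slot, distinct, cap_n,
                               sequential_cm = TRUE, steps = 10) {
  fits <- if (data_scale == "nominal") {
    slot$scale_capability %in% c("nominal", "nom/ord")
  } else {
    slot$scale_capability %in% c("ordinal", "nom/ord")
  }
  if (!fits) return("red")
  eff <- if (data_scale %in% c("continuous", "interval"))
    min(distinct, steps) else distinct
  if (eff > cap_n) return("yellow")
  if (data_scale != "nominal" && slot$vtype == "color" &&
      slot$scale_capability == "nom/ord" && !sequential_cm)
    return("yellow")
  "green"
}

# metadata with a given scale and distinct-value count
oracle_meta <- function(scale, distinct) {
  if (scale %in% c("nominal", "ordinal")) {
    dom <- sprintf("v%03d", seq_len(distinct))
    variable_meta("v", scale, dom, distinct_count = distinct)
  } else {
    variable_meta("v", scale, c(0, 100), distinct_count = distinct)
  }
}

# O(n * k) per-record filter scan
oracle_filter_mask <- function(dataset, state) {
  rec <- dataset$records
  vapply(seq_len(nrow(rec)), function(i) {
    for (v in names(state$ranges)) {
      e <- state$ranges[[v]]
      val <- rec[[v]][i]
      if (is.na(val)) {
        if (!v %in% state$include_missing) return(FALSE)
        next
      }
      meta <- dataset$variables[[v]]
      ok <- if (is.numeric(e)) {
        x <- if (meta$scale == "ordinal") match(as.character(val),
                                                meta$domain)
             else as.numeric(val)
        x >= e[1] && x <= e[2]
      } else as.character(val) %in% e
      if (!ok) return(FALSE)
    }
    TRUE
  }, logical(1))
}

# pairwise occlusion constraints for the dimetric camera: glyph i must be
# drawn before glyph j whenever i is strictly deeper and their screen
# footprints (cell plus a nominal height extent) overlap
oracle_occlusion_ok <- function(placements, order,
                                grid = dimetric_grid(),
                                height_px = 24) {
  n <- nrow(placements)
  pos <- project(placements$gx, placements$gy, 0, grid)
  depth <- placements$gx + placements$gy
  rank <- integer(n)
  rank[order] <- seq_len(n)
  hw <- grid$cell_w_px / 2
  hh <- grid$cell_h_px / 2
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (depth[i] >= depth[j]) next
      overlap <- abs(pos[i, 1] - pos[j, 1]) < 2 * hw &&
        (pos[i, 2] + hh) > (pos[j, 2] - height_px) &&
        (pos[j, 2] + hh) > (pos[i, 2] - height_px)
      if (overlap && rank[i] > rank[j]) return(FALSE)
    }
  }
  TRUE
}

# tiny CSV writer for fixtures (independent of write_cases)
write_fixture_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

demo_mapping <- function()
  glyph_mapping("1" = "t_stage", "2" = "age", "3" = "deceased",
                "4" = "sex", "6" = "dfs_months")
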