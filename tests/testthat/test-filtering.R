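six_record_fixture <- function() {
  rec <- data.frame(
    age = c(55, 45, 60, NA, 58, 52),
    sex = c("F", "F", "M", "F", "F", "M"),
    t_stage = c("T1", "T2", NA, "T3", "T2", "T1"),
    stringsAsFactors = FALSE)
  glyph_dataset(rec, declared_scales = c(t_stage = "ordinal"),
                declared_orders = list(t_stage = c("T1", "T2", "T3", "T4")))
}

test_that("an empty filter selects everything", {
  ds <- generate_cases(cohort_config(n = 10), seed = 1)
  expect_equal(sum(apply_filter(ds, filter_state())), 10L)
})

test_that("conjunctive filters match the brute-force row scan", {
  ds <- six_record_fixture()
  st <- filter_state(age = c(50, 60), sex = "F")
  mask <- apply_filter(ds, st)
  expect_equal(mask, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(mask, oracle_filter_mask(ds, st))
  # missing values fail unless included
  st_inc <- filter_state(age = c(50, 60), include_missing = "age")
  expect_true(apply_filter(ds, st_inc)[4])
  expect_false(apply_filter(ds, filter_state(age = c(50, 60)))[4])
})

test_that("numeric ranges on unordered categories are rejected", {
  ds <- six_record_fixture()
  expect_error(apply_filter(ds, filter_state(sex = c(1, 2))),
               "nominal")
  # but ordinal variables accept rank ranges
  m <- apply_filter(ds, filter_state(t_stage = c(1, 2)))
  expect_equal(m, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_error(apply_filter(ds, filter_state(ghost = "x")), "not in dataset")
  expect_error(apply_filter(ds, filter_state(sex = "Z")), "not in domain")
})

test_that("random filter states agree with the oracle scan", {
  ds <- generate_cases(preset_config("colon", n = 400), seed = 8)
  set.seed(123)
  for (rep in 1:25) {
    entries <- list()
    if (runif(1) < 0.7) {
      lo <- runif(1, 0, 80); entries$age <- c(lo, lo + runif(1, 5, 30))
    }
    if (runif(1) < 0.5)
      entries$sex <- sample(c("M", "F"), sample(1:2, 1))
    if (runif(1) < 0.5)
      entries$t_stage <- sample(c("T1", "T2", "T3", "T4"), sample(1:3, 1))
    inc <- if (runif(1) < 0.3) "t_stage" else character()
    st <- filter_state(ranges = entries, include_missing = inc)
    expect_equal(apply_filter(ds, st), oracle_filter_mask(ds, st))
  }
})

test_that("filters over disjoint variables compose conjunctively", {
  ds <- generate_cases(preset_config("lung", n = 300), seed = 9)
  s1 <- filter_state(age = c(50, 70))
  s2 <- filter_state(sex = "M")
  both <- filter_state(age = c(50, 70), sex = "M")
  expect_equal(apply_filter(ds, both),
               apply_filter(ds, s1) & apply_filter(ds, s2))
})

test_that("histogram bins are half-open with a closed last bin", {
  ds <- glyph_dataset(data.frame(age = c(1, 5, 5, 9)))
  h <- compute_histogram(ds, "age", binning = list(width = 5))
  expect_equal(h$edges, c(0, 5, 10))
  expect_equal(h$overall_counts, c(1L, 3L))
  # value on the top edge falls into the (closed) last bin
  ds2 <- glyph_dataset(data.frame(age = c(0, 5, 10)))
  h2 <- compute_histogram(ds2, "age", binning = list(edges = c(0, 5, 10)))
  expect_equal(h2$overall_counts, c(1L, 2L))
  expect_error(
    compute_histogram(ds2, "age", binning = list(edges = c(0, 10, 5))),
    "strictly increasing")
})

test_that("histogram conservation and bin domination hold under any mask", {
  ds <- generate_cases(preset_config("thyroid", n = 500), seed = 10)
  set.seed(11)
  for (v in c("age", "t_stage", "sex", "dfs_months")) {
    mask <- runif(500) < 0.4
    h <- compute_histogram(ds, v, mask = mask)
    col <- ds$records[[v]]
    expect_equal(sum(h$overall_counts), sum(!is.na(col)))
    expect_equal(sum(h$selected_counts), sum(!is.na(col) & mask))
    expect_true(all(h$selected_counts <= h$overall_counts))
    expect_equal(h$missing_overall, sum(is.na(col)))
    h0 <- compute_histogram(ds, v, mask = rep(FALSE, 500))
    expect_true(all(h0$selected_counts == 0L))
    hall <- compute_histogram(ds, v)
    expect_equal(hall$selected_counts, hall$overall_counts)
  }
})

test_that("subgroup summaries compare two cohorts side by side", {
  ds <- make_comparison_cohorts(seed = 2)
  a <- apply_filter(ds, filter_state(organ = "thyroid"))
  b <- apply_filter(ds, filter_state(organ = "lung"))
  s <- subgroup_summary(ds, a, b, c("sex", "t_stage"))
  expect_equal(unname(s$totals["a"] + s$totals["b"]), nrow(ds$records))
  sex_tab <- s$tables$sex
  frac_m <- function(cnt) cnt[sex_tab$bin == "M"] / sum(cnt)
  expect_gt(frac_m(sex_tab$count_b), frac_m(sex_tab$count_a))
  # identical masks give identical tables
  s2 <- subgroup_summary(ds, a, a, "t_stage")
  expect_equal(s2$tables$t_stage$count_a, s2$tables$t_stage$count_b)
})
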