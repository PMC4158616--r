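# Seeded generator of cancer-registry-like case tables. The generator does
# not aim at clinically calibrated epidemiology; it reproduces the
# structural features a registry exploration tool must cope with: sex-skewed
# organ cohorts, T-stage-dependent mortality and disease-free survival,
# sex-biased missing staging, and age data-entry errors at exactly 0 and
# 100 years.

#' Cohort generator configuration
#'
#' @param n Number of cases.
#' @param organ Organ token stamped on every record.
#' @param male_fraction Probability of sex `"M"`.
#' @param age_mean,age_sd Age distribution (years); ages are drawn from a
#'   normal truncated to \\[0, 100\\] and rounded to whole years.
#' @param year_range Examination-year range `c(first, last)`, sampled
#'   uniformly.
#' @param t_stage_probs Probability vector over T1..T4 (sums to 1).
#' @param missing_t_rate Probability that the T-stage is missing; either a
#'   single rate or a named pair `c(M = , F = )` for a sex-biased rate.
#' @param mortality_by_t Probability of death per T class (length 4).
#' @param dfs_mean_by_t Mean disease-free survival per T class, in months
#'   (length 4); draws are exponential, truncated at `followup_months` and
#'   rounded to 0.1 months.
#' @param followup_months Administrative follow-up truncation (months).
#' @param outlier_rate Probability that a record's age is overwritten with
#'   0 or 100, emulating data-entry errors.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 1000L, organ = "organ",
                          male_fraction = 0.5,
                          age_mean = 60, age_sd = 15,
                          year_range = c(1984L, 2004L),
                          t_stage_probs = c(0.25, 0.35, 0.25, 0.15),
                          missing_t_rate = 0.05,
                          mortality_by_t = c(0.05, 0.15, 0.35, 0.6),
                          dfs_mean_by_t = c(90, 60, 36, 18),
                          followup_months = 240,
                          outlier_rate = 0) {
  stopifnot(n >= 0, age_sd > 0, length(year_range) == 2L,
            year_range[1] <= year_range[2],
            length(t_stage_probs) == 4L, length(mortality_by_t) == 4L,
            length(dfs_mean_by_t) == 4L, all(dfs_mean_by_t > 0),
            followup_months > 0)
  probs <- c(male_fraction, t_stage_probs, missing_t_rate, mortality_by_t,
             outlier_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (abs(sum(t_stage_probs) - 1) > 1e-9)
    stop("t_stage_probs must sum to 1 (got ", sum(t_stage_probs), ")")
  if (length(missing_t_rate) == 2L &&
      !setequal(names(missing_t_rate), c("M", "F")))
    stop("sex-specific missing_t_rate must be named c(M = , F = )")
  structure(list(n = as.integer(n), organ = organ,
                 male_fraction = male_fraction,
                 age_mean = age_mean, age_sd = age_sd,
                 year_range = as.integer(year_range),
                 t_stage_probs = t_stage_probs,
                 missing_t_rate = missing_t_rate,
                 mortality_by_t = mortality_by_t,
                 dfs_mean_by_t = dfs_mean_by_t,
                 followup_months = followup_months,
                 outlier_rate = outlier_rate),
            class = "cohort_config")
}

t_levels <- c("T1", "T2", "T3", "T4")
n_levels <- c("N0", "N1", "N2", "N3")
m_levels <- c("M0", "M1")
g_levels <- c("G1", "G2", "G3", "G4")

# declared scales/orders for generated tables
synthetic_declarations <- function() {
  list(declared_scales = c(organ = "nominal", sex = "nominal",
                           age = "continuous", exam_year = "continuous",
                           t_stage = "ordinal", n_stage = "ordinal",
                           m_stage = "ordinal", grading = "ordinal",
                           receptor = "nominal", deceased = "nominal",
                           dfs_months = "continuous",
                           os_months = "continuous"),
       declared_orders = list(t_stage = t_levels, n_stage = n_levels,
                              m_stage = m_levels, grading = g_levels))
}

rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 100) {
  # inverse-CDF sampling of the truncated normal: one uniform per draw,
  # keeps the consumed random-number count independent of the bounds
  u <- stats::runif(n)
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws `n` case records under `config`. Sex is Bernoulli, age a truncated
#' normal on \\[0, 100\\] rounded to years, examination year uniform on the
#' configured range, T-stage categorical with the configured probabilities
#' and then blanked with the (possibly sex-specific) missing rate, N/M
#' stage and grading correlated with T, the death flag Bernoulli per T
#' class, disease-free survival exponential per T class truncated at
#' follow-up, and overall survival bounded below by disease-free survival.
#' A fraction `outlier_rate` of records get their age overwritten with
#' exactly 0 or 100 years. The same `(config, seed)` pair always yields a
#' byte-identical dataset.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A [glyph_dataset()].
#' @export
generate_cases <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"), is.numeric(seed))
  n <- config$n
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  sex <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")
  age <- round(rtruncnorm01(n, config$age_mean, config$age_sd))
  year <- config$year_range[1] +
    floor(stats::runif(n) * (diff(config$year_range) + 1L))
  t_idx <- 1L + findInterval(stats::runif(n),
                             cumsum(config$t_stage_probs)[-4],
                             left.open = FALSE)
  t_stage <- t_levels[t_idx]
  miss_rate <- if (length(config$missing_t_rate) == 2L)
    unname(config$missing_t_rate[sex]) else rep(config$missing_t_rate, n)
  t_missing <- stats::runif(n) < miss_rate
  t_stage[t_missing] <- NA_character_

  # N/M/grading loosely follow T: higher T shifts the categorical weights
  draw_graded <- function(levels, base, slope) {
    k <- length(levels)
    out <- character(n)
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      w <- base + slope * (t_idx[i] - 1) * seq(0, 1, length.out = k)
      w <- pmax(w, 0.01); w <- w / sum(w)
      out[i] <- levels[1L + findInterval(u[i], cumsum(w)[-k])]
    }
    out
  }
  n_stage <- draw_graded(n_levels, c(0.7, 0.2, 0.07, 0.03), 0.5)
  m_stage <- draw_graded(m_levels, c(0.9, 0.1), 0.6)
  grading <- draw_graded(g_levels, c(0.3, 0.4, 0.2, 0.1), 0.4)
  n_stage[t_missing] <- NA_character_

  receptor <- ifelse(stats::runif(n) < 0.35, "pos", "neg")
  deceased <- stats::runif(n) < config$mortality_by_t[t_idx]
  dfs <- round(pmin(stats::rexp(n, rate = 1 / config$dfs_mean_by_t[t_idx]),
                    config$followup_months), 1)
  os <- round(pmin(dfs + stats::rexp(n, rate = 1 / 24) *
                     ifelse(deceased, 1, 2),
                   config$followup_months), 1)

  n_out <- stats::rbinom(1, n, config$outlier_rate)
  if (n_out > 0) {
    idx <- sample.int(n, n_out)
    age[idx] <- ifelse(stats::runif(n_out) < 0.5, 0, 100)
  }

  rec <- data.frame(organ = rep(config$organ, n), sex = sex, age = age,
                    exam_year = year, t_stage = t_stage, n_stage = n_stage,
                    m_stage = m_stage, grading = grading,
                    receptor = receptor,
                    deceased = ifelse(deceased, "yes", "no"),
                    dfs_months = dfs, os_months = os,
                    stringsAsFactors = FALSE)
  decl <- synthetic_declarations()
  glyph_dataset(rec, declared_scales = decl$declared_scales,
                declared_orders = decl$declared_orders,
                provenance = sprintf("synthetic:%s:n=%d:seed=%d",
                                     config$organ, n, as.integer(seed)))
}

#' Preset cohort configurations
#'
#' Qualitative emulations of registry cohorts: `thyroid` (female-skewed,
#' young, low mortality, small T, with age outliers at 0/100 injected as
#' data-entry errors), `lung` (male-skewed, older, high mortality, larger
#' T), `colon` (balanced sex, sex-biased missing T-staging: male 0.15
#' versus female 0.05).
#'
#' @param preset `"thyroid"`, `"lung"` or `"colon"`.
#' @param n Number of cases (defaults per preset: 2109 thyroid, 1782 lung,
#'   11000 colon).
#' @return A [cohort_config()].
#' @export
preset_config <- function(preset = c("thyroid", "lung", "colon"), n = NULL) {
  preset <- match.arg(preset)
  switch(preset,
    thyroid = cohort_config(
      n = if (is.null(n)) 2109L else n, organ = "thyroid",
      male_fraction = 0.25, age_mean = 45, age_sd = 16,
      t_stage_probs = c(0.45, 0.3, 0.17, 0.08),
      missing_t_rate = 0.04,
      mortality_by_t = c(0.02, 0.05, 0.12, 0.3),
      dfs_mean_by_t = c(140, 110, 70, 30),
      outlier_rate = 0.003),
    lung = cohort_config(
      n = if (is.null(n)) 1782L else n, organ = "lung",
      male_fraction = 0.72, age_mean = 65, age_sd = 11,
      t_stage_probs = c(0.12, 0.28, 0.35, 0.25),
      missing_t_rate = 0.06,
      mortality_by_t = c(0.3, 0.5, 0.7, 0.85),
      dfs_mean_by_t = c(60, 36, 18, 8),
      outlier_rate = 0),
    colon = cohort_config(
      n = if (is.null(n)) 11000L else n, organ = "colon",
      male_fraction = 0.53, age_mean = 68, age_sd = 12,
      t_stage_probs = c(0.2, 0.3, 0.35, 0.15),
      missing_t_rate = c(M = 0.15, F = 0.05),
      mortality_by_t = c(0.1, 0.25, 0.45, 0.7),
      dfs_mean_by_t = c(100, 70, 40, 16),
      outlier_rate = 0.001))
}

#' Two-cohort comparison dataset (thyroid versus lung)
#'
#' Concatenates a female-skewed, low-mortality thyroid-like cohort of 2109
#' cases (including a long-survivor subgroup with no death event and a few
#' age entry errors at 0/100) and a male-skewed, high-mortality lung-like
#' cohort of 1782 cases, tagged by organ — the canonical side-by-side
#' age-pyramid comparison.
#'
#' @param seed Integer seed.
#' @return A [glyph_dataset()] with 3891 records.
#' @export
make_comparison_cohorts <- function(seed = 1L) {
  a <- generate_cases(preset_config("thyroid"), seed = seed)
  b <- generate_cases(preset_config("lung"), seed = seed + 1L)
  bind_datasets(a, b, provenance = sprintf("synthetic:mixed:seed=%d",
                                           as.integer(seed)))
}

#' Concatenate datasets with identical variables
#'
#' @param ... [glyph_dataset()] objects sharing the same columns.
#' @param provenance Source tag of the result.
#' @return A [glyph_dataset()].
#' @export
bind_datasets <- function(..., provenance = "bind") {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  nm <- names(parts[[1]]$records)
  for (p in parts) stopifnot(identical(names(p$records), nm))
  rec <- do.call(rbind, lapply(parts, `[[`, "records"))
  rownames(rec) <- NULL
  decl <- meta_declarations(parts[[1]])
  glyph_dataset(rec, declared_scales = decl$declared_scales,
                declared_orders = decl$declared_orders,
                provenance = provenance)
}
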