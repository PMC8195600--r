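test_that("area/standard-length normalization is linear and guarded", {
  expect_equal(normalize_bmi(0, 5), 0)
  expect_equal(normalize_bmi(1000, 5), 200)
  expect_equal(normalize_bmi(2 * 1000, 2 * 5), normalize_bmi(1000, 5))
  expect_equal(normalize_bmi(2000, 5), 2 * normalize_bmi(1000, 5))
  expect_error(normalize_bmi(1000, 0), "input error")
  expect_error(normalize_bmi(-1, 5), "input error")
})

test_that("longitudinal summaries report means, CIs and group sizes", {
  m <- data.frame(fish_id = paste0("f", 1:6), group = "g", day = 0,
                  area_um2 = rep(500, 6), standard_length_mm = 5,
                  area_per_sl = 100)
  s <- summarize_longitudinal(m, "area")
  expect_equal(s$mean, 500)
  expect_equal(s$ci_hi - s$ci_lo, 0)
  expect_equal(s$n, 6)
  # n = 1 gets an undefined CI
  s1 <- summarize_longitudinal(m[1, , drop = FALSE], "area")
  expect_false(s1$ci_defined)
  # noiseless cohort: summary means equal the generator curves exactly
  p0 <- cohort_sim_params(between_fish_sd = 0, within_fish_sd = 0, seed = 1)
  co <- generate_cohort(p0)
  sa <- summarize_longitudinal(co, "area")
  for (g in p0$groups$label)
    expect_equal(sa$mean[sa$group == g][order(sa$day[sa$group == g])],
                 p0$area_curves[[g]])
  expect_error(summarize_longitudinal(co, "weight"), "unknown metric")
})

test_that("t-interval coverage of the day means is near nominal", {
  withr::local_seed(77)
  truth <- 100
  hits <- replicate(2000, {
    m <- data.frame(fish_id = paste0("f", 1:8), group = "g", day = 0,
                    area_um2 = rnorm(8, truth, 20), standard_length_mm = 5)
    m$area_per_sl <- m$area_um2 / 5
    s <- summarize_longitudinal(m, "area")
    s$ci_lo <= truth && truth <= s$ci_hi
  })
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})

test_that("two-group comparison reproduces exact Mann-Whitney behavior", {
  mk <- function(a, b) data.frame(
    fish_id = seq_len(length(a) + length(b)),
    group = rep(c("A", "B"), c(length(a), length(b))),
    day = 0, area_um2 = c(a, b), standard_length_mm = 5,
    area_per_sl = c(a, b) / 5)
  # permutation of the same values: U = n1 n2 / 2, p = 1
  r <- compare_groups(mk(c(1, 2, 3, 4), c(4, 1, 3, 2)), "area")
  expect_equal(r$statistic, 8)  # 4*4/2
  expect_equal(r$p_value, 1)
  # {1,2,3} vs {4,5,6}: exact two-sided p = 0.1
  r2 <- compare_groups(mk(c(1, 2, 3), c(4, 5, 6)), "area")
  expect_equal(r2$p_value, 0.1)
  expect_error(compare_groups(mk(numeric(0), c(1, 2)), "area"), "input error")
})

test_that("exact p-values match full enumeration for all n1 + n2 <= 8", {
  withr::local_seed(11)
  for (n1 in 2:4) for (n2 in n1:(8 - n1)) {
    for (rep in 1:3) {
      x <- sample(100, n1); y <- sample(100, n2)
      while (any(x %in% y)) y <- sample(100, n2)  # tie-free for exactness
      m <- data.frame(fish_id = seq_len(n1 + n2),
                      group = rep(c("A", "B"), c(n1, n2)), day = 0,
                      area_um2 = c(x, y), standard_length_mm = 5,
                      area_per_sl = c(x, y) / 5)
      expect_equal(compare_groups(m, "area")$p_value,
                   oracle_mw_exact_p(x, y),
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("multi-group comparison runs Kruskal-Wallis with Dunn post hoc", {
  withr::local_seed(21)
  m <- data.frame(fish_id = 1:30, group = rep(c("A", "B", "C"), each = 10),
                  day = 0,
                  area_um2 = c(rnorm(10, 100, 10), rnorm(10, 100, 10),
                               rnorm(10, 200, 10)),
                  standard_length_mm = 5)
  m$area_per_sl <- m$area_um2 / 5
  r <- compare_groups(m, "area")
  expect_match(r$method, "kruskal")
  expect_lt(r$p_value, 0.01)
  pw <- r$pairwise
  expect_equal(nrow(pw), 3)
  # adjusted p never below raw, and order-preserving under Holm
  expect_true(all(pw$p_adj >= pw$p_raw - 1e-15))
  o <- order(pw$p_raw)
  expect_true(all(diff(pw$p_adj[o]) >= -1e-15))
  # the separated group drives the significant pairs
  sig <- pw[pw$p_adj < 0.05, ]
  expect_true(all(sig$group1 == "C" | sig$group2 == "C"))
})

test_that("type-I error of the two-group test is near nominal at n = 10", {
  withr::local_seed(99)
  reps <- 2000
  p <- replicate(reps, {
    m <- data.frame(fish_id = 1:20, group = rep(c("A", "B"), each = 10),
                    day = 0, area_um2 = rnorm(20), standard_length_mm = 5)
    m$area_per_sl <- m$area_um2 / 5
    compare_groups(m, "area")$p_value
  })
  rate <- mean(p <= 0.05)
  expect_gte(rate, 0.03)  # exact test size at n=10 is 0.0433
  expect_lte(rate, 0.06)
})

test_that("percent-positive gate behaves at its definitional extremes", {
  ctl <- generate_flow_sample(50000, 0, seed = 1, condition = "low")
  same <- generate_flow_sample(50000, 0, seed = 2)
  expect_lt(abs(percent_positive(same, ctl) - 0.01), 0.005)
  # all sample events below the control minimum
  lo <- list(tdtomato = rep(0.001, 100))
  expect_equal(percent_positive(lo, ctl), 0, ignore_attr = TRUE)
  expect_error(percent_positive(list(tdtomato = numeric(0)), ctl), "input error")
})

test_that("percent positive recovers a planted mixture fraction", {
  ctl <- generate_flow_sample(1e5, 0, seed = 31, condition = "low")
  s <- generate_flow_sample(1e5, 0.3, seed = 32)
  expect_lt(abs(percent_positive(s, ctl) - 0.30), 0.01)
})

test_that("percent positive is invariant under monotone transforms", {
  ctl <- generate_flow_sample(5000, 0, seed = 41)
  s <- generate_flow_sample(5000, 0.25, seed = 42)
  base <- as.numeric(percent_positive(s, ctl))
  for (f in list(log1p, sqrt, function(x) x^3)) {
    ts <- list(tdtomato = f(s$events$tdtomato))
    tc <- list(tdtomato = f(ctl$events$tdtomato))
    expect_equal(as.numeric(percent_positive(ts, tc)), base)
  }
})

test_that("cohort CSV round trip preserves measurements", {
  co <- generate_cohort(cohort_sim_params(seed = 3))
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(back$measurements$area_um2, co$measurements$area_um2,
               tolerance = 1e-12)
  expect_equal(sort(back$design$days), co$design$days)
})
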