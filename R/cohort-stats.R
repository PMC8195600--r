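#' Normalize adipose area to standard length
#'
#' The BMI-like adiposity index: area divided by standard length, in
#' um^2 / mm (or px^2 / mm if areas are uncalibrated; do not mix units).
#'
#' @param area adipose area (um^2), >= 0.
#' @param standard_length standard length (mm), > 0.
#' @return `area / standard_length`.
#' @export
normalize_bmi <- function(area, standard_length) {
  if (any(standard_length <= 0))
    stopf("input error: standard_length must be > 0")
  if (any(area < 0)) stopf("input error: area must be >= 0")
  area / standard_length
}

metric_column <- function(metric) {
  switch(metric,
         area = "area_um2",
         standard_length = "standard_length_mm",
         area_per_sl = "area_per_sl",
         stopf("input error: unknown metric '%s' (use area, standard_length or area_per_sl)",
               metric))
}

#' Per-group, per-day longitudinal summary
#'
#' Mean and t-based 95\% confidence interval of the chosen metric for every
#' group and observation day. Groups with fewer than 2 fish on a day get an
#' undefined CI (`ci_defined = FALSE`).
#'
#' @param data a `cohort_dataset` (from [generate_cohort()]) or its
#'   `measurements` data.frame.
#' @param metric `"area"`, `"standard_length"` or `"area_per_sl"`.
#' @param conf confidence level.
#' @return data.frame with `group, day, n, mean, ci_lo, ci_hi, ci_defined`.
#' @export
summarize_longitudinal <- function(data, metric = "area", conf = 0.95) {
  meas <- if (inherits(data, "cohort_dataset")) data$measurements else data
  col <- metric_column(metric)
  if (!col %in% names(meas)) stopf("input error: column '%s' not found", col)
  sp <- split(meas[[col]], list(meas$group, meas$day), drop = TRUE)
  keys <- strsplit(names(sp), "\\.(?=[^.]*$)", perl = TRUE)
  out <- do.call(rbind, lapply(seq_along(sp), function(i) {
    v <- sp[[i]]
    n <- length(v)
    m <- mean(v)
    if (n >= 2L) {
      se <- sd(v) / sqrt(n)
      tq <- qt(1 - (1 - conf) / 2, df = n - 1L)
      lo <- m - tq * se; hi <- m + tq * se; def <- TRUE
    } else {
      lo <- NA_real_; hi <- NA_real_; def <- FALSE
    }
    data.frame(group = keys[[i]][1], day = as.numeric(keys[[i]][2]),
               n = n, mean = m, ci_lo = lo, ci_hi = hi, ci_defined = def,
               stringsAsFactors = FALSE)
  }))
  out[order(out$group, out$day), , drop = FALSE]
}

# Dunn's pairwise z-tests on the pooled ranks after a Kruskal-Wallis test,
# with tie correction and multiplicity adjustment.
dunn_test <- function(values, groups, p_adjust_method = "holm") {
  groups <- factor(groups)
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  labs <- levels(groups)
  pairs <- utils::combn(labs, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p_raw[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_raw = p_raw, p_adj = p.adjust(p_raw, p_adjust_method),
             stringsAsFactors = FALSE)
}

#' Nonparametric group comparison
#'
#' Two groups: two-sided Mann-Whitney (Wilcoxon rank-sum) test, exact for
#' small samples without ties, normal approximation with tie correction
#' otherwise. More than two groups: Kruskal-Wallis followed by Dunn's
#' pairwise z-tests with multiplicity adjustment (Holm by default); both raw
#' and adjusted p-values are reported.
#'
#' @param data a `cohort_dataset`, its `measurements` data.frame, or any
#'   data.frame with a `group` column and the metric column.
#' @param metric `"area"`, `"standard_length"` or `"area_per_sl"`.
#' @param day optional: restrict to one observation day.
#' @param p_adjust_method method for Dunn's adjusted p-values (see
#'   [stats::p.adjust()]).
#' @return A list of class `group_comparison`: `method`, `statistic`,
#'   `p_value`, `ns`, and for > 2 groups `pairwise` (Dunn's table).
#' @export
compare_groups <- function(data, metric = "area", day = NULL,
                           p_adjust_method = "holm") {
  meas <- if (inherits(data, "cohort_dataset")) data$measurements else data
  col <- metric_column(metric)
  if (!is.null(day)) meas <- meas[meas$day == day, , drop = FALSE]
  groups <- factor(meas$group)
  values <- meas[[col]]
  ns <- table(groups)
  if (any(ns == 0) || length(ns) < 2L)
    stopf("input error: need >= 2 non-empty groups")
  if (length(ns) == 2L) {
    labs <- levels(groups)
    x <- values[groups == labs[1]]; y <- values[groups == labs[2]]
    exact <- !anyDuplicated(values) && length(x) < 50 && length(y) < 50
    wt <- wilcox.test(x, y, alternative = "two.sided", exact = exact,
                      correct = !exact)
    out <- list(method = "mann-whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value, ns = as.integer(ns),
                groups = labs)
  } else {
    kw <- kruskal.test(values, groups)
    out <- list(method = "kruskal-wallis + dunn",
                statistic = unname(kw$statistic), p_value = kw$p.value,
                ns = as.integer(ns), groups = levels(groups),
                pairwise = dunn_test(values, groups, p_adjust_method))
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value, paste(x$ns, collapse = ", ")))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Dunn):\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}

#' Percent-positive flow gate from a control sample
#'
#' The gate is the `control_quantile` of the control (lipid-droplet-low)
#' sample's reporter intensities; the returned value is the fraction of
#' sample events strictly above the gate. The gate is the inverse-ECDF
#' (type 1) quantile, i.e. an actual control order statistic, which makes the
#' result invariant under any strictly monotone transform applied to both
#' sample and control.
#'
#' @param sample,control [generate_flow_sample()] objects (or data frames
#'   with a `tdtomato` column).
#' @param control_quantile quantile of the control defining the gate.
#' @return Fraction in \[0, 1\]; the gate value is attached as attribute
#'   `"gate"`.
#' @export
percent_positive <- function(sample, control, control_quantile = 0.99) {
  xs <- if (inherits(sample, "flow_sample")) sample$events$tdtomato
        else sample$tdtomato
  xc <- if (inherits(control, "flow_sample")) control$events$tdtomato
        else control$tdtomato
  if (length(xc) == 0L) stopf("input error: control sample is empty")
  if (length(xs) == 0L) stopf("input error: sample is empty")
  gate <- unname(quantile(xc, control_quantile, type = 1))
  frac <- mean(xs > gate)
  attr(frac, "gate") <- gate
  frac
}
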