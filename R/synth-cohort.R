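#' Parameters for the longitudinal growth-cohort simulator
#'
#' Each group has an expected standard-length curve (mm) and an expected
#' visceral adipose area curve (um^2) over the observation days. The default
#' emulates a fed-versus-fasted time course in juvenile (21 dpf) fish imaged
#' on days 0, 2, 5 and 7: fed fish grow and accrue adipose area, while fasted
#' fish hold adiposity through day 2 and lose it afterwards (delayed-onset
#' kinetics), with standard length plateauing.
#'
#' @param groups data.frame with columns `label`, `n_fish`, `kind`
#'   (`"fed"`, `"fasted"` or `"other"`; controls which monotonicity
#'   constraints are enforced).
#' @param days observation days, strictly ascending.
#' @param sl_curves named list (by group label) of expected standard length
#'   per day, mm.
#' @param area_curves named list (by group label) of expected area per day,
#'   um^2.
#' @param between_fish_sd fractional SD of a per-fish multiplicative random
#'   effect (shared across that fish's days; repeated measures).
#' @param within_fish_sd fractional SD of per-observation noise.
#' @param seed integer seed.
#' @return A list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(groups = data.frame(
                                label = c("fed", "fasted"),
                                n_fish = c(46L, 57L),
                                kind = c("fed", "fasted"),
                                stringsAsFactors = FALSE),
                              days = c(0, 2, 5, 7),
                              sl_curves = list(
                                fed = c(5.5, 6.0, 6.6, 7.0),
                                fasted = c(5.5, 5.5, 5.5, 5.5)),
                              area_curves = list(
                                fed = c(40000, 60000, 90000, 120000),
                                fasted = c(40000, 40000, 25000, 15000)),
                              between_fish_sd = 0.15,
                              within_fish_sd = 0.05,
                              seed = 1L) {
  if (is.unsorted(days, strictly = TRUE))
    stopf("input error: 'days' must be strictly ascending")
  stopifnot(is.data.frame(groups),
            all(c("label", "n_fish") %in% names(groups)))
  if (is.null(groups$kind)) groups$kind <- "other"
  assert_scalar_num(between_fish_sd, "between_fish_sd", min = 0)
  assert_scalar_num(within_fish_sd, "within_fish_sd", min = 0)
  for (g in groups$label) {
    sl <- sl_curves[[g]]; ar <- area_curves[[g]]
    if (is.null(sl) || is.null(ar) || length(sl) != length(days) ||
        length(ar) != length(days))
      stopf("curves for group '%s' must cover every observation day", g)
    kind <- groups$kind[groups$label == g]
    if (kind == "fed" && is.unsorted(sl))
      stopf("expected standard length must be non-decreasing for fed group '%s'", g)
    if (kind == "fasted") {
      i2 <- which(days <= 2)
      if (length(i2) > 1 && any(ar[i2] < 0.95 * ar[1]))
        stopf("fasted group '%s': expected area through day 2 must stay >= 95%% of day 0", g)
      after <- which(days > 2)
      if (length(after) > 0) {
        path <- ar[c(max(i2), after)]
        if (any(diff(path) >= 0))
          stopf("fasted group '%s': expected area must decline strictly after day 2", g)
      }
    }
  }
  structure(list(groups = groups, days = as.numeric(days),
                 sl_curves = sl_curves, area_curves = area_curves,
                 between_fish_sd = between_fish_sd,
                 within_fish_sd = within_fish_sd, seed = as.integer(seed)),
            class = "cohort_sim_params")
}

#' Preset: high-fat-diet versus control-feed cohort parameters
#'
#' Two-week diet time course (days 0, 7, 14): both groups grow, the
#' high-fat-diet group accrues visceral adipose area faster while standard
#' length stays similar between diets.
#'
#' @param seed integer seed.
#' @return A [cohort_sim_params()].
#' @export
cohort_sim_params_hfd <- function(seed = 1L) {
  cohort_sim_params(
    groups = data.frame(label = c("control", "hfd"), n_fish = c(57L, 61L),
                        kind = c("fed", "fed"), stringsAsFactors = FALSE),
    days = c(0, 7, 14),
    sl_curves = list(control = c(5.5, 7.0, 8.2), hfd = c(5.5, 7.0, 8.2)),
    area_curves = list(control = c(40000, 90000, 140000),
                       hfd = c(40000, 140000, 210000)),
    seed = seed)
}

#' Simulate a repeated-measures growth cohort
#'
#' Every fish keeps its identity across days: a per-fish multiplicative
#' random effect (fractional SD `between_fish_sd`) scales its whole
#' trajectory, and per-observation noise (`within_fish_sd`) perturbs each
#' measurement. With both SDs zero every trajectory equals the group mean
#' curve exactly.
#'
#' @param params a [cohort_sim_params()].
#' @return An object of class `cohort_dataset`: `measurements` (data.frame
#'   with `fish_id, group, day, area_um2, standard_length_mm, area_per_sl`)
#'   and `design` (`groups`, `days`, `repeated = TRUE`).
#' @export
generate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  withr::with_seed(params$seed, {
    out <- list()
    for (gi in seq_len(nrow(params$groups))) {
      g <- params$groups$label[gi]
      n <- params$groups$n_fish[gi]
      sl <- params$sl_curves[[g]]
      ar <- params$area_curves[[g]]
      for (f in seq_len(n)) {
        fid <- sprintf("%s_%03d", g, f)
        eff_a <- max(1 + rnorm(1, 0, params$between_fish_sd), 0.05)
        eff_s <- max(1 + rnorm(1, 0, params$between_fish_sd / 3), 0.05)
        for (di in seq_along(params$days)) {
          a <- ar[di] * eff_a * max(1 + rnorm(1, 0, params$within_fish_sd), 0)
          s <- sl[di] * eff_s * max(1 + rnorm(1, 0, params$within_fish_sd / 3), 0.05)
          out[[length(out) + 1L]] <- data.frame(
            fish_id = fid, group = g, day = params$days[di],
            area_um2 = a, standard_length_mm = s,
            area_per_sl = normalize_bmi(a, s), stringsAsFactors = FALSE)
        }
      }
    }
    meas <- do.call(rbind, out)
    structure(list(measurements = meas,
                   design = list(groups = params$groups$label,
                                 days = params$days, repeated = TRUE)),
              class = "cohort_dataset")
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d measurements, groups: %s, days: %s\n",
              nrow(x$measurements), paste(x$design$groups, collapse = ", "),
              paste(x$design$days, collapse = ", ")))
  invisible(x)
}

#' Simulate a two-population flow-cytometry sample
#'
#' Reporter (tdTomato) intensities are drawn from a two-component lognormal
#' mixture of lipid-droplet-negative and -positive cells; membership is
#' binomial with probability `fraction_positive`, and the true labels are
#' returned for recovery tests. GFP intensities mark all events as
#' reporter-line cells.
#'
#' @param n_cells number of events (>= 1).
#' @param fraction_positive probability an event is lipid-droplet positive.
#' @param neg_mu_sigma,pos_mu_sigma `c(meanlog, sdlog)` of the negative /
#'   positive component on the log intensity scale.
#' @param seed integer seed.
#' @param condition label stored on the sample.
#' @return An object of class `flow_sample`: `events` (data.frame with
#'   `tdtomato`, `gfp`), `condition`, `true_label` (logical).
#' @export
generate_flow_sample <- function(n_cells, fraction_positive,
                                 neg_mu_sigma = c(log(150), 0.4),
                                 pos_mu_sigma = c(log(3000), 0.4),
                                 seed = 1L, condition = "sample") {
  if (n_cells < 1L) stopf("n_cells must be >= 1")
  if (fraction_positive < 0 || fraction_positive > 1)
    stopf("fraction_positive must lie in [0, 1]")
  withr::with_seed(as.integer(seed), {
    pos <- rbinom(n_cells, 1L, fraction_positive) == 1L
    tdt <- numeric(n_cells)
    tdt[!pos] <- rlnorm(sum(!pos), neg_mu_sigma[1], neg_mu_sigma[2])
    tdt[pos] <- rlnorm(sum(pos), pos_mu_sigma[1], pos_mu_sigma[2])
    gfp <- rlnorm(n_cells, log(1000), 0.3)
    structure(list(events = data.frame(tdtomato = tdt, gfp = gfp),
                   condition = condition, true_label = pos),
              class = "flow_sample")
  })
}

#' Write / read a cohort as tidy CSV
#'
#' One row per fish-day with unit-bearing headers:
#' `fish_id, group, day, area_um2, standard_length_mm, area_per_sl`.
#'
#' @param data a `cohort_dataset` or its `measurements` data.frame.
#' @param path CSV path.
#' @return `path` (write) or a `cohort_dataset` (read).
#' @export
write_cohort_csv <- function(data, path) {
  meas <- if (inherits(data, "cohort_dataset")) data$measurements else data
  write.csv(meas, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  meas <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "group", "day", "area_um2", "standard_length_mm")
  if (!all(need %in% names(meas)))
    stopf("format error: cohort CSV needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(meas[, c("fish_id", "day")]))
    stopf("format error: duplicated (fish_id, day) pairs")
  if (is.null(meas$area_per_sl))
    meas$area_per_sl <- normalize_bmi(meas$area_um2, meas$standard_length_mm)
  structure(list(measurements = meas,
                 design = list(groups = unique(meas$group),
                               days = sort(unique(meas$day)), repeated = TRUE)),
            class = "cohort_dataset")
}
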