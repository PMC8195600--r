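#' Default 96-well screen layout
#'
#' Builds per-plate layouts for a compound screen: 80 compound wells per plate
#' (columns 2-11), DMSO vehicle wells in column 1 rows 1-4, positive-control
#' (lipolysis-stimulated) wells in column 1 rows 5-8, glycerol standards in
#' column 12 rows 1-6 carrying `standard_concs`, and column 12 rows 7-8 empty.
#' Compound ids `C0001..C<80*n_plates>` are assigned plate by plate in
#' column-major order.
#'
#' @param n_plates number of plates.
#' @param standard_concs glycerol standard ladder, mg/ml (>= 2 distinct).
#' @return A list of `n_plates` data frames (class `plate_layout`) with
#'   columns `well`, `row`, `col`, `role`, `compound_id`, `standard_conc`.
#' @export
default_screen_layout <- function(n_plates = 16L,
                                  standard_concs = seq(0, 1, length.out = 6)) {
  stopifnot(n_plates >= 1L, length(unique(standard_concs)) >= 2L)
  layouts <- vector("list", n_plates)
  next_id <- 1L
  for (p in seq_len(n_plates)) {
    row <- rep(1:8, times = 12)
    col <- rep(1:12, each = 8)
    role <- rep("compound", 96L)
    role[col == 1 & row <= 4] <- "dmso"
    role[col == 1 & row >= 5] <- "positive_control"
    role[col == 12 & row <= 6] <- "standard"
    role[col == 12 & row >= 7] <- "empty"
    compound_id <- rep(NA_character_, 96L)
    ncomp <- sum(role == "compound")
    compound_id[role == "compound"] <-
      sprintf("C%04d", seq(next_id, next_id + ncomp - 1L))
    next_id <- next_id + ncomp
    standard_conc <- rep(NA_real_, 96L)
    standard_conc[role == "standard"] <- standard_concs[row[role == "standard"]]
    lay <- data.frame(well = paste0(LETTERS[row], col), row = row, col = col,
                      role = role, compound_id = compound_id,
                      standard_conc = standard_conc,
                      stringsAsFactors = FALSE)
    class(lay) <- c("plate_layout", "data.frame")
    layouts[[p]] <- lay
  }
  layouts
}

validate_layout <- function(lay) {
  roles <- c("compound", "dmso", "positive_control", "standard", "empty")
  if (!all(lay$role %in% roles))
    stopf("layout error: unknown role(s): %s",
          paste(setdiff(unique(lay$role), roles), collapse = ", "))
  if (anyDuplicated(lay[, c("row", "col")]))
    stopf("layout error: a well is assigned more than one role")
  if (any(lay$role == "standard" & !is.finite(lay$standard_conc)))
    stopf("layout error: standard wells must carry concentrations")
  invisible(lay)
}

#' Default multiplicative well-position bias map
#'
#' Wells on the outer ring of the plate evaporate faster and read
#' systematically differently from interior wells; the default map raises the
#' border by `edge_amp` and corners by a further `corner_amp`.
#'
#' @param edge_amp fractional elevation of border wells.
#' @param corner_amp additional fractional elevation of the four corners.
#' @return 8 x 12 matrix of strictly positive factors.
#' @export
edge_bias_map <- function(edge_amp = 0.2, corner_amp = 0.1) {
  b <- matrix(1, 8, 12)
  b[1, ] <- b[8, ] <- b[, 1] <- b[, 12] <- 1 + edge_amp
  b[c(1, 8), c(1, 12)] <- 1 + edge_amp + corner_amp
  b
}

#' Parameters for the plate-screen simulator
#'
#' @param n_plates number of plates; ignored if `layouts` supplies its own.
#' @param layouts list of plate layouts, one per plate (default
#'   [default_screen_layout()]).
#' @param position_bias 8 x 12 strictly positive multiplicative bias grid.
#' @param baseline_glycerol vehicle-well glycerol concentration, mg/ml.
#' @param inhibitor_effects named numeric vector mapping compound id to a
#'   fractional reduction of glycerol release in \[0, 1\].
#' @param stimulated_fold fold increase of glycerol in positive-control wells.
#' @param cv fractional (lognormal) measurement noise; 0 = noiseless.
#' @param curve_slope,curve_intercept absorbance response: AU per mg/ml and
#'   blank AU.
#' @param seed integer seed.
#' @return A list of class `screen_sim_params`.
#' @export
screen_sim_params <- function(n_plates = 16L,
                              layouts = default_screen_layout(n_plates),
                              position_bias = edge_bias_map(),
                              baseline_glycerol = 0.4,
                              inhibitor_effects = NULL,
                              stimulated_fold = 3,
                              cv = 0.05,
                              curve_slope = 0.8,
                              curve_intercept = 0.05,
                              seed = 1L) {
  stopifnot(is.list(layouts), length(layouts) >= 1L)
  lapply(layouts, validate_layout)
  stopifnot(is.matrix(position_bias), all(dim(position_bias) == c(8L, 12L)))
  if (any(position_bias <= 0)) stopf("position_bias must be strictly positive")
  assert_scalar_num(baseline_glycerol, "baseline_glycerol", min = 0)
  assert_scalar_num(stimulated_fold, "stimulated_fold", min = 0)
  assert_scalar_num(cv, "cv", min = 0)
  assert_scalar_num(curve_slope, "curve_slope")
  assert_scalar_num(curve_intercept, "curve_intercept")
  if (!is.null(inhibitor_effects)) {
    if (is.null(names(inhibitor_effects)) || any(!nzchar(names(inhibitor_effects))))
      stopf("inhibitor_effects must be a named vector of compound ids")
    if (any(inhibitor_effects < 0 | inhibitor_effects > 1))
      stopf("fractional reductions must lie in [0, 1]")
    known <- unlist(lapply(layouts, function(l) l$compound_id))
    missing <- setdiff(names(inhibitor_effects), known)
    if (length(missing))
      stopf("layout error: inhibitor_effects names absent from layout: %s",
            paste(head(missing, 5L), collapse = ", "))
  }
  structure(list(n_plates = length(layouts), layouts = layouts,
                 position_bias = position_bias,
                 baseline_glycerol = baseline_glycerol,
                 inhibitor_effects = inhibitor_effects,
                 stimulated_fold = stimulated_fold, cv = cv,
                 curve_slope = curve_slope, curve_intercept = curve_intercept,
                 seed = as.integer(seed)),
            class = "screen_sim_params")
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)   # mean exactly 1
}

#' Simulate a glycerol-release compound screen
#'
#' Per biological well (compound / DMSO / positive control), glycerol is
#' `baseline * (1 - reduction) * position_bias * lognormal(cv)`; positive
#' controls use `baseline * stimulated_fold` instead. Absorbance is
#' `curve_slope * glycerol + curve_intercept`; standard wells carry their
#' nominal concentration (no position bias) with the same fractional noise on
#' absorbance; empty wells read the blank. The truth table records every
#' compound's planted fractional reduction.
#'
#' @param params a [screen_sim_params()].
#' @return `list(plates = list of screen_plate, truth = data.frame, params)`;
#'   each `screen_plate` has `plate_id`, `absorbance` (8 x 12 matrix) and
#'   `layout`.
#' @export
generate_screen <- function(params = screen_sim_params()) {
  stopifnot(inherits(params, "screen_sim_params"))
  withr::with_seed(params$seed, {
    plates <- vector("list", params$n_plates)
    truth <- list()
    for (p in seq_len(params$n_plates)) {
      lay <- params$layouts[[p]]
      absb <- matrix(NA_real_, 8, 12)
      red <- numeric(nrow(lay))
      for (i in seq_len(nrow(lay))) {
        r <- lay$row[i]; cc <- lay$col[i]
        role <- lay$role[i]
        if (role == "standard") {
          a <- params$curve_slope * lay$standard_conc[i] + params$curve_intercept
          absb[r, cc] <- a * lognormal_noise(1L, params$cv)
        } else if (role == "empty") {
          absb[r, cc] <- params$curve_intercept
        } else {
          redi <- 0
          if (role == "compound" && !is.null(params$inhibitor_effects)) {
            e <- params$inhibitor_effects[lay$compound_id[i]]
            if (!is.na(e)) redi <- unname(e)
          }
          fold <- if (role == "positive_control") params$stimulated_fold else 1 - redi
          gly <- params$baseline_glycerol * fold * params$position_bias[r, cc] *
            lognormal_noise(1L, params$cv)
          absb[r, cc] <- params$curve_slope * gly + params$curve_intercept
          red[i] <- redi
        }
      }
      comp <- lay$role == "compound"
      truth[[p]] <- data.frame(compound_id = lay$compound_id[comp],
                               plate_id = p, row = lay$row[comp],
                               col = lay$col[comp], reduction = red[comp],
                               stringsAsFactors = FALSE)
      plates[[p]] <- structure(list(plate_id = p, absorbance = absb, layout = lay),
                               class = "screen_plate")
    }
    list(plates = plates, truth = do.call(rbind, truth), params = params)
  })
}

#' @export
print.screen_plate <- function(x, ...) {
  cat(sprintf("<screen_plate> plate %s, absorbance 8 x 12, %d compound wells\n",
              x$plate_id, sum(x$layout$role == "compound")))
  invisible(x)
}

#' Write / read a screen as one tidy CSV
#'
#' One row per well: `plate_id, well, row, col, role, compound_id,
#' standard_conc_mg_ml, absorbance_au`.
#'
#' @param plates list of `screen_plate` objects.
#' @param path output CSV path.
#' @return `path` (write) or a list of `screen_plate` (read).
#' @export
write_screen_csv <- function(plates, path) {
  rows <- lapply(plates, function(pl) {
    lay <- pl$layout
    data.frame(plate_id = pl$plate_id, well = lay$well, row = lay$row,
               col = lay$col, role = lay$role, compound_id = lay$compound_id,
               standard_conc_mg_ml = lay$standard_conc,
               absorbance_au = pl$absorbance[cbind(lay$row, lay$col)],
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_csv
#' @export
read_screen_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "row", "col", "role", "absorbance_au")
  if (!all(need %in% names(tab)))
    stopf("format error: screen CSV needs columns %s", paste(need, collapse = ", "))
  lapply(split(tab, tab$plate_id), function(sub) {
    absb <- matrix(NA_real_, 8, 12)
    absb[cbind(sub$row, sub$col)] <- sub$absorbance_au
    lay <- data.frame(well = if ("well" %in% names(sub)) sub$well else
                        paste0(LETTERS[sub$row], sub$col),
                      row = sub$row, col = sub$col, role = sub$role,
                      compound_id = if ("compound_id" %in% names(sub))
                        sub$compound_id else NA_character_,
                      standard_conc = if ("standard_conc_mg_ml" %in% names(sub))
                        sub$standard_conc_mg_ml else NA_real_,
                      stringsAsFactors = FALSE)
    class(lay) <- c("plate_layout", "data.frame")
    structure(list(plate_id = sub$plate_id[1], absorbance = absb,
                   layout = validate_layout(lay)),
              class = "screen_plate")
  })
}
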