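#' Fit a glycerol standard curve
#'
#' Ordinary least squares of absorbance on concentration:
#' `absorbance = slope * conc + intercept`.
#'
#' @param conc glycerol standard concentrations, mg/ml (>= 2 distinct), or a
#'   two-column data frame `(conc, absorbance)`.
#' @param absorbance measured absorbances (AU at 540 nm).
#' @return A list of class `standard_curve` with `slope` (AU per mg/ml),
#'   `intercept` (AU) and `r_squared`.
#' @export
fit_standard_curve <- function(conc, absorbance = NULL) {
  if (is.data.frame(conc)) {
    absorbance <- conc[[2]]
    conc <- conc[[1]]
  }
  ok <- complete.cases(conc, absorbance)
  conc <- conc[ok]; absorbance <- absorbance[ok]
  if (length(unique(conc)) < 2L)
    stopf("fit error: need >= 2 distinct standard concentrations")
  fit <- lm(absorbance ~ conc)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n = length(conc)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> absorbance = %.6g * conc + %.6g (r2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Convert absorbance to glycerol concentration
#'
#' Inverts the standard curve: `(a - intercept) / slope`. Negative results are
#' clamped to 0 with a warning (they arise from blank-level noise).
#'
#' @param a absorbance values (AU).
#' @param curve a [fit_standard_curve()] result.
#' @return Glycerol concentrations, mg/ml.
#' @export
absorbance_to_glycerol <- function(a, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0)
    stopf("degenerate-curve error: slope is 0, absorbance cannot be inverted")
  g <- (a - curve$intercept) / curve$slope
  below <- sum(g < -sqrt(.Machine$double.eps), na.rm = TRUE)
  if (below > 0)
    warning(sprintf("%d absorbance value(s) below the blank; clamping glycerol to 0",
                    below), call. = FALSE)
  pmax(g, 0)
}

#' Per-position normalization of a multi-plate screen
#'
#' For every well position `(r, c)`, the normalization factor is the
#' arithmetic mean of the glycerol concentration at that position across all
#' plates, computed over compound and DMSO wells only (standards, positive
#' controls and empties are excluded from both the factors and the normalized
#' table). Each eligible well is then divided by its position factor, so a
#' purely positional multiplicative bias cancels exactly.
#'
#' @param plates list of `screen_plate` objects sharing layout geometry.
#' @param curve a [fit_standard_curve()] used to convert absorbance.
#' @return `list(factors = 8 x 12 matrix (NA at excluded positions),
#'   table = data.frame)` with one row per compound/DMSO well: `plate_id,
#'   well, row, col, role, compound_id, raw_glycerol, factor, normalized`.
#' @export
position_normalize <- function(plates, curve) {
  stopifnot(length(plates) >= 1L)
  rows <- lapply(plates, function(pl) {
    lay <- pl$layout
    keep <- lay$role %in% c("compound", "dmso")
    lay <- lay[keep, , drop = FALSE]
    gly <- absorbance_to_glycerol(pl$absorbance[cbind(lay$row, lay$col)], curve)
    data.frame(plate_id = pl$plate_id, well = lay$well, row = lay$row,
               col = lay$col, role = lay$role, compound_id = lay$compound_id,
               raw_glycerol = gly, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  factors <- matrix(NA_real_, 8, 12)
  agg <- stats::aggregate(raw_glycerol ~ row + col, data = tab, FUN = mean)
  factors[cbind(agg$row, agg$col)] <- agg$raw_glycerol
  bad <- which(!is.na(factors) & factors <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("normalization error: non-positive factor at position (%d, %d)",
          bad[1, 1], bad[1, 2])
  tab$factor <- factors[cbind(tab$row, tab$col)]
  tab$normalized <- tab$raw_glycerol / tab$factor
  list(factors = factors, table = tab)
}

#' Call lipolysis-inhibitor hits
#'
#' For every compound well, the fold change versus vehicle is its
#' position-normalized glycerol divided by the mean position-normalized
#' glycerol of the DMSO wells on the same plate. `reduction = 1 - fold`;
#' a compound is a hit when the reduction reaches `hit_threshold`
#' (boundary inclusive: "at least" a 40\% reduction by default).
#' Results are ranked by ascending `log2_fold`, ties broken by compound id.
#'
#' @param table the normalized table from [position_normalize()] (or the list
#'   it returns).
#' @param hit_threshold fractional reduction required for a hit.
#' @return data.frame with one row per compound: `compound_id, plate_id, row,
#'   col, raw_glycerol, position_normalized, fold_vs_dmso, log2_fold,
#'   reduction, is_hit`.
#' @export
call_hits <- function(table, hit_threshold = 0.40) {
  if (is.list(table) && !is.data.frame(table) && !is.null(table$table))
    table <- table$table
  dm <- table[table$role == "dmso", , drop = FALSE]
  comp <- table[table$role == "compound", , drop = FALSE]
  if (nrow(comp) == 0L) stopf("no compound wells in the table")
  dmso_mean <- tapply(dm$normalized, dm$plate_id, mean)
  missing <- setdiff(unique(comp$plate_id), names(dmso_mean))
  if (length(missing))
    stopf("control-missing error: plate(s) without DMSO wells: %s",
          paste(missing, collapse = ", "))
  base <- dmso_mean[as.character(comp$plate_id)]
  fold <- comp$normalized / base
  res <- data.frame(compound_id = comp$compound_id, plate_id = comp$plate_id,
                    row = comp$row, col = comp$col,
                    raw_glycerol = comp$raw_glycerol,
                    position_normalized = comp$normalized,
                    fold_vs_dmso = fold, log2_fold = log2(fold),
                    reduction = 1 - fold,
                    is_hit = (1 - fold) >= hit_threshold,
                    stringsAsFactors = FALSE)
  res[order(res$log2_fold, res$compound_id), , drop = FALSE]
}

#' Plate-control quality report
#'
#' Per plate: DMSO mean and CV (on glycerol concentration), positive-control
#' fold versus DMSO, and flags for plates where stimulation failed
#' (positive-control fold <= 1) or the DMSO CV exceeds `dmso_cv_limit`.
#'
#' @param plates list of `screen_plate` objects with DMSO and positive-control
#'   wells.
#' @param curve a [fit_standard_curve()].
#' @param dmso_cv_limit maximum acceptable DMSO coefficient of variation.
#' @return data.frame with one row per plate: `plate_id, dmso_mean, dmso_cv,
#'   positive_fold, flag_no_stimulation, flag_dmso_cv, flagged`.
#' @export
control_qc <- function(plates, curve, dmso_cv_limit = 0.2) {
  rows <- lapply(plates, function(pl) {
    lay <- pl$layout
    if (!any(lay$role == "dmso") || !any(lay$role == "positive_control"))
      stopf("layout error: control_qc needs dmso and positive_control wells (plate %s)",
            pl$plate_id)
    gly <- function(role) {
      sel <- lay[lay$role == role, , drop = FALSE]
      absorbance_to_glycerol(pl$absorbance[cbind(sel$row, sel$col)], curve)
    }
    dm <- gly("dmso"); pc <- gly("positive_control")
    dmean <- mean(dm)
    dcv <- if (dmean > 0) sd(dm) / dmean else NA_real_
    pfold <- mean(pc) / dmean
    data.frame(plate_id = pl$plate_id, dmso_mean = dmean, dmso_cv = dcv,
               positive_fold = pfold,
               flag_no_stimulation = pfold <= 1,
               flag_dmso_cv = !is.na(dcv) && dcv > dmso_cv_limit)
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$flag_no_stimulation | out$flag_dmso_cv
  out
}

#' Run the full screen analysis
#'
#' Fits the standard curve from the plates' standard wells (pooled across
#' plates), position-normalizes, calls hits and computes control QC.
#'
#' @param plates list of `screen_plate` objects.
#' @param hit_threshold fractional reduction for hit calling.
#' @param dmso_cv_limit QC limit for the DMSO coefficient of variation.
#' @return `list(curve, factors, table, hits, qc)`.
#' @export
analyze_screen <- function(plates, hit_threshold = 0.40, dmso_cv_limit = 0.2) {
  std <- do.call(rbind, lapply(plates, function(pl) {
    lay <- pl$layout[pl$layout$role == "standard", , drop = FALSE]
    if (nrow(lay) == 0L) return(NULL)
    data.frame(conc = lay$standard_conc,
               absorbance = pl$absorbance[cbind(lay$row, lay$col)])
  }))
  if (is.null(std) || nrow(std) == 0L)
    stopf("no standard wells found; cannot fit a standard curve")
  curve <- fit_standard_curve(std$conc, std$absorbance)
  norm <- position_normalize(plates, curve)
  hits <- call_hits(norm$table, hit_threshold)
  qc <- control_qc(plates, curve, dmso_cv_limit)
  list(curve = curve, factors = norm$factors, table = norm$table,
       hits = hits, qc = qc)
}

#' Hit calling from published normalized log2 fold values
#'
#' Applies the reduction threshold to an already-normalized table of per
#' compound log2 fold changes versus vehicle (the form in which screen
#' results are usually published): a compound is a hit when
#' `1 - 2^log2_fold >= hit_threshold`.
#'
#' The boundary is inclusive; a relative tolerance of `sqrt(.Machine$double.eps)`
#' absorbs the float round trip through the log2 representation so a fold of
#' exactly `1 - hit_threshold` is always a hit.
#'
#' @param log2_fold numeric vector of normalized log2 fold changes.
#' @param hit_threshold fractional reduction required for a hit.
#' @return Logical vector of hit flags.
#' @export
screen_hits_from_log2 <- function(log2_fold, hit_threshold = 0.40) {
  (1 - 2^log2_fold) >= hit_threshold - sqrt(.Machine$double.eps)
}

#' Read a compound/log2 table exported from published screen source data
#'
#' Expects a CSV with a compound identifier column and a numeric column of
#' normalized log2 fold values (column names matched case-insensitively
#' against "log2").
#'
#' @param path CSV path.
#' @return data.frame with columns `compound_id`, `log2_fold`.
#' @export
read_screen_log2 <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  lcol <- grep("log2", names(tab), ignore.case = TRUE, value = TRUE)
  if (length(lcol) == 0L) stopf("format error: no log2 column found in %s", path)
  data.frame(compound_id = tab[[1]], log2_fold = as.numeric(tab[[lcol[1]]]),
             stringsAsFactors = FALSE)
}
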