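test_that("standard curve fitting matches hand lines and the normal-equations oracle", {
  c1 <- fit_standard_curve(c(0, 1, 2), c(0, 0.5, 1.0))
  expect_equal(c1$slope, 0.5)
  expect_equal(c1$intercept, 0, tolerance = 1e-12)
  expect_equal(c1$r_squared, 1)
  c2 <- fit_standard_curve(c(0, 1), c(0.1, 0.6))
  expect_equal(c2$slope, 0.5)
  expect_equal(c2$intercept, 0.1)
  withr::local_seed(3)
  x <- runif(20, 0, 1)
  y <- 0.8 * x + 0.05 + rnorm(20, 0, 0.01)
  fit <- fit_standard_curve(x, y)
  o <- oracle_ols(x, y)
  expect_equal(fit$slope, unname(o["slope"]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(o["intercept"]), tolerance = 1e-12)
  expect_error(fit_standard_curve(c(1, 1, 1), c(0.1, 0.2, 0.3)), "fit error")
})

test_that("absorbance inversion and the noiseless simulator round trip exactly", {
  curve <- fit_standard_curve(c(0, 1), c(0.05, 0.85))  # slope 0.8, intercept 0.05
  expect_equal(absorbance_to_glycerol(0.05, curve), 0)
  expect_equal(absorbance_to_glycerol(0.25, fit_standard_curve(c(0, 1), c(0, 0.5))), 0.5)
  expect_warning(absorbance_to_glycerol(0.0, curve), "clamping")
  # full simulator round trip at cv = 0
  s <- generate_screen(screen_sim_params(n_plates = 3, cv = 0, seed = 5))
  an <- analyze_screen(s$plates)
  for (pl in s$plates) {
    lay <- pl$layout
    bio <- lay$role %in% c("compound", "dmso", "positive_control")
    gly <- absorbance_to_glycerol(pl$absorbance[cbind(lay$row, lay$col)][bio], an$curve)
    fold <- ifelse(lay$role[bio] == "positive_control", 3, 1)
    planted <- 0.4 * fold * s$params$position_bias[cbind(lay$row, lay$col)][bio]
    expect_lt(max(abs(gly - planted) / planted), 1e-9)
  }
})

test_that("position normalization removes multiplicative bias exactly at cv = 0", {
  s <- generate_screen(screen_sim_params(n_plates = 16, cv = 0, seed = 7))
  an <- analyze_screen(s$plates)
  expect_lt(max(abs(an$table$normalized - 1)), 1e-9)
  expect_lt(max(abs(an$hits$fold_vs_dmso - 1)), 1e-9)
  # hand-check the factor arithmetic on a two-plate toy
  toy <- s$plates[1:2]
  toy[[1]]$absorbance[2, 2] <- an$curve$intercept + an$curve$slope * 2
  toy[[2]]$absorbance[2, 2] <- an$curve$intercept + an$curve$slope * 4
  nt <- position_normalize(toy, an$curve)
  expect_equal(nt$factors[2, 2], 3)
  v <- nt$table$normalized[nt$table$row == 2 & nt$table$col == 2]
  expect_equal(sort(v), c(2 / 3, 4 / 3))
})

test_that("normalization factors exclude standards and flag bad positions", {
  s <- generate_screen(screen_sim_params(n_plates = 2, cv = 0, seed = 2))
  an <- analyze_screen(s$plates)
  # standard (col 12) and positive-control (col 1 rows 5-8) positions carry no factor
  expect_true(all(is.na(an$factors[1:6, 12])))
  expect_true(all(is.na(an$factors[5:8, 1])))
  expect_true(all(!is.na(an$factors[, 2:11])))
})

test_that("hit threshold is inclusive at exactly 40% reduction", {
  tab <- data.frame(plate_id = 1,
                    well = c("A1", "A2", "A3", "A4"),
                    row = 1, col = 1:4,
                    role = c("dmso", "compound", "compound", "compound"),
                    compound_id = c(NA, "X059", "X060", "X061"),
                    raw_glycerol = c(1, 0.59, 0.60, 0.61),
                    factor = 1,
                    normalized = c(1, 0.59, 0.60, 0.61))
  hits <- call_hits(tab, hit_threshold = 0.40)
  expect_identical(hits$is_hit[match(c("X059", "X060", "X061"), hits$compound_id)],
                   c(TRUE, TRUE, FALSE))
  # internal identities hold row by row
  expect_equal(hits$reduction, 1 - hits$fold_vs_dmso)
  expect_equal(hits$log2_fold, log2(hits$fold_vs_dmso))
  # missing dmso is an error
  expect_error(call_hits(tab[tab$role == "compound", , drop = FALSE]),
               "control-missing")
})

test_that("hit calling is invariant to rescaling every plate by one constant", {
  ids <- planted_inhibitor_ids()
  eff <- stats::setNames(rep(0.5, length(ids)), ids)
  s <- generate_screen(screen_sim_params(cv = 0.02, inhibitor_effects = eff, seed = 1))
  an <- analyze_screen(s$plates)
  # multiply every well's glycerol by 5 (absorbance re-expressed through the
  # same curve), keep the same curve: normalized values and hits are unchanged
  scaled <- lapply(s$plates, function(pl) {
    gly <- (pl$absorbance - an$curve$intercept) / an$curve$slope
    pl$absorbance <- an$curve$slope * (5 * gly) + an$curve$intercept
    pl
  })
  n1 <- position_normalize(s$plates, an$curve)
  n2 <- position_normalize(scaled, an$curve)
  expect_equal(n2$table$normalized, n1$table$normalized, tolerance = 1e-12)
  h1 <- call_hits(n1$table); h2 <- call_hits(n2$table)
  expect_equal(h2$is_hit, h1$is_hit)
  expect_equal(h2$fold_vs_dmso, h1$fold_vs_dmso, tolerance = 1e-12)
})

test_that("planted inhibitors are recovered with no false positives at low noise", {
  ids <- planted_inhibitor_ids()
  eff <- stats::setNames(rep(0.5, length(ids)), ids)
  s <- generate_screen(screen_sim_params(cv = 0.02, inhibitor_effects = eff, seed = 1))
  an <- analyze_screen(s$plates)
  called <- an$hits$compound_id[an$hits$is_hit]
  expect_setequal(called, ids)
  expect_equal(nrow(an$hits), 1280)
  # truth table agrees with what was planted
  expect_equal(sort(s$truth$compound_id[s$truth$reduction > 0]), sort(ids))
})

test_that("control QC reports stimulation folds and flags failures", {
  s3 <- generate_screen(screen_sim_params(n_plates = 4, cv = 0,
                                          stimulated_fold = 3, seed = 4))
  an <- analyze_screen(s3$plates)
  expect_equal(an$qc$positive_fold, rep(3, 4), tolerance = 1e-9)
  expect_false(any(an$qc$flagged))
  s1 <- generate_screen(screen_sim_params(n_plates = 4, cv = 0,
                                          stimulated_fold = 1, seed = 4))
  qc1 <- analyze_screen(s1$plates)$qc
  expect_true(all(qc1$flag_no_stimulation))
  # dmso CV from a cv = 0.1 simulation is ~0.1 over 16 plates
  s10 <- generate_screen(screen_sim_params(n_plates = 16, cv = 0.1, seed = 6))
  qc10 <- analyze_screen(s10$plates)$qc
  expect_lt(abs(mean(qc10$dmso_cv) - 0.1), 0.04)
})

test_that("published-style log2 tables yield inclusive-threshold hit flags", {
  lf <- log2(c(0.59, 0.60, 0.61, 1.0, 1.3))
  expect_identical(screen_hits_from_log2(lf), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "screen_log2.csv")
  write.csv(data.frame(compound = paste0("D", 1:5), log2_value = lf), path,
            row.names = FALSE)
  tab <- read_screen_log2(path)
  expect_equal(sum(screen_hits_from_log2(tab$log2_fold)), 2)
})
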