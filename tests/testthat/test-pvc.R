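test_that("normalized GM fraction follows its defining arithmetic", {
  expect_equal(normalized_gm_fraction(0.5, 0.5), 0.5)
  expect_equal(normalized_gm_fraction(0, 0.8), 0)
  expect_equal(normalized_gm_fraction(0.3, 0.1), 0.75)
  expect_true(is.na(normalized_gm_fraction(0, 0)))
  expect_error(normalized_gm_fraction(-0.1, 0.5), "non-negative")
})

test_that("noiseless linear data is recovered exactly by the regression", {
  fx <- regression_fixture(n = 100, s_gm = 1.0, s_wm = 0.7, noise_sd = 0)
  fit <- fit_pure_tissue(fx$map, fx$fractions)
  expect_equal(fit$s_wm, 0.7, tolerance = 1e-10)
  expect_equal(fit$s_gm, 1.0, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("a constant tissue-normalized map yields zero slope", {
  n <- 60
  shape <- function(v) array(v, c(n, 1L, 1L))
  fg <- shape(seq(0.1, 0.9, length.out = n))
  fw <- shape(1 - seq(0.1, 0.9, length.out = n))
  map <- metabolite_map(shape(0.8 * (fg + fw)), "Glu")
  fit <- fit_pure_tissue(map, list(gm = fg, wm = fw))
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$s_gm, 0.8, tolerance = 1e-12)
  expect_equal(fit$s_wm, 0.8, tolerance = 1e-12)
})

test_that("noisy recovery stays within regression standard errors", {
  # independent oracle: the same OLS done directly with lm on the raw data
  fx <- regression_fixture(n = 500, s_gm = 1.2, s_wm = 0.7,
                           noise_sd = 0.05, seed = 21L)
  fit <- fit_pure_tissue(fx$map, fx$fractions, min_tissue = 0)
  tot <- fx$fractions$gm + fx$fractions$wm
  oracle <- lm(as.vector(fx$map$values / tot) ~ fx$g)
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-10)
  expect_equal(fit$slope, unname(coef(oracle)[2]), tolerance = 1e-10)
  se <- sqrt(diag(vcov(oracle)))
  expect_lt(abs(fit$s_wm - 0.7), 3 * se[1])
  expect_lt(abs(fit$s_gm - 1.2), 3 * sqrt(se[1]^2 + se[2]^2) * 2)
})

test_that("regression refuses degenerate inputs", {
  fx <- regression_fixture(n = 5, noise_sd = 0)
  expect_error(fit_pure_tissue(fx$map, fx$fractions, min_voxels = 10),
               "insufficient")
  n <- 20
  shape <- function(v) array(v, c(n, 1L, 1L))
  same_g <- list(gm = shape(0.5), wm = shape(0.5))
  map <- metabolite_map(shape(runif(n)), "Glu")
  expect_error(fit_pure_tissue(map, same_g), "spread")
})

test_that("redistribution conserves the voxel mean and follows the fractions", {
  est <- list(s_gm = 1.2, s_wm = 0.7)
  cells <- c(5L, 5L, 10L)
  # homogeneous voxel: every cell equals the measured value
  uni <- list(gm = array(0.4, cells), wm = array(0.5, cells))
  expect_equal(redistribute_voxel(0.9, uni, est),
               array(0.9, cells), tolerance = 1e-12)
  # half pure CSF, half pure GM: GM cells get 2x, CSF cells 0
  half <- list(gm = array(0, cells), wm = array(0, cells))
  half$gm[1:125] <- 1
  out <- redistribute_voxel(0.6, half, est)
  expect_equal(unique(out[1:125]), 1.2, tolerance = 1e-12)
  expect_equal(unique(out[126:250]), 0, tolerance = 1e-12)
  expect_equal(mean(out), 0.6, tolerance = 1e-12)
  # random fixtures: conservation to 1e-12 and proportionality to p
  set.seed(8)
  for (rep in 1:20) {
    fg <- array(runif(prod(cells)), cells)
    fw <- array(runif(prod(cells)), cells) * (1 - fg)
    measured <- runif(1, 0.2, 2)
    out <- redistribute_voxel(measured, list(gm = fg, wm = fw), est)
    expect_equal(mean(out), measured, tolerance = 1e-12)
    p <- fg * est$s_gm + fw * est$s_wm
    expect_equal(out, measured * p / mean(p), tolerance = 1e-12)
  }
  # an all-CSF voxel cannot host signal
  csf <- list(gm = array(0, cells), wm = array(0, cells))
  flagged <- redistribute_voxel(0.5, csf, est)
  expect_true(all(is.na(flagged)))
  expect_true(attr(flagged, "flagged"))
})

test_that("T1 correction factor matches the steady-state closed form", {
  t1s <- t1_table(data.frame(
    metabolite = c("Glu", "Glu", "tCr", "tCr"),
    tissue = c("GM", "WM", "GM", "WM"),
    t1_ms = c(1500, 1500, 1000, 1000)))
  seqp <- sequence_params(35, 300)
  # frozen oracle from an independent scalar evaluation of
  # sin(a)(1-E)/(1-cos(a)E) at a = 35 deg, TR = 300 ms
  expect_equal(t1_correction_factor("Glu", "GM", t1s, seqp),
               1.1977108559, tolerance = 1e-9)
  # identical T1s give factor 1
  same <- t1_table(data.frame(metabolite = c("Glu", "tCr"),
                              tissue = "GM", t1_ms = 1400))
  expect_equal(t1_correction_factor("Glu", "GM", same, seqp), 1)
  # full-relaxation limit TR -> infinity
  long_tr <- sequence_params(35, 1e6)
  expect_equal(t1_correction_factor("Glu", "GM", t1s, long_tr), 1,
               tolerance = 1e-6)
  # missing entries are named
  expect_error(t1_correction_factor("GABA", "GM", t1s, seqp), "GABA")
})

test_that("T1 factor is monotone in the metabolite T1", {
  seqp <- sequence_params()
  f <- vapply(seq(800, 2600, by = 300), function(t1) {
    t1s <- t1_table(data.frame(metabolite = c("X", "tCr"), tissue = "GM",
                               t1_ms = c(t1, 1000)))
    t1_correction_factor("X", "GM", t1s, seqp)
  }, 0)
  expect_true(all(diff(f) > 0))
})

test_that("full PVC inverts the noiseless forward model", {
  geom <- small_geom()
  spec <- small_spec(geom, noise_sd = 0)
  study <- simulate_study(spec, geom)
  met <- "Glu"
  pvc <- run_pvc(study$native[[met]], study$fractions_adj, mask = NULL,
                 geometry = geom, t1s = NULL)
  fit <- attr(pvc, "provenance")$fit
  truth_vals <- spec$pure_values[[met]]
  expect_equal(fit$s_gm, unname(truth_vals["gm"]), tolerance = 1e-6)
  expect_equal(fit$s_wm, unname(truth_vals["wm"]), tolerance = 1e-6)
  # corrected map equals the acquisition-domain truth wherever tissue
  # occupies at least half the cell
  adj <- study$fractions_adj
  sel <- (adj$gm + adj$wm) >= 0.5
  diff <- abs(pvc$values - study$truth_adj[[met]]$values)
  expect_lt(max(diff[sel], na.rm = TRUE), 1e-6)
})

test_that("PVC shifts a deep-GM nucleus ROI toward the pure-GM truth", {
  geom <- small_geom()
  spec <- small_spec(geom, noise_sd = 0)
  study <- simulate_study(spec, geom)
  met <- "Glu"
  s_gm <- spec$pure_values[[met]]["gm"]
  uncorrected <- regrid_nearest(study$native[[met]], geom$anat_res_mm)
  corrected <- run_pvc(study$native[[met]], study$fractions_adj,
                       geometry = geom, t1s = NULL)
  # ROI: all anatomical cells whose center lies inside the nucleus
  nuc <- spec$structures[[5]]
  d <- spec$dims
  x <- (seq_len(d[1]) - 0.5); y <- (seq_len(d[2]) - 0.5); z <- (seq_len(d[3]) - 0.5)
  roi <- outer(outer(((x - nuc$center[1]) / nuc$radii[1])^2,
                     ((y - nuc$center[2]) / nuc$radii[2])^2, `+`),
               ((z - nuc$center[3]) / nuc$radii[3])^2, `+`) <= 1
  expect_gt(sum(roi), 100)
  mu_unc <- mean(uncorrected$values[roi], na.rm = TRUE)
  mu_cor <- mean(corrected$values[roi], na.rm = TRUE)
  # partial-volume dilution pulls the uncorrected ROI below the GM truth;
  # the corrected ROI mean lies strictly closer to it
  expect_lt(mu_unc, s_gm)
  expect_lt(abs(mu_cor - s_gm), abs(mu_unc - s_gm))
})

test_that("all-missing input yields an all-missing corrected map", {
  geom <- small_geom()
  d <- anat_slab_dims(geom)
  nd <- c(geom$acq_matrix, geom$n_slices)
  fr <- tissue_fractions(array(0.5, d), array(0.5, d), array(0, d),
                         adjusted = TRUE)
  empty <- metabolite_map(array(NA_real_, nd), "Glu")
  out <- run_pvc(empty, fr, geometry = geom, t1s = NULL)
  expect_true(all(is.na(out$values)))
})

test_that("pure-tissue recovery is accurate across the parameter plane", {
  # median |error| of s_gm, s_wm over seeded replicates at sigma = 0.05
  set.seed(123)
  grid <- expand.grid(s_gm = c(0.5, 1.0, 1.5), s_wm = c(0.5, 1.0, 1.5))
  for (i in seq_len(nrow(grid))) {
    errs <- vapply(1:10, function(r) {
      fx <- regression_fixture(n = 400, s_gm = grid$s_gm[i],
                               s_wm = grid$s_wm[i], noise_sd = 0.05,
                               seed = 1000L * i + r)
      fit <- fit_pure_tissue(fx$map, fx$fractions, min_tissue = 0.5)
      max(abs(fit$s_gm - grid$s_gm[i]) / grid$s_gm[i],
          abs(fit$s_wm - grid$s_wm[i]) / grid$s_wm[i])
    }, 0)
    expect_lt(median(errs), 0.05)
  }
})

test_that("regression standard errors grow with the noise level", {
  ses <- vapply(c(0.01, 0.05, 0.1, 0.2), function(sd) {
    fx <- regression_fixture(n = 400, noise_sd = sd, seed = 5L)
    fit_pure_tissue(fx$map, fx$fractions, min_tissue = 0)$se_slope
  }, 0)
  expect_true(all(diff(ses) > 0))
})
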