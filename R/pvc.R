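#' Normalized gray-matter fraction
#'
#' The regression covariate of the pure-tissue model: GM fraction divided by
#' the sum of the GM and WM fractions. Vectorized; cells with no GM or WM
#' tissue return `NA` (they are excluded from the regression).
#'
#' @param f_gm,f_wm Numeric GM and WM fractions, >= 0.
#' @return Numeric in \[0, 1\], `NA` where `f_gm + f_wm == 0`.
#' @export
normalized_gm_fraction <- function(f_gm, f_wm) {
  if (any(f_gm < 0, na.rm = TRUE) || any(f_wm < 0, na.rm = TRUE))
    stop("tissue fractions must be non-negative")
  tot <- f_gm + f_wm
  out <- f_gm / tot
  out[tot == 0] <- NA_real_
  out
}

#' Sequence parameters for steady-state T1 correction
#'
#' @param flip_angle_deg Excitation flip angle in degrees (0, 90\].
#' @param tr_ms Repetition time in ms, > 0.
#' @return An object of class `sequence_params`.
#' @export
sequence_params <- function(flip_angle_deg = 35, tr_ms = 300) {
  if (flip_angle_deg <= 0 || flip_angle_deg > 90)
    stop("flip angle must be in (0, 90] degrees")
  if (tr_ms <= 0) stop("TR must be positive")
  structure(list(flip_angle_deg = flip_angle_deg, tr_ms = tr_ms),
            class = "sequence_params")
}

#' Metabolite/tissue T1 table
#'
#' Longitudinal relaxation times per metabolite and tissue used for the
#' steady-state saturation correction. The package ships editable
#' representative 7 T defaults (ms); studies should substitute values
#' matched to their field strength and literature of choice.
#'
#' @param entries A data frame with columns `metabolite`, `tissue`
#'   (`"GM"`/`"WM"`) and `t1_ms`, or `NULL` for the defaults.
#' @param source Label recording where the values come from.
#' @return An object of class `t1_table` (a data frame).
#' @export
t1_table <- function(entries = NULL, source = "representative-7T-defaults") {
  if (is.null(entries)) {
    entries <- data.frame(
      metabolite = rep(c("tNAA", "tCr", "tCho", "Glu", "Glx", "mI_Gly", "GSH"),
                       each = 2),
      tissue = rep(c("GM", "WM"), 7),
      t1_ms = c(1730, 1630,   # tNAA
                1550, 1450,   # tCr
                1300, 1200,   # tCho
                1220, 1160,   # Glu
                1220, 1160,   # Glx
                1100, 1050,   # mI + Gly
                950,  900)    # GSH
    )
  }
  stopifnot(all(c("metabolite", "tissue", "t1_ms") %in% names(entries)))
  if (any(entries$t1_ms <= 0)) stop("all T1 entries must be positive")
  structure(entries, class = c("t1_table", "data.frame"),
            source = source)
}

# Steady-state saturation factor of a spoiled acquisition at flip angle a,
# repetition time TR and longitudinal relaxation time T1:
# E(T1) = sin(a) (1 - exp(-TR/T1)) / (1 - cos(a) exp(-TR/T1)).
ernst_saturation <- function(t1_ms, flip_angle_deg, tr_ms) {
  a <- flip_angle_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

lookup_t1 <- function(t1s, metabolite, tissue) {
  hit <- t1s$metabolite == metabolite & t1s$tissue == tissue
  if (!any(hit))
    stop(sprintf("missing T1 entry for %s in %s", metabolite, tissue))
  t1s$t1_ms[which(hit)[1]]
}

#' Steady-state T1 correction factor for a ratio map
#'
#' Metabolite maps are ratios over total creatine, so differential T1
#' saturation between the metabolite and the tCr reference biases the
#' ratio. The multiplicative correction is `E(T1_tCr) / E(T1_met)` evaluated
#' with the tissue-specific T1 of both compounds, where `E` is the
#' steady-state saturation factor at the sequence's flip angle and TR.
#'
#' @param metabolite Metabolite name.
#' @param tissue `"GM"` or `"WM"`.
#' @param t1s A [t1_table()].
#' @param seq_params A [sequence_params()].
#' @return Unitless multiplier applied to the ratio map.
#' @export
t1_correction_factor <- function(metabolite, tissue, t1s = t1_table(),
                                 seq_params = sequence_params()) {
  t1_met <- lookup_t1(t1s, metabolite, tissue)
  t1_ref <- lookup_t1(t1s, "tCr", tissue)
  ernst_saturation(t1_ref, seq_params$flip_angle_deg, seq_params$tr_ms) /
    ernst_saturation(t1_met, seq_params$flip_angle_deg, seq_params$tr_ms)
}

#' Estimate pure-tissue metabolite levels by regression
#'
#' Ordinary least-squares fit of the tissue-normalized metabolite value
#' `y = M / (f_gm + f_wm)` against the normalized GM fraction
#' `g = f_gm / (f_gm + f_wm)` over voxels that survive QA filtering and
#' contain at least `min_tissue` GM+WM. Extrapolation to `g = 1` gives the
#' pure-GM level and to `g = 0` the pure-WM level. Fractions must be
#' PSF-adjusted and aggregated to the native grid of the map, so that the
#' covariate sees the same voxel bleeding as the data.
#'
#' @param map A [metabolite_map()] on the native grid (QA-filtered voxels
#'   `NA`, or supply `mask`).
#' @param fractions_native List with `gm`, `wm` arrays on the native grid
#'   (from [aggregate_fractions_to_native()]).
#' @param mask Optional [qa_mask()]; applied before fitting.
#' @param min_tissue Minimum GM+WM fraction for a voxel to enter the
#'   regression (default 0.5, excluding CSF-dominated voxels).
#' @param min_voxels Minimum number of usable voxels (default 10).
#' @return An object of class `pure_tissue_fit`: `s_gm`, `s_wm`, `slope`,
#'   `intercept`, `n_voxels`, `r2`, and coefficient standard errors
#'   `se_slope`, `se_intercept`.
#' @export
fit_pure_tissue <- function(map, fractions_native, mask = NULL,
                            min_tissue = 0.5, min_voxels = 10) {
  stopifnot(inherits(map, "metabolite_map"))
  v <- map$values
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "qa_mask"))
    v[!mask$keep] <- NA_real_
  }
  fg <- fractions_native$gm
  fw <- fractions_native$wm
  if (!identical(dim(fg), dim(v)))
    stop("fraction grid does not match the map's native grid")
  tot <- fg + fw
  use <- !is.na(v) & tot >= min_tissue & tot > 0
  if (sum(use) < min_voxels)
    stop(sprintf("insufficient data: %d voxels after exclusions (need >= %d)",
                 sum(use), min_voxels))
  g <- fg[use] / tot[use]
  y <- v[use] / tot[use]
  if (length(unique(g)) < 2L)
    stop("insufficient data: normalized GM fraction has no spread")
  fit <- stats::lm(y ~ g)
  co <- stats::coef(fit)
  # coefficient SEs and R^2 computed directly (robust to perfect fits)
  n <- length(y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  sigma2 <- ss_res / (n - 2)
  x_mat <- cbind(1, g)
  se <- sqrt(pmax(diag(sigma2 * solve(crossprod(x_mat))), 0))
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  s_wm <- unname(co[1])
  s_gm <- unname(co[1] + co[2])
  if (s_wm < 0 || s_gm < 0)
    warning("negative extrapolated pure-tissue value; retained unclipped")
  structure(
    list(s_gm = s_gm, s_wm = s_wm,
         slope = unname(co[2]), intercept = unname(co[1]),
         n_voxels = sum(use), r2 = r2,
         se_intercept = unname(se[1]), se_slope = unname(se[2]),
         min_tissue = min_tissue),
    class = "pure_tissue_fit"
  )
}

#' @export
print.pure_tissue_fit <- function(x, ...) {
  cat(sprintf("pure-tissue fit: s_GM = %.4f, s_WM = %.4f (n = %d, R^2 = %.3f)\n",
              x$s_gm, x$s_wm, x$n_voxels, x$r2))
  invisible(x)
}

#' Redistribute one voxel's signal over its anatomical cells
#'
#' Given the measured voxel value and the PSF-adjusted tissue fractions of
#' the anatomical cells it contains, predicts the relative signal of each
#' cell as `p = f_gm * s_gm + f_wm * s_wm` (CSF contributes nothing) and
#' rescales so the mean over the voxel's cells equals the measured value
#' exactly: the redistribution moves signal within the voxel but never
#' changes its average.
#'
#' @param measured Measured voxel value (ratio over tCr).
#' @param cell_fractions List with `gm`, `wm` numeric arrays covering
#'   exactly the voxel's anatomical cells.
#' @param est A [fit_pure_tissue()] result (or any list with `s_gm`, `s_wm`).
#' @return Numeric array of per-cell values with the same shape; all `NA`
#'   (with attribute `flagged = TRUE`) if the voxel holds no GM/WM signal.
#' @export
redistribute_voxel <- function(measured, cell_fractions, est) {
  p <- cell_fractions$gm * est$s_gm + cell_fractions$wm * est$s_wm
  mp <- mean(p)
  if (!is.finite(mp) || mp <= 0) {
    out <- p
    out[] <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  measured * p / mp
}

#' Run the full partial-volume and T1 correction for one metabolite
#'
#' Pipeline composition: fit pure-tissue levels from the QA-filtered native
#' map against PSF-adjusted fractions aggregated to the native grid;
#' redistribute each native voxel's signal over its anatomical cells in
#' proportion to the locally predicted pure-tissue signal; then apply the
#' steady-state T1 correction per cell, mixing the GM and WM factors by the
#' local tissue fractions.
#'
#' @param map A [metabolite_map()] on the native grid.
#' @param fractions PSF-adjusted [tissue_fractions()] at anatomical
#'   resolution.
#' @param mask Optional [qa_mask()].
#' @param geometry An [acq_geometry()].
#' @param t1s A [t1_table()], or `NULL` to skip T1 correction.
#' @param seq_params A [sequence_params()].
#' @param min_tissue Regression tissue-fraction floor (see
#'   [fit_pure_tissue()]).
#' @param min_voxels Minimum regression voxel count.
#' @return A corrected [metabolite_map()] at anatomical resolution with
#'   attribute `provenance` (fit, voxel counts, settings).
#' @export
run_pvc <- function(map, fractions, mask = NULL, geometry = acq_geometry(),
                    t1s = t1_table(), seq_params = sequence_params(),
                    min_tissue = 0.5, min_voxels = 10) {
  stopifnot(inherits(map, "metabolite_map"), inherits(fractions, "tissue_fractions"))
  if (!fractions$adjusted)
    warning("fractions are not PSF-adjusted; partial-volume model assumes they are")
  if (!is.null(mask)) map <- apply_mask(map, mask)
  if (all(is.na(map$values))) {
    out <- metabolite_map(array(NA_real_, dim(fractions$gm)), map$metabolite,
                          spacing_mm = rep(fractions$spacing_mm, 3),
                          grid_name = "anat")
    attr(out, "provenance") <- list(fit = NULL, n_input = 0L, n_output = 0L)
    return(out)
  }
  frac_native <- aggregate_fractions_to_native(fractions, geometry)
  est <- fit_pure_tissue(map, frac_native, mask = NULL,
                         min_tissue = min_tissue, min_voxels = min_voxels)
  block <- as.integer(round(geometry$voxel_size_mm / fractions$spacing_mm))
  # predicted relative signal per anatomical cell and its per-voxel mean
  p <- fractions$gm * est$s_gm + fractions$wm * est$s_wm
  p_mean <- block_expand(block_mean(p, block), block)
  measured <- block_expand(map$values, block)
  corrected <- measured * p / p_mean
  corrected[p_mean <= 0] <- NA_real_
  if (!is.null(t1s)) {
    fac_gm <- t1_correction_factor(map$metabolite, "GM", t1s, seq_params)
    fac_wm <- t1_correction_factor(map$metabolite, "WM", t1s, seq_params)
    tot <- fractions$gm + fractions$wm
    fac <- (fractions$gm * fac_gm + fractions$wm * fac_wm) / tot
    fac[tot == 0] <- NA_real_
    corrected <- corrected * fac
  }
  out <- metabolite_map(corrected, map$metabolite,
                        spacing_mm = rep(fractions$spacing_mm, 3),
                        grid_name = "anat")
  attr(out, "provenance") <- list(
    fit = est,
    n_input = sum(!is.na(map$values)),
    n_output = sum(!is.na(corrected)),
    settings = list(min_tissue = min_tissue, min_voxels = min_voxels,
                    t1_corrected = !is.null(t1s),
                    flip_angle_deg = seq_params$flip_angle_deg,
                    tr_ms = seq_params$tr_ms)
  )
  out
}
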