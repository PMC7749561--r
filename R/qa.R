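#' Per-voxel quality-assurance metrics
#'
#' Bundles the fitting-stage QA outputs on the native MRSI grid: SNR,
#' linewidth (FWHM in ppm), per-metabolite Cramer-Rao lower bounds (%SD)
#' and the lipid-to-total-creatine amplitude ratio.
#'
#' @param snr Numeric 3D array, unitless, >= 0.
#' @param fwhm_ppm Numeric 3D array, ppm, >= 0.
#' @param crlb Named list of numeric 3D arrays (%SD), one per metabolite;
#'   must include the `"tCr"` reference for filter propagation.
#' @param lip_over_tcr Numeric 3D array, unitless.
#' @param spacing_mm Native voxel size in mm.
#' @return An object of class `qa_bundle`.
#' @export
qa_bundle <- function(snr, fwhm_ppm, crlb, lip_over_tcr,
                      spacing_mm = c(5, 5, 10)) {
  stopifnot(is.list(crlb), !is.null(names(crlb)))
  d <- dim(snr)
  for (f in c(list(fwhm_ppm, lip_over_tcr), crlb))
    if (!identical(dim(f), d)) stop("all QA fields must share one grid")
  if (min(snr, na.rm = TRUE) < 0 || min(fwhm_ppm, na.rm = TRUE) < 0)
    stop("SNR and FWHM must be non-negative")
  if (min(vapply(crlb, min, 0, na.rm = TRUE)) < 0)
    stop("CRLB values must be non-negative")
  structure(
    list(snr = snr, fwhm_ppm = fwhm_ppm, crlb = crlb,
         lip_over_tcr = lip_over_tcr, spacing_mm = as.numeric(spacing_mm)),
    class = "qa_bundle"
  )
}

#' Quality-assurance thresholds
#'
#' Keep criteria are strict inequalities: a voxel is retained only if
#' SNR > `snr_min`, FWHM < `fwhm_max` ppm, Lip13ab/tCr < `lip_tcr_max` and
#' CRLB < `crlb_max` %SD; boundary values are discarded.
#'
#' @param snr_min Minimum SNR (default 3).
#' @param fwhm_max Maximum linewidth in ppm (default 0.15).
#' @param lip_tcr_max Maximum lipid-to-tCr ratio (default 2).
#' @param crlb_max Maximum CRLB in %SD (default 50).
#' @return An object of class `qa_thresholds`.
#' @export
qa_thresholds <- function(snr_min = 3, fwhm_max = 0.15,
                          lip_tcr_max = 2, crlb_max = 50) {
  vals <- c(snr_min = snr_min, fwhm_max = fwhm_max,
            lip_tcr_max = lip_tcr_max, crlb_max = crlb_max)
  if (any(vals <= 0)) stop("all QA thresholds must be strictly positive")
  structure(as.list(vals), class = "qa_thresholds")
}

#' Build a binary quality mask for one metabolite
#'
#' A voxel is kept iff all four criteria pass (strict inequalities). The
#' returned mask records, per criterion, which voxels it removed.
#'
#' @param qa A [qa_bundle()].
#' @param thresholds A [qa_thresholds()].
#' @param metabolite Name of the metabolite whose CRLB field applies.
#' @return An object of class `qa_mask`: list with `keep` (logical array),
#'   `failed` (named list of logical arrays, one per criterion) and
#'   `metabolite`.
#' @export
build_qa_mask <- function(qa, thresholds = qa_thresholds(), metabolite) {
  stopifnot(inherits(qa, "qa_bundle"), inherits(thresholds, "qa_thresholds"))
  if (!metabolite %in% names(qa$crlb))
    stop(sprintf("unknown metabolite '%s': no CRLB field", metabolite))
  failed <- list(
    snr = !(qa$snr > thresholds$snr_min),
    fwhm = !(qa$fwhm_ppm < thresholds$fwhm_max),
    lipid = !(qa$lip_over_tcr < thresholds$lip_tcr_max),
    crlb = !(qa$crlb[[metabolite]] < thresholds$crlb_max)
  )
  keep <- !(failed$snr | failed$fwhm | failed$lipid | failed$crlb)
  structure(list(keep = keep, failed = failed, metabolite = metabolite),
            class = "qa_mask")
}

#' Which criteria removed each discarded voxel
#'
#' @param mask A [qa_mask()].
#' @return Character array: comma-joined failing criteria per voxel, `""`
#'   where the voxel is kept.
#' @export
mask_provenance <- function(mask) {
  stopifnot(inherits(mask, "qa_mask"))
  out <- array("", dim = dim(mask$keep))
  for (crit in names(mask$failed)) {
    f <- mask$failed[[crit]]
    out[f] <- ifelse(out[f] == "", crit, paste(out[f], crit, sep = ","))
  }
  out
}

#' Propagate the tCr reference filter to all metabolite masks
#'
#' Because metabolite maps are expressed as ratios over total creatine,
#' voxels whose tCr CRLB exceeds the threshold are removed from every
#' metabolite mask, regardless of that metabolite's own CRLB. Idempotent.
#'
#' @param masks Named list of [qa_mask()] objects, one per metabolite.
#' @param qa The [qa_bundle()]; must contain a `"tCr"` CRLB field.
#' @param thresholds A [qa_thresholds()].
#' @return The list of masks with the tCr criterion intersected in.
#' @export
propagate_tcr_filter <- function(masks, qa, thresholds = qa_thresholds()) {
  stopifnot(inherits(qa, "qa_bundle"))
  if (!"tCr" %in% names(qa$crlb))
    stop("missing reference: QA bundle has no tCr CRLB field")
  tcr_fail <- qa$crlb[["tCr"]] > thresholds$crlb_max
  lapply(masks, function(m) {
    stopifnot(inherits(m, "qa_mask"))
    m$failed$tcr_crlb <- tcr_fail
    m$keep <- m$keep & !tcr_fail
    m
  })
}

#' Apply a quality mask to a metabolite map
#'
#' Discarded voxels are set to the missing-value marker (`NA`); kept voxels
#' are unchanged.
#'
#' @param map A [metabolite_map()] on the native grid.
#' @param mask A [qa_mask()] on the same grid.
#' @return A [metabolite_map()].
#' @export
apply_mask <- function(map, mask) {
  stopifnot(inherits(map, "metabolite_map"), inherits(mask, "qa_mask"))
  if (!identical(dim(map$values), dim(mask$keep)))
    stop("shape error: map and mask grids differ")
  v <- map$values
  v[!mask$keep] <- NA_real_
  out <- map
  out$values <- v
  out
}
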