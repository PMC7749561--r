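#' Tissue fractional-volume maps
#'
#' GM/WM/CSF fractional volumes on the anatomical grid of the MRSI slab,
#' either as raw segmentations or after convolution with the acquisition
#' PSF ("adjusted").
#'
#' @param gm,wm,csf Numeric 3D arrays in \[0, 1\] on the anatomical grid.
#' @param spacing_mm Isotropic cell size in mm.
#' @param adjusted Logical: have the fields been convolved with the PSF?
#' @return An object of class `tissue_fractions`.
#' @export
tissue_fractions <- function(gm, wm, csf, spacing_mm = 1, adjusted = FALSE) {
  stopifnot(identical(dim(gm), dim(wm)), identical(dim(gm), dim(csf)),
            length(dim(gm)) == 3L)
  rng <- range(gm, wm, csf)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-6)
    stop("tissue fractions must lie in [0, 1]")
  if (max(gm + wm + csf) > 1 + 1e-6)
    stop("tissue fractions must sum to at most 1")
  structure(
    list(gm = gm, wm = wm, csf = csf,
         spacing_mm = as.numeric(spacing_mm), adjusted = isTRUE(adjusted)),
    class = "tissue_fractions"
  )
}

#' @export
print.tissue_fractions <- function(x, ...) {
  d <- dim(x$gm)
  cat(sprintf("tissue fractions %d x %d x %d at %g mm (%s)\n",
              d[1], d[2], d[3], x$spacing_mm,
              if (x$adjusted) "PSF-adjusted" else "raw segmentation"))
  invisible(x)
}

# Symmetric (edge-inclusive) reflective padding of a matrix.
pad_reflect <- function(m, kh) {
  d <- dim(m)
  ix <- c(rev(seq_len(min(kh[1], d[1]))), seq_len(d[1]),
          d[1] + 1 - rev(seq_len(min(kh[1], d[1]))))
  iy <- c(rev(seq_len(min(kh[2], d[2]))), seq_len(d[2]),
          d[2] + 1 - rev(seq_len(min(kh[2], d[2]))))
  m[ix, iy, drop = FALSE]
}

# Crop a kernel to the symmetric odd-sized bounding box of its significant
# support (relative threshold on the peak); keeps unit sum by renormalizing.
crop_kernel <- function(kernel, rel_tol = 1e-12) {
  pk <- which(kernel == max(kernel), arr.ind = TRUE)[1, ]
  keep <- which(kernel > rel_tol * max(kernel), arr.ind = TRUE)
  hx <- max(abs(keep[, 1] - pk[1]))
  hy <- max(abs(keep[, 2] - pk[2]))
  hx <- min(hx, pk[1] - 1L, nrow(kernel) - pk[1])
  hy <- min(hy, pk[2] - 1L, ncol(kernel) - pk[2])
  k <- kernel[(pk[1] - hx):(pk[1] + hx), (pk[2] - hy):(pk[2] + hy), drop = FALSE]
  k / sum(k)
}

# 2D "same"-size convolution with reflective boundary via FFT. The kernel
# must have odd dimensions with its center at the middle element.
conv2_reflect <- function(img, kernel) {
  d <- dim(img)
  kd <- dim(kernel)
  kh <- (kd - 1L) %/% 2L
  if (any(kh > d)) {
    # truncate an over-wide kernel to the largest support the image can
    # reflect; renormalize to keep unit sum
    hx <- min(kh[1], d[1]); hy <- min(kh[2], d[2])
    kernel <- kernel[(kh[1] + 1 - hx):(kh[1] + 1 + hx),
                     (kh[2] + 1 - hy):(kh[2] + 1 + hy), drop = FALSE]
    kernel <- kernel / sum(kernel)
    kd <- dim(kernel)
    kh <- (kd - 1L) %/% 2L
  }
  kh_eff <- kh
  padded <- pad_reflect(img, kh_eff)
  pd <- dim(padded)
  kmat <- matrix(0, pd[1], pd[2])
  # place kernel center at (1,1) with circular wrap
  ii <- ((seq_len(kd[1]) - 1L - kh[1]) %% pd[1]) + 1L
  jj <- ((seq_len(kd[2]) - 1L - kh[2]) %% pd[2]) + 1L
  kmat[ii, jj] <- kmat[ii, jj] + kernel
  out <- Re(stats::fft(stats::fft(padded) * stats::fft(kmat), inverse = TRUE)) /
    prod(pd)
  out[(kh_eff[1] + 1):(kh_eff[1] + d[1]), (kh_eff[2] + 1):(kh_eff[2] + d[2]),
      drop = FALSE]
}

#' Convolve tissue segmentations with the acquisition PSF
#'
#' Convolves each tissue fraction field in-plane (per 1 mm sub-slice) with
#' the PSF kernel to mimic the voxel-bleeding of the MRSI acquisition.
#' Reflective boundary handling avoids artificial tissue loss at slab
#' edges. The through-slice response is treated as an ideal boxcar, so no
#' convolution is applied along the slice axis.
#'
#' @param fractions Raw [tissue_fractions()].
#' @param psf A [build_psf()] kernel at the same resolution.
#' @param support_tol Relative support threshold used to crop the kernel
#'   before convolution.
#' @return PSF-adjusted [tissue_fractions()].
#' @export
convolve_fractions <- function(fractions, psf, support_tol = 1e-12) {
  stopifnot(inherits(fractions, "tissue_fractions"), inherits(psf, "psf"))
  if (fractions$adjusted)
    stop("double adjustment: fractions are already PSF-convolved")
  if (abs(fractions$spacing_mm - psf$anat_res_mm) > 1e-9)
    stop("fraction grid and PSF resolution differ")
  kernel <- crop_kernel(psf$kernel, support_tol)
  conv_field <- function(f) {
    out <- f
    for (z in seq_len(dim(f)[3])) out[, , z] <- conv2_reflect(f[, , z], kernel)
    # clip tiny numerical overshoot only
    small_neg <- out < 0 & out > -1e-6
    small_over <- out > 1 & out < 1 + 1e-6
    out[small_neg] <- 0
    out[small_over] <- 1
    out
  }
  tissue_fractions(conv_field(fractions$gm), conv_field(fractions$wm),
                   conv_field(fractions$csf),
                   spacing_mm = fractions$spacing_mm, adjusted = TRUE)
}

#' Aggregate anatomical-resolution fractions onto the native MRSI grid
#'
#' Mean-pools each tissue field over the block of anatomical cells making up
#' one native voxel (250 cells for 5 x 5 x 10 mm at 1 mm).
#'
#' @param fractions A [tissue_fractions()] at anatomical resolution.
#' @param geometry An [acq_geometry()].
#' @return A list with `gm`, `wm`, `csf` arrays on the native grid.
#' @export
aggregate_fractions_to_native <- function(fractions, geometry) {
  stopifnot(inherits(fractions, "tissue_fractions"),
            inherits(geometry, "acq_geometry"))
  block <- as.integer(round(geometry$voxel_size_mm / fractions$spacing_mm))
  list(gm = block_mean(fractions$gm, block),
       wm = block_mean(fractions$wm, block),
       csf = block_mean(fractions$csf, block))
}
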