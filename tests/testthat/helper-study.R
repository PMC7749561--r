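# Shared small-scale fixtures, built in code.

# A desk-scale geometry: 22 x 22 native grid over a 110 mm FOV, one 10 mm
# slice; anatomical slab 110 x 110 x 10 at 1 mm.
small_geom <- function(n_slices = 1L) {
  acq_geometry(fov_mm = c(110, 110), acq_matrix = c(22L, 22L),
               voxel_size_mm = c(5, 5, 10), n_slices = n_slices)
}

small_spec <- function(geometry = small_geom(), noise_sd = 0, seed = 1L,
                       qa_defects = default_qa_defects()) {
  phantom_spec(dims = anat_slab_dims(geometry),
               spacing_mm = geometry$anat_res_mm,
               noise_sd = noise_sd, seed = seed, qa_defects = qa_defects)
}

# Random QA bundle on a given native grid, seeded; metric ranges straddle
# the default thresholds so all four criteria are exercised.
random_qa_bundle <- function(nd = c(10L, 10L, 2L), mets = c("Glu", "tCr"),
                             seed = 42L) {
  set.seed(seed)
  n <- prod(nd)
  crlb <- lapply(mets, function(m) array(runif(n, 0, 100), nd))
  names(crlb) <- mets
  qa_bundle(
    snr = array(runif(n, 0, 10), nd),
    fwhm_ppm = array(runif(n, 0, 0.3), nd),
    crlb = crlb,
    lip_over_tcr = array(runif(n, 0, 4), nd),
    spacing_mm = c(5, 5, 10)
  )
}

# Native-level regression fixture: n voxels with known pure-tissue values,
# returned as map + native fraction list shaped (n, 1, 1).
regression_fixture <- function(n = 500, s_gm = 1.2, s_wm = 0.7,
                               noise_sd = 0.05, seed = 1L,
                               metabolite = "Glu") {
  set.seed(seed)
  fg <- runif(n, 0.05, 0.95)
  fw <- runif(n, 0.05, 0.95)
  tot <- fg + fw
  scale <- pmin(1 / tot, 1)      # keep fractions physical
  fg <- fg * scale; fw <- fw * scale
  tot <- fg + fw
  g <- fg / tot
  y_true <- s_wm + (s_gm - s_wm) * g
  m <- (y_true + rnorm(n, 0, noise_sd)) * tot
  shape <- function(v) array(v, c(n, 1L, 1L))
  list(
    map = metabolite_map(pmax(shape(m), 0), metabolite,
                         spacing_mm = c(5, 5, 10)),
    fractions = list(gm = shape(fg), wm = shape(fw)),
    g = g, s_gm = s_gm, s_wm = s_wm
  )
}
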