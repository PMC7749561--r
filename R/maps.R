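#' Per-metabolite value map on a named grid
#'
#' Container for a metabolite ratio map (values relative to total creatine)
#' on either the native MRSI grid or the 1 mm anatomical grid. Filtered or
#' absent voxels carry `NA`.
#'
#' @param values Numeric 3D array (x, y, slice).
#' @param metabolite Metabolite name, e.g. `"Glu"`.
#' @param spacing_mm Cell size in mm, length-3 numeric.
#' @param grid_name Descriptive grid label (`"native"` or `"anat"`).
#' @return An object of class `metabolite_map`.
#' @export
metabolite_map <- function(values, metabolite,
                           spacing_mm = c(5, 5, 10),
                           grid_name = "native") {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 3L, length(spacing_mm) == 3L)
  if (any(values < -1e-9, na.rm = TRUE))
    warning("metabolite map contains negative values")
  structure(
    list(values = values, metabolite = as.character(metabolite),
         spacing_mm = as.numeric(spacing_mm), grid_name = grid_name),
    class = "metabolite_map"
  )
}

#' @export
print.metabolite_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("%s map on %s grid %d x %d x %d (%g x %g x %g mm), %d of %d voxels present\n",
              x$metabolite, x$grid_name, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              sum(!is.na(x$values)), length(x$values)))
  invisible(x)
}

#' Up-sample a native map by cell replication
#'
#' Replicates each native in-plane cell into `factor x factor` cells, so a
#' single MRSI voxel becomes `factor^2` voxels (16 for the default factor of
#' 4). Values are unchanged and mean-pooling by the same factor recovers the
#' input exactly.
#'
#' @param map_native A [metabolite_map()] on the native grid.
#' @param factor Integer in-plane replication factor, >= 1.
#' @return A [metabolite_map()] with `factor^2` times as many in-plane cells.
#' @export
upsample_native_grid <- function(map_native, factor) {
  stopifnot(inherits(map_native, "metabolite_map"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(map_native)
  v <- map_native$values
  d <- dim(v)
  out <- v[rep(seq_len(d[1]), each = factor),
           rep(seq_len(d[2]), each = factor), , drop = FALSE]
  metabolite_map(out, map_native$metabolite,
                 spacing_mm = map_native$spacing_mm / c(factor, factor, 1),
                 grid_name = map_native$grid_name)
}

# Mean-pool a 3D array over non-overlapping blocks; inverse of replication.
block_mean <- function(a, block) {
  d <- dim(a)
  stopifnot(length(d) == 3L, all(d %% block == 0))
  dn <- d %/% block
  dim(a) <- c(block[1], dn[1], block[2], dn[2], block[3], dn[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(prod(block), prod(dn))
  out <- colMeans(a)
  dim(out) <- dn
  out
}

# Replicate a (native-sized) 3D array onto the fine grid by block expansion.
block_expand <- function(a, block) {
  d <- dim(a)
  a[rep(seq_len(d[1]), each = block[1]),
    rep(seq_len(d[2]), each = block[2]),
    rep(seq_len(d[3]), each = block[3]), drop = FALSE]
}

#' Mean-pool a map back to a coarser grid
#'
#' Inverse of [upsample_native_grid()]: averages `factor x factor` in-plane
#' blocks. Exact round trip with replication up-sampling.
#'
#' @param map A [metabolite_map()].
#' @param factor Integer in-plane pooling factor.
#' @return A [metabolite_map()].
#' @export
mean_pool_grid <- function(map, factor) {
  stopifnot(inherits(map, "metabolite_map"))
  factor <- as.integer(factor)
  v <- block_mean(map$values, c(factor, factor, 1L))
  metabolite_map(v, map$metabolite,
                 spacing_mm = map$spacing_mm * c(factor, factor, 1),
                 grid_name = map$grid_name)
}

#' Regrid a native map to anatomical resolution by nearest neighbor
#'
#' Subdivides each native voxel into the 1 mm (or `anat_res_mm`) cells it
#' contains: every anatomical cell takes the value of the native voxel
#' containing its center (half-open voxel extents). A 5 x 5 x 10 mm voxel at
#' 1 mm resolution becomes 250 identical cells; missing voxels propagate.
#'
#' @param map_native A [metabolite_map()] on the native grid.
#' @param anat_res_mm Target isotropic resolution in mm.
#' @return A [metabolite_map()] on the anatomical grid.
#' @export
regrid_nearest <- function(map_native, anat_res_mm = 1) {
  stopifnot(inherits(map_native, "metabolite_map"))
  sp <- map_native$spacing_mm
  d <- dim(map_native$values)
  nd <- as.integer(round(d * sp / anat_res_mm))
  if (any(abs(d * sp / anat_res_mm - nd) > 1e-9))
    stop("geometry error: anatomical grid does not span the native extent exactly")
  idx <- function(n_out, w) {
    centers <- ((seq_len(n_out) - 1) + 0.5) * anat_res_mm
    pmin(pmax(floor(centers / w), 0) + 1L, round(n_out * anat_res_mm / w))
  }
  out <- map_native$values[idx(nd[1], sp[1]), idx(nd[2], sp[2]), idx(nd[3], sp[3]),
                           drop = FALSE]
  metabolite_map(out, map_native$metabolite,
                 spacing_mm = rep(anat_res_mm, 3), grid_name = "anat")
}
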