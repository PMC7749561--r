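#' Reference-grid descriptor
#'
#' A regular grid in reference (atlas) space: dimensions, isotropic or
#' anisotropic spacing, and the world coordinate of the first cell's corner.
#' World coordinates of cell centers are `origin + (index + 0.5) * spacing`
#' with 0-based indices.
#'
#' @param dims Integer length-3 grid size.
#' @param spacing_mm Numeric length-3 cell size in mm (scalar recycled).
#' @param origin_mm Numeric length-3 world position of the grid corner.
#' @return An object of class `ref_grid`.
#' @export
ref_grid <- function(dims, spacing_mm = 1, origin_mm = c(0, 0, 0)) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  structure(list(dims = as.integer(dims), spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "ref_grid")
}

grid_centers <- function(grid) {
  # 3 x n matrix of cell-center world coordinates, column-major cell order
  d <- grid$dims
  cx <- grid$origin_mm[1] + (seq_len(d[1]) - 0.5) * grid$spacing_mm[1]
  cy <- grid$origin_mm[2] + (seq_len(d[2]) - 0.5) * grid$spacing_mm[2]
  cz <- grid$origin_mm[3] + (seq_len(d[3]) - 0.5) * grid$spacing_mm[3]
  rbind(rep(cx, times = d[2] * d[3]),
        rep(rep(cy, each = d[1]), times = d[3]),
        rep(cz, each = d[1] * d[2]))
}

#' Spatial-normalization transform chain
#'
#' Three-stage mapping from the MRSI slab to reference space: a rigid
#' slice-to-anatomy matrix, an affine anatomy-to-reference matrix, and an
#' optional nonlinear stage given as a dense displacement field. The
#' displacement field follows the resampling convention of common
#' registration tools: it is defined on the reference grid and gives, per
#' reference cell, the millimeter offset added to the reference coordinate
#' before pulling it back through the inverse affines.
#'
#' @param tx1 4x4 rigid matrix (slab to subject anatomy), row-major world
#'   mapping `y = A x`.
#' @param tx2 4x4 affine matrix (anatomy to reference, linear stage).
#' @param warp Optional list of three numeric 3D arrays (`dx`, `dy`, `dz`)
#'   on the reference grid, displacements in mm; all values must be finite.
#' @return An object of class `transform_chain`.
#' @export
transform_chain <- function(tx1 = diag(4), tx2 = diag(4), warp = NULL) {
  check_affine <- function(m, name) {
    if (!is.matrix(m) || !all(dim(m) == c(4, 4)))
      stop(sprintf("%s must be a 4x4 matrix", name))
    if (abs(det(m)) < 1e-12)
      stop(sprintf("invalid transform: %s is singular", name))
  }
  check_affine(tx1, "tx1"); check_affine(tx2, "tx2")
  if (!is.null(warp)) {
    stopifnot(is.list(warp), length(warp) == 3L)
    if (!all(vapply(warp, function(w) all(is.finite(w)), TRUE)))
      stop("invalid transform: displacement field contains non-finite values")
  }
  structure(list(tx1 = tx1, tx2 = tx2, warp = warp), class = "transform_chain")
}

apply_affine <- function(m, pts) {
  # pts: 3 x n
  out <- m %*% rbind(pts, 1)
  out[1:3, , drop = FALSE]
}

# Missing-aware trilinear sampling of a 3D array at continuous 0-based cell
# coordinates (3 x n). Weights over missing/out-of-bounds corners are
# renormalized; a point with no present corner is NA.
sample_trilinear <- function(values, coords) {
  d <- dim(values)
  x <- coords[1, ]; y <- coords[2, ]; z <- coords[3, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  acc <- numeric(length(x)); wtot <- numeric(length(x))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    inside <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
    idx <- which(inside & w > 0)
    if (length(idx)) {
      v <- values[cbind(ix[idx] + 1, iy[idx] + 1, iz[idx] + 1)]
      ok <- !is.na(v)
      idx <- idx[ok]
      if (length(idx)) {
        acc[idx] <- acc[idx] + w[idx] * v[ok]
        wtot[idx] <- wtot[idx] + w[idx]
      }
    }
  }
  out <- acc / wtot
  out[wtot == 0] <- NA_real_
  out
}

sample_nearest <- function(values, coords) {
  d <- dim(values)
  ix <- round(coords[1, ]); iy <- round(coords[2, ]); iz <- round(coords[3, ])
  inside <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
  out <- rep(NA_real_, ncol(coords))
  idx <- which(inside)
  if (length(idx))
    out[idx] <- values[cbind(ix[idx] + 1, iy[idx] + 1, iz[idx] + 1)]
  out
}

#' Resample a map to reference space through a transform chain
#'
#' Pulls each reference cell center back through the composed mapping in a
#' single resampling step (one interpolation, not three): the nonlinear
#' displacement is added in reference space, then the inverse of the
#' composed affines maps to input-space coordinates where the map is
#' sampled. Cells mapping outside the input domain become missing; trilinear
#' interpolation is missing-aware (weights renormalized over present
#' neighbors).
#'
#' @param map_1mm A [metabolite_map()] at anatomical resolution; its grid is
#'   assumed to start at world origin (0, 0, 0).
#' @param chain A [transform_chain()].
#' @param ref A [ref_grid()] describing the output space.
#' @param interpolation `"trilinear"` (continuous maps) or `"nearest"`
#'   (masks, QA maps).
#' @return A [metabolite_map()] on the reference grid.
#' @export
apply_transform_chain <- function(map_1mm, chain, ref,
                                  interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(map_1mm, "metabolite_map"), inherits(chain, "transform_chain"),
            inherits(ref, "ref_grid"))
  interpolation <- match.arg(interpolation)
  pts <- grid_centers(ref)
  if (!is.null(chain$warp)) {
    for (ax in 1:3) {
      w <- chain$warp[[ax]]
      if (!identical(as.integer(dim(w)), ref$dims))
        stop("displacement field does not match the reference grid")
      pts[ax, ] <- pts[ax, ] + as.vector(w)
    }
  }
  inv <- solve(chain$tx2 %*% chain$tx1)
  src <- apply_affine(inv, pts)
  # continuous 0-based input cell coordinates (input grid corner at origin)
  ci <- (src - 0.5 * map_1mm$spacing_mm) / map_1mm$spacing_mm
  vals <- switch(interpolation,
                 trilinear = sample_trilinear(map_1mm$values, ci),
                 nearest = sample_nearest(map_1mm$values, ci))
  out <- array(vals, dim = ref$dims)
  metabolite_map(out, map_1mm$metabolite, spacing_mm = ref$spacing_mm,
                 grid_name = "reference")
}

#' Group-average reference-space maps with data-density masking
#'
#' Averages co-registered subject maps cell-wise, counts how many subjects
#' contribute at each cell (the data density), and masks cells supported by
#' fewer than `min_density` subjects. SD uses the n-1 denominator and is
#' missing where fewer than two subjects contribute.
#'
#' @param maps List of [metabolite_map()] objects on one reference grid.
#' @param min_density Minimum subject count per cell (default 3).
#' @return An object of class `atlas_average`: `mean`, `sd`, integer
#'   `density`, `n_inputs`, `min_density`.
#' @export
average_with_density <- function(maps, min_density = 3) {
  if (length(maps) == 0L) stop("empty input list")
  dims <- dim(maps[[1]]$values)
  stack <- vapply(maps, function(m) {
    stopifnot(inherits(m, "metabolite_map"))
    if (!identical(dim(m$values), dims)) stop("maps are not on one grid")
    m$values
  }, array(0, dims))
  dim(stack) <- c(prod(dims), length(maps))
  present <- !is.na(stack)
  density <- as.integer(rowSums(present))
  s1 <- rowSums(stack, na.rm = TRUE)
  s2 <- rowSums(stack^2, na.rm = TRUE)
  mean_v <- ifelse(density > 0, s1 / density, NA_real_)
  var_v <- ifelse(density > 1, pmax(s2 - density * mean_v^2, 0) / (density - 1),
                  NA_real_)
  sd_v <- sqrt(var_v)
  low <- density < min_density
  mean_v[low] <- NA_real_
  sd_v[low] <- NA_real_
  shape <- function(v) { dim(v) <- dims; v }
  structure(
    list(mean = shape(mean_v), sd = shape(sd_v), density = shape(density),
         n_inputs = length(maps), min_density = min_density),
    class = "atlas_average"
  )
}

#' @export
print.atlas_average <- function(x, ...) {
  cat(sprintf("atlas average of %d maps; %d cells pass density >= %d\n",
              x$n_inputs, sum(!is.na(x$mean)), x$min_density))
  invisible(x)
}

#' Region-of-interest statistics of an averaged map
#'
#' Mean, SD and cell count of the averaged ratio map over each named binary
#' region. Regions with no overlap with the density-passing area are
#' reported as absent (`present = FALSE`, statistics `NA`), never as zero.
#'
#' @param avg An [average_with_density()] result.
#' @param masks Named list of logical arrays on the reference grid.
#' @return A data frame with columns `region`, `n_cells`, `mean`, `sd`,
#'   `present`, of class `roi_report`.
#' @export
roi_statistics <- function(avg, masks) {
  stopifnot(inherits(avg, "atlas_average"), is.list(masks), !is.null(names(masks)))
  rows <- lapply(names(masks), function(rn) {
    m <- masks[[rn]]
    if (!identical(dim(m), dim(avg$mean)))
      stop(sprintf("region '%s' is not on the reference grid", rn))
    v <- avg$mean[m]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      data.frame(region = rn, n_cells = 0L, mean = NA_real_, sd = NA_real_,
                 present = FALSE)
    else
      data.frame(region = rn, n_cells = length(v), mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                 present = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("roi_report", "data.frame")
  out
}

#' Write an ROI report as a mean +/- SD table
#'
#' One row per region, columns `region`, `n_cells` and `value` formatted as
#' `"mean ± SD"`; absent regions are written with an empty value.
#'
#' @param report A [roi_statistics()] data frame.
#' @param path Output CSV path.
#' @param digits Decimal places for the formatted values.
#' @return The path, invisibly.
#' @export
write_roi_report <- function(report, path, digits = 2) {
  fmt <- ifelse(report$present,
                sprintf("%.*f \u00b1 %.*f", digits, report$mean, digits,
                        report$sd),
                "")
  utils::write.csv(
    data.frame(region = report$region, n_cells = report$n_cells, value = fmt),
    path, row.names = FALSE)
  invisible(path)
}
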