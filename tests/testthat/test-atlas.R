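test_that("nearest regridding subdivides voxels exactly", {
  # one native 5 x 5 x 10 mm voxel becomes 250 identical 1 mm cells
  one <- metabolite_map(array(0.42, c(1, 1, 1)), "Glu")
  out <- regrid_nearest(one, 1)
  expect_identical(dim(out$values), c(5L, 5L, 10L))
  expect_identical(length(out$values), 250L)
  expect_true(all(out$values == 0.42))
  # missing native voxels propagate to all their cells
  nav <- metabolite_map(array(c(1, NA, 2, 3), c(2, 2, 1)), "Glu")
  reg <- regrid_nearest(nav, 1)
  expect_identical(sum(is.na(reg$values)), 250L)
  # per-voxel mean is conserved exactly (250 identical copies)
  set.seed(41)
  rnd <- metabolite_map(array(runif(8), c(2, 2, 2)), "Glu")
  up <- regrid_nearest(rnd, 1)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    cells <- up$values[(i - 1) * 5 + 1:5, (j - 1) * 5 + 1:5, (k - 1) * 10 + 1:10]
    expect_identical(unique(as.vector(cells)), rnd$values[i, j, k])
  }
})

test_that("checkerboard regridding matches a containing-voxel lookup oracle", {
  set.seed(13)
  nd <- c(6L, 4L, 2L)
  vals <- array(as.numeric((outer(1:6, 1:4, `+`) %% 2)), nd) + array(runif(prod(nd)), nd)
  m <- metabolite_map(vals, "Glu")
  out <- regrid_nearest(m, 1)
  d <- dim(out$values)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    # independent lookup of the native voxel containing the cell center
    ctr <- (c(i, j, k) - 0.5) * 1
    nv <- floor(ctr / c(5, 5, 10)) + 1
    expect_identical(out$values[i, j, k], vals[nv[1], nv[2], nv[3]])
  }
})

test_that("identity chain resampling is bit-identical under nearest", {
  set.seed(2)
  vals <- array(runif(10 * 12 * 4), c(10L, 12L, 4L))
  vals[sample(length(vals), 30)] <- NA
  m <- metabolite_map(vals, "Glu", spacing_mm = c(1, 1, 1), grid_name = "anat")
  ref <- ref_grid(dim(vals), 1)
  out <- apply_transform_chain(m, transform_chain(), ref, "nearest")
  expect_identical(out$values, vals)
  # trilinear at exact cell centers also reproduces values
  out_tri <- apply_transform_chain(m, transform_chain(), ref, "trilinear")
  expect_equal(out_tri$values[!is.na(vals)], vals[!is.na(vals)],
               tolerance = 1e-12)
})

test_that("a pure translation shifts the feature centroid by the translation", {
  vals <- array(0, c(20L, 20L, 3L))
  vals[8:10, 9:11, 2] <- 1
  m <- metabolite_map(vals, "Glu", spacing_mm = c(1, 1, 1), grid_name = "anat")
  tx1 <- diag(4); tx1[1, 4] <- 5   # +5 mm along x
  ref <- ref_grid(c(20L, 20L, 3L), 1)
  out <- apply_transform_chain(m, transform_chain(tx1 = tx1), ref, "nearest")
  centroid <- function(a) {
    w <- which(a == 1, arr.ind = TRUE)
    colMeans(w)
  }
  expect_equal(unname(centroid(out$values)[1] - centroid(vals)[1]), 5)
  expect_equal(unname(centroid(out$values)[2:3] - centroid(vals)[2:3]), c(0, 0))
})

test_that("singular transforms are rejected and warps validated", {
  expect_error(transform_chain(tx1 = matrix(0, 4, 4)), "singular")
  bad_warp <- list(array(Inf, c(2, 2, 2)), array(0, c(2, 2, 2)),
                   array(0, c(2, 2, 2)))
  expect_error(transform_chain(warp = bad_warp), "non-finite")
})

test_that("one-shot composed resampling beats sequential three-step resampling", {
  # smooth analytic field sampled on the input grid
  d <- c(30L, 30L, 6L)
  f <- function(x, y, z) 1 + sin(x / 6) * cos(y / 7) + 0.1 * z
  grid_vals <- function(dims, fn) {
    out <- array(0, dims)
    for (k in seq_len(dims[3]))
      out[, , k] <- outer(seq_len(dims[1]) - 0.5, seq_len(dims[2]) - 0.5,
                          function(a, b) fn(a, b, (k - 0.5)))
    out
  }
  m <- metabolite_map(grid_vals(d, f), "Glu", spacing_mm = c(1, 1, 1),
                      grid_name = "anat")
  rot <- function(theta, ctr) {
    t1 <- diag(4); t1[1:3, 4] <- -ctr
    r <- diag(4)
    r[1, 1] <- cos(theta); r[1, 2] <- -sin(theta)
    r[2, 1] <- sin(theta); r[2, 2] <- cos(theta)
    t2 <- diag(4); t2[1:3, 4] <- ctr
    t2 %*% r %*% t1
  }
  tx1 <- rot(0.15, c(15, 15, 3))
  tx2 <- rot(-0.08, c(15, 15, 3)); tx2[1, 4] <- tx2[1, 4] + 1.7
  ref <- ref_grid(d, 1)
  chain <- transform_chain(tx1 = tx1, tx2 = tx2)
  oneshot <- apply_transform_chain(m, chain, ref, "trilinear")
  seq1 <- apply_transform_chain(m, transform_chain(tx1 = tx1), ref, "trilinear")
  seq2 <- apply_transform_chain(seq1, transform_chain(tx1 = tx2), ref, "trilinear")
  # analytic oracle: the exact field at the pulled-back coordinates
  inv <- solve(tx2 %*% tx1)
  err <- function(res) {
    tot <- 0; n <- 0
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      v <- res$values[i, j, k]
      if (is.na(v)) next
      p <- inv %*% c(i - 0.5, j - 0.5, k - 0.5, 1)
      # skip points whose pullback leaves the analytic domain
      if (any(p[1:3] < 0) || any(p[1:3] > d)) next
      tot <- tot + (v - f(p[1], p[2], p[3]))^2
      n <- n + 1
    }
    sqrt(tot / n)
  }
  e1 <- err(oneshot); e2 <- err(seq2)
  expect_false(identical(oneshot$values, seq2$values))
  expect_lt(e1, e2)
})

test_that("density masking and averaging follow the counting rules", {
  set.seed(31)
  dims <- c(8L, 8L, 2L)
  mk <- function(miss_frac, val = NULL) {
    v <- array(if (is.null(val)) runif(prod(dims)) else val, dims)
    v[sample(length(v), round(miss_frac * length(v)))] <- NA
    metabolite_map(v, "Glu", spacing_mm = c(1, 1, 1), grid_name = "reference")
  }
  # a single input map is fully masked at the default density
  solo <- average_with_density(list(mk(0.2)), min_density = 3)
  expect_true(all(is.na(solo$mean)))
  expect_true(all(solo$density %in% 0:1))
  # identical constant maps: mean = constant, sd = 0, density = n
  const <- replicate(5, mk(0, 0.7), simplify = FALSE)
  avg <- average_with_density(const, min_density = 3)
  expect_true(all(avg$mean == 0.7))
  expect_true(all(avg$sd == 0))
  expect_true(all(avg$density == 5L))
  # seeded cohort: density equals exhaustive per-cell counting
  cohort <- replicate(23, mk(0.4), simplify = FALSE)
  a <- average_with_density(cohort, min_density = 3)
  for (i in seq_len(prod(dims))) {
    cnt <- sum(vapply(cohort, function(m) !is.na(m$values[i]), TRUE))
    expect_identical(a$density[i], cnt)
    if (cnt < 3) expect_true(is.na(a$mean[i]))
  }
  expect_lte(max(a$density), 23L)
  total_present <- sum(vapply(cohort, function(m) sum(!is.na(m$values)), 0L))
  expect_identical(sum(a$density), total_present)
  expect_error(average_with_density(list()), "empty")
})

test_that("averaging is order-invariant and density masking is monotone", {
  set.seed(17)
  dims <- c(6L, 6L, 1L)
  cohort <- replicate(7, {
    v <- array(runif(prod(dims)), dims)
    v[sample(length(v), 12)] <- NA
    metabolite_map(v, "Glu", spacing_mm = c(1, 1, 1), grid_name = "reference")
  }, simplify = FALSE)
  a1 <- average_with_density(cohort, 3)
  a2 <- average_with_density(rev(cohort), 3)
  expect_identical(a1$mean, a2$mean)
  expect_identical(a1$sd, a2$sd)
  expect_identical(a1$density, a2$density)
  # raising min_density never unmasks a cell
  for (k in 1:6) {
    lo <- average_with_density(cohort, k)
    hi <- average_with_density(cohort, k + 1)
    expect_true(all(is.na(hi$mean) | !is.na(lo$mean)))
    newly <- !is.na(hi$mean) & is.na(lo$mean)
    expect_identical(sum(newly), 0L)
  }
})

test_that("ROI statistics report absent regions as absent", {
  dims <- c(6L, 6L, 1L)
  vals <- array(0.5, dims)
  maps <- replicate(3, metabolite_map(vals, "Glu", spacing_mm = c(1, 1, 1),
                                      grid_name = "reference"),
                    simplify = FALSE)
  avg <- average_with_density(maps, 3)
  inside <- array(FALSE, dims); inside[2:4, 2:4, 1] <- TRUE
  stats <- roi_statistics(avg, list(core = inside, nowhere = array(FALSE, dims)))
  expect_equal(stats$mean[stats$region == "core"], 0.5)
  expect_equal(stats$sd[stats$region == "core"], 0)
  expect_identical(stats$n_cells[stats$region == "core"], 9L)
  expect_false(stats$present[stats$region == "nowhere"])
  expect_true(is.na(stats$mean[stats$region == "nowhere"]))
  # formatted report round-trips through CSV
  path <- tempfile(fileext = ".csv")
  write_roi_report(stats, path)
  tab <- read.csv(path)
  expect_identical(nrow(tab), 2L)
  expect_match(tab$value[1], "0.50")
})
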