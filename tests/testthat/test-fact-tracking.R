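test_that("every in-tube seed of a straight tube yields a streamline spanning the tube", {
  sf <- straight_fields()
  str_all <- track_all(sf$fa, sf$e1, sf$voxel_size)
  n_seeds <- sum(sf$fa >= 0.15)
  expect_equal(length(str_all), n_seeds)
  caps <- range(sf$spec$centerline[, 1])        # x = 4 and 44 mm
  spans <- vapply(str_all, function(pts) {
    xr <- range(pts[, 1])
    abs(xr[1] - caps[1]) <= 2 && abs(xr[2] - caps[2]) <= 2
  }, logical(1))
  expect_true(all(spans))
})

test_that("no streamline is emitted where FA is below threshold", {
  fa <- array(0, c(6, 6, 6))
  e1 <- array(rep(c(1, 0, 0), each = 216), c(6, 6, 6, 3))
  expect_length(track_all(fa, e1, c(2, 2, 2)), 0L)
})

test_that("tracking never turns between tubes crossing at 90 degrees", {
  cf <- crossing_fields()
  str_all <- track_all(cf$fa, cf$e1, cf$voxel_size)
  expect_gt(length(str_all), 0L)
  for (pts in str_all) {
    expect_lt(max_turning_angle(pts), 50)
    # straight tubes: every segment parallel to the overall chord
    chord <- pts[nrow(pts), ] - pts[1, ]
    chord <- chord / sqrt(sum(chord^2))
    d <- diff(pts)
    d <- d / sqrt(rowSums(d^2))
    expect_true(all(abs(d %*% chord) > cos(10 * pi / 180)))
  }
})

test_that("raising the FA threshold never lengthens streamlines or adds any", {
  ph <- phantom_spec()
  co <- make_cohort(ph, cohort_spec(n_control = 4, n_patient = 4, seed = 31))
  fit <- fit_tensor(co$mean_dwi, co$scheme)
  sm <- scalar_maps(fit)
  e1 <- principal_directions(fit, mask = sm$fa >= 0.1)
  prev_count <- Inf
  prev_maxlen <- Inf
  for (th in c(0.15, 0.3, 0.5)) {
    s <- track_all(sm$fa, e1, ph$voxel_size, fa_thresh = th, min_length = 0)
    lens <- vapply(s, polyline_length, numeric(1))
    expect_lte(length(s), prev_count)
    if (length(lens)) expect_lte(max(lens), prev_maxlen + 1e-9)
    prev_count <- length(s)
    prev_maxlen <- if (length(lens)) max(lens) else 0
  }
})

test_that("emitted streamlines respect the FA and angle constraints and are deterministic", {
  ph <- phantom_spec()
  co <- make_cohort(ph, cohort_spec(n_control = 4, n_patient = 4, seed = 32))
  fit <- fit_tensor(co$mean_dwi, co$scheme)
  sm <- scalar_maps(fit)
  e1 <- principal_directions(fit, mask = sm$fa >= 0.15)
  a <- track_all(sm$fa, e1, ph$voxel_size)
  b <- track_all(sm$fa, e1, ph$voxel_size)
  expect_identical(a, b)
  expect_lte(length(a), sum(sm$fa >= 0.15))
  for (pts in a) {
    expect_lte(max_turning_angle(pts), 50 + 1e-6)
    vox <- alongtract:::.streamline_voxels(pts, ph$grid_shape,
                                           ph$voxel_size)
    expect_true(all(sm$fa[vox] >= 0.15))
    expect_gte(polyline_length(pts), 10)
    expect_true(all(is.finite(pts)))
  }
})

test_that("multi-ROI selection keeps exactly the streamlines hitting every ROI", {
  sf <- straight_fields()
  str_all <- track_all(sf$fa, sf$e1, sf$voxel_size)
  roi1 <- roi_spec("sagittal", slice = 4L)
  roi2 <- roi_spec("sagittal", slice = 20L)
  bundle <- select_by_rois(str_all, list(roi1, roi2), sf$grid,
                           sf$voxel_size, name = "tube")
  # brute-force oracle: a full-plane sagittal ROI at slice i is hit iff the
  # streamline's x-range overlaps [(i-1) vs, i vs]
  hits <- function(pts, i) min(pts[, 1]) <= i * 2 && max(pts[, 1]) >= (i - 1) * 2
  oracle <- sum(vapply(str_all, function(p) hits(p, 4) && hits(p, 20),
                       logical(1)))
  expect_equal(length(bundle$streamlines), oracle)
  expect_gt(length(bundle$streamlines), 0L)

  # a streamline touching only one ROI is excluded
  short <- matrix(c(7, 9, 9, 12, 9, 9), 2, 3, byrow = TRUE)
  sel <- select_by_rois(list(short), list(roi1, roi2), sf$grid,
                        sf$voxel_size)
  expect_length(sel$streamlines, 0L)
  sel1 <- select_by_rois(list(short), list(roi1), sf$grid, sf$voxel_size)
  expect_length(sel1$streamlines, 1L)

  expect_error(roi_spec("coronal"), "slice")
  expect_error(select_by_rois(str_all, list(), sf$grid, sf$voxel_size),
               "at least one ROI")
  empty <- roi_spec("sagittal", slice = 4L, range1 = c(5L, 4L))
  expect_error(select_by_rois(str_all, list(empty), sf$grid, sf$voxel_size),
               "empty")
})

test_that("cingulum tripartition clips streamlines at the coronal planes", {
  # straight anterior-posterior line crossing both planes
  line <- cbind(rep(10, 50), seq(2, 38, length.out = 50), rep(10, 50))
  b <- structure(list(name = "cgc", streamlines = list(line)),
                 class = "bundle")
  parts <- partition_cgc(b, c(12, 26))
  lens <- vapply(parts, function(p)
    sum(vapply(p$streamlines, polyline_length, numeric(1))), numeric(1))
  expect_equal(sum(lens), polyline_length(line), tolerance = 1e-6)
  expect_length(parts$anterior$streamlines, 1L)
  expect_length(parts$middle$streamlines, 1L)
  expect_length(parts$posterior$streamlines, 1L)

  # entirely between the planes -> middle only
  mid <- cbind(rep(10, 10), seq(14, 24, length.out = 10), rep(10, 10))
  # neither plane intersects this bundle, which also warns
  expect_warning(
    parts2 <- partition_cgc(structure(list(name = "cgc",
                                           streamlines = list(mid)),
                                      class = "bundle"), c(12, 26)),
    "outside")
  expect_length(parts2$middle$streamlines, 1L)
  expect_length(parts2$anterior$streamlines, 0L)
  expect_length(parts2$posterior$streamlines, 0L)

  # C-shaped bundle: partition centroids ordered along y
  th <- seq(0, pi, length.out = 100)
  cshape <- cbind(rep(10, 100), 20 + 15 * cos(th), 10 + 15 * sin(th))
  parts3 <- partition_cgc(structure(list(name = "cgc",
                                         streamlines = list(cshape)),
                                    class = "bundle"), c(12, 28))
  cent <- vapply(parts3, function(p)
    mean(do.call(rbind, p$streamlines)[, 2]), numeric(1))
  expect_true(cent[["anterior"]] > cent[["middle"]])
  expect_true(cent[["middle"]] > cent[["posterior"]])

  expect_warning(partition_cgc(b, c(100, 200)), "outside")
  expect_error(partition_cgc(b, c(26, 12)), "y_post < y_ant")
})

test_that("overlap ratio reproduces Dice and Jaccard counts", {
  a <- array(FALSE, c(10, 10, 2))
  a[1:50] <- TRUE
  expect_equal(overlap_ratio(a, a), 1)
  b <- array(FALSE, c(10, 10, 2))
  b[101:150] <- TRUE
  expect_equal(overlap_ratio(a, b), 0)
  a100 <- array(FALSE, c(10, 10, 2)); a100[1:100] <- TRUE
  b50 <- array(FALSE, c(10, 10, 2)); b50[1:50] <- TRUE
  expect_equal(overlap_ratio(a100, b50, "dice"), 2 * 50 / 150)
  expect_equal(overlap_ratio(a100, b50, "jaccard"), 0.5)
  expect_error(overlap_ratio(array(FALSE, c(2, 2, 2)),
                             array(FALSE, c(2, 2, 2))), "empty")
  expect_error(overlap_ratio(a, array(TRUE, c(9, 10, 2))), "different grids")
})

test_that("bundle voxelization matches an integer-walk oracle and stays near the tube", {
  grid <- c(24L, 10L, 10L)
  line <- matrix(c(1, 9, 9, 45, 9, 9), 2, 3, byrow = TRUE)
  b <- structure(list(name = "line", streamlines = list(line)),
                 class = "bundle")
  m <- bundle_mask(b, grid, c(2, 2, 2))
  # x from 1 to 45 mm at 2 mm voxels -> voxels 1..23 in x, row j=5, k=5
  expect_equal(sum(m), 23L)
  expect_true(all(which(m, arr.ind = TRUE)[, 2] == 5))
  expect_error(bundle_mask(structure(list(name = "e", streamlines = list()),
                                     class = "bundle"), grid, 2), "empty")

  sf <- straight_fields()
  str_all <- track_all(sf$fa, sf$e1, sf$voxel_size)
  bm <- bundle_mask(structure(list(name = "tube", streamlines = str_all),
                              class = "bundle"), sf$grid, sf$voxel_size)
  # containment in the 1-voxel-dilated tube mask
  dil <- sf$phantom$mask
  for (ax in 1:3) for (sh in c(-1, 1)) {
    shifted <- array(FALSE, sf$grid)
    idx_src <- lapply(sf$grid, seq_len)
    idx_dst <- idx_src
    n <- sf$grid[ax]
    if (sh == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    shifted[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      sf$phantom$mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    dil <- dil | shifted
  }
  expect_true(all(dil[bm]))
})

test_that("the atlas ROI protocol records the published slice indices", {
  p <- limbic_roi_protocol()
  expect_equal(p$fornix$roi1$slice, 150L)
  expect_equal(p$fornix$roi2$slice, 108L)
  expect_equal(p$cgh$roi2$slice, 125L)
  expect_equal(p$cgc$roi2$slice, 183L)
  expect_equal(p$cgc_partition$posterior_plane$slice, 127L)
  expect_equal(p$cgc_partition$anterior_plane$slice, 162L)
})
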