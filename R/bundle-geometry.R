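# Bundle geometry: arc-length resampling, orientation alignment, the
# 30-point mean curve, metric-profile extraction and along-curve smoothing.

#' Total length of a polyline
#' @param points Matrix of ordered 3D points.
#' @return Length in the units of `points`.
#' @export
polyline_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Resample a polyline at uniform arc-length spacing
#'
#' @param points Matrix of >= 2 ordered 3D points with positive total
#'   length.
#' @param n Number of output points.
#' @return An `n` x 3 matrix: points at equal cumulative-arc-length steps,
#'   endpoints preserved.
#' @export
resample_arclength <- function(points, n = 30L) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("polyline needs at least 2 points")
  seglen <- sqrt(rowSums(diff(points)^2))
  keep <- c(TRUE, seglen > 0)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 2L) stop("polyline has zero length")
  cum <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  target <- seq(0, cum[length(cum)], length.out = n)
  out <- matrix(0, n, 3L)
  for (a in 1:3)
    out[, a] <- approx(cum, points[, a], xout = target, ties = "ordered")$y
  out
}

#' Orient every streamline of a bundle consistently
#'
#' Flips each streamline, when needed, so that its first point is nearer the
#' origin (an ROI centroid or an explicit 3D point) than its last point,
#' giving the bundle a single anatomical direction (e.g. hippocampus to
#' body for the fornix).
#'
#' @param bundle A bundle.
#' @param origin Either a 3-vector in world mm, or a [roi_spec()] together
#'   with `grid_shape`/`voxel_size`.
#' @param grid_shape,voxel_size Grid geometry, required when `origin` is an
#'   ROI.
#' @param tol Endpoints equidistant within `tol` mm keep their order (a
#'   warning notes the ambiguity).
#' @return The bundle with aligned streamline orientations.
#' @export
orient_bundle <- function(bundle, origin, grid_shape = NULL,
                          voxel_size = c(2, 2, 2), tol = 1e-6) {
  stopifnot(inherits(bundle, "bundle"))
  if (inherits(origin, "roi_spec")) {
    if (is.null(grid_shape)) stop("grid_shape needed to resolve an ROI origin")
    if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
    origin <- .roi_centroid(origin, grid_shape, voxel_size)
  }
  bundle$streamlines <- lapply(bundle$streamlines, function(pts) {
    d_first <- sqrt(sum((pts[1, ] - origin)^2))
    d_last <- sqrt(sum((pts[nrow(pts), ] - origin)^2))
    if (abs(d_first - d_last) <= tol) {
      warning("ambiguous streamline orientation; keeping original order")
      pts
    } else if (d_last < d_first) {
      pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    } else pts
  })
  bundle
}

#' Mean curve of a bundle, parameterized at 30 arc-length points
#'
#' The bundle's geometric representation: each (consistently oriented)
#' streamline is resampled to `n` equal-arc-length points, the point sets
#' are averaged coordinate-wise across streamlines, and the averaged
#' polyline is re-parameterized to exactly `n` uniform arc-length points.
#'
#' @param bundle A non-empty bundle; orient it first (or pass `origin`).
#' @param n Number of curve points.
#' @param origin Optional origin forwarded to [orient_bundle()].
#' @param orientation Free-text anatomical orientation tag stored on the
#'   curve (e.g. `"hippocampus->body"`).
#' @param grid_shape,voxel_size Forwarded to [orient_bundle()] when `origin`
#'   is an ROI.
#' @return An object of class `mean_curve`: list with `points` (`n` x 3,
#'   world mm), `arc` (cumulative arc length per point), `bundle` (name) and
#'   `orientation`.
#' @export
mean_curve <- function(bundle, n = 30L, origin = NULL,
                       orientation = "start->end", grid_shape = NULL,
                       voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(bundle, "bundle"))
  if (length(bundle$streamlines) == 0L) stop("bundle is empty")
  if (!is.null(origin))
    bundle <- orient_bundle(bundle, origin, grid_shape, voxel_size)
  res <- lapply(bundle$streamlines, resample_arclength, n = n)
  avg <- Reduce(`+`, res) / length(res)
  pts <- resample_arclength(avg, n = n)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  structure(list(points = pts, arc = arc, bundle = bundle$name,
                 orientation = orientation),
            class = "mean_curve")
}

#' @export
print.mean_curve <- function(x, ...) {
  cat(sprintf("Mean curve of '%s': %d points, %.1f mm, oriented %s\n",
              x$bundle, nrow(x$points), max(x$arc), x$orientation))
  invisible(x)
}

# Trilinear interpolation of a 3D map at world-mm points (voxel centers at
# (i - 0.5) * voxel_size). Points must lie inside the grid box; sampling
# within the outer half-voxel clamps to the edge voxel.
.trilinear <- function(map, points, voxel_size) {
  dims <- dim(map)
  u <- sweep(points, 2L, voxel_size, "/")
  out_of_grid <- which(apply(u < 0, 1L, any) |
                       apply(sweep(u, 2L, dims, ">"), 1L, any))
  if (length(out_of_grid))
    stop("curve point ", out_of_grid[1], " lies outside the map grid")
  uc <- u - 0.5
  i0 <- floor(uc) + 1L
  fr <- uc - (i0 - 1L)
  lo <- pmax(pmin(i0, dims[col(i0)]), 1L)
  hi <- pmax(pmin(i0 + 1L, dims[col(i0)]), 1L)
  dim(lo) <- dim(hi) <- dim(i0)
  val <- numeric(nrow(points))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- if (dx == 0) lo[, 1] else hi[, 1]
    jj <- if (dy == 0) lo[, 2] else hi[, 2]
    kk <- if (dz == 0) lo[, 3] else hi[, 3]
    w <- (if (dx == 0) 1 - fr[, 1] else fr[, 1]) *
      (if (dy == 0) 1 - fr[, 2] else fr[, 2]) *
      (if (dz == 0) 1 - fr[, 3] else fr[, 3])
    val <- val + w * map[cbind(ii, jj, kk)]
  }
  val
}

#' Sample a scalar map along a mean curve
#'
#' Trilinear interpolation of a subject's metric map at each curve point;
#' all subjects share the same (atlas-space) curve, so profiles are
#' point-to-point comparable across subjects.
#'
#' @param map 3D scalar array (FA, RD or AD).
#' @param curve A [mean_curve()] or a plain matrix of points (world mm).
#' @param voxel_size Voxel size in mm.
#' @return Numeric vector, one value per curve point.
#' @export
extract_profile <- function(map, curve, voxel_size = c(2, 2, 2)) {
  pts <- if (inherits(curve, "mean_curve")) curve$points else as.matrix(curve)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  .trilinear(map, pts, voxel_size)
}

#' Smooth a profile by averaging nearest neighbors along the curve
#'
#' Default (`window = "six"`): each point is replaced by the mean of itself
#' and its five nearest neighbors by index, the tie at distance three
#' resolved toward the curve start (offsets -3..+2); near the ends the
#' window truncates to the available points. `window = "five"` uses the
#' symmetric centred five-point window (offsets -2..+2) instead.
#'
#' @param values Numeric profile (length 30 by convention; any length >= 1
#'   is accepted for the windows to truncate against).
#' @param n_expected If non-NULL, error unless `length(values)` matches.
#' @param window `"six"` or `"five"`.
#' @return Smoothed profile, same length.
#' @export
smooth_profile <- function(values, n_expected = 30L,
                           window = c("six", "five")) {
  window <- match.arg(window)
  if (!is.null(n_expected) && length(values) != n_expected)
    stop("profile has length ", length(values), ", expected ", n_expected)
  offs <- if (window == "six") -3:2 else -2:2
  n <- length(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- i + offs
    idx <- idx[idx >= 1L & idx <= n]
    out[i] <- mean(values[idx])
  }
  out
}
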