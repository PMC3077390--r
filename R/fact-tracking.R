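# Deterministic FACT streamline tractography (voxel-boundary propagation
# along principal eigenvectors), multi-ROI bundle extraction, cingulum
# tripartition, voxel masks and the volume-overlap reliability measure.

#' Whole-volume FACT tractography
#'
#' Seeds every voxel at or above the FA threshold (optionally restricted by
#' `seed_mask`) and propagates bidirectionally along the per-voxel principal
#' eigenvector in the classic FACT fashion: the direction is updated on each
#' voxel entry, polyline vertices are laid down at voxel-boundary crossings,
#' and propagation stops on entering a voxel below the FA threshold, on a
#' turning angle above `angle_thresh`, or on leaving the grid. The
#' eigenvector sign is chosen to continue the incoming direction.
#'
#' @param fa 3D FA map.
#' @param e1 4D principal-direction field (x, y, z, 3), e.g. from
#'   [principal_directions()].
#' @param voxel_size Voxel edge length(s) in mm.
#' @param fa_thresh FA termination/seeding threshold, in (0, 1).
#' @param angle_thresh Maximum turning angle in degrees, in (0, 90].
#' @param min_length Minimum streamline length in mm; shorter ones are
#'   dropped.
#' @param seed_mask Optional logical 3D array restricting seed voxels.
#' @return A list of streamlines, each a matrix of ordered 3D points in
#'   world mm.
#' @export
track_all <- function(fa, e1, voxel_size = c(2, 2, 2), fa_thresh = 0.15,
                      angle_thresh = 50, min_length = 10,
                      seed_mask = NULL) {
  dims <- dim(fa)
  if (length(dim(e1)) != 4L || any(dim(e1)[1:3] != dims))
    stop("fa and e1 are not on the same grid")
  if (fa_thresh <= 0 || fa_thresh >= 1) stop("fa_thresh must be in (0, 1)")
  if (angle_thresh <= 0 || angle_thresh > 90)
    stop("angle_thresh must be in (0, 90] degrees")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  cos_thresh <- cos(angle_thresh * pi / 180)

  seeds <- fa >= fa_thresh
  if (!is.null(seed_mask)) seeds <- seeds & seed_mask
  seed_idx <- which(seeds, arr.ind = TRUE)
  nvox3 <- dims
  e1m <- matrix(e1, prod(dims), 3L)
  fav <- as.vector(fa)
  lin <- function(v) v[1] + nvox3[1] * (v[2] - 1L + nvox3[2] * (v[3] - 1L))

  trace_half <- function(v0, d0) {
    # vertices at boundary crossings, starting after the seed center
    pts <- vector("list", 512L)
    np <- 0L
    v <- v0
    p <- (v - 0.5) * voxel_size
    d <- d0
    for (step in 1:5000) {
      tb <- rep(Inf, 3)
      for (a in 1:3) {
        if (d[a] > 1e-12) tb[a] <- (v[a] * voxel_size[a] - p[a]) / d[a]
        else if (d[a] < -1e-12) tb[a] <- ((v[a] - 1) * voxel_size[a] - p[a]) / d[a]
      }
      tmin <- min(tb)
      pexit <- p + tmin * d
      np <- np + 1L
      pts[[np]] <- pexit
      vn <- floor((pexit + 1e-7 * d) / voxel_size) + 1L
      if (any(vn < 1L) || any(vn > nvox3)) break
      li <- lin(vn)
      if (fav[li] < fa_thresh) break
      dn <- e1m[li, ]
      dp <- sum(dn * d)
      if (dp < 0) { dn <- -dn; dp <- -dp }
      if (dp < cos_thresh) break
      v <- vn
      p <- pexit
      d <- dn
    }
    do.call(rbind, pts[seq_len(np)])
  }

  out <- vector("list", nrow(seed_idx))
  nkeep <- 0L
  for (s in seq_len(nrow(seed_idx))) {
    v0 <- seed_idx[s, ]
    d0 <- e1m[lin(v0), ]
    if (any(!is.finite(d0))) next
    fwd <- trace_half(v0, d0)
    bwd <- trace_half(v0, -d0)
    center <- matrix((v0 - 0.5) * voxel_size, 1L, 3L)
    pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE], center, fwd)
    keep <- c(TRUE, rowSums((pts[-1L, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 1e-18)
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) < 2L) next
    if (polyline_length(pts) < min_length) next
    nkeep <- nkeep + 1L
    out[[nkeep]] <- pts
  }
  out[seq_len(nkeep)]
}

#' Define a region of interest
#'
#' Either a full in-plane rectangle on a single slice (axis given
#' anatomically -- `"sagittal"` = x, `"coronal"` = y, `"axial"` = z -- or as
#' the axis letter), or an arbitrary voxel mask.
#'
#' @param kind `"sagittal"`, `"coronal"`, `"axial"` (or `"x"`, `"y"`, `"z"`)
#'   for plane ROIs; `"mask"` for a voxel mask.
#' @param slice Slice index (1-based) for plane ROIs.
#' @param range1,range2 Inclusive index ranges `c(lo, hi)` in the two
#'   remaining axes (in axis order); `NULL` means the full extent.
#' @param mask Logical 3D array for `kind = "mask"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(kind, slice = NULL, range1 = NULL, range2 = NULL,
                     mask = NULL) {
  alias <- c(sagittal = 1L, coronal = 2L, axial = 3L, x = 1L, y = 2L, z = 3L)
  if (identical(kind, "mask")) {
    if (is.null(mask) || !any(mask)) stop("mask ROI is empty")
    return(structure(list(kind = "mask", mask = mask), class = "roi_spec"))
  }
  if (!kind %in% names(alias)) stop("unknown ROI kind: ", kind)
  if (is.null(slice)) stop("plane ROI needs a slice index")
  structure(list(kind = "plane", axis = unname(alias[[kind]]),
                 slice = as.integer(slice),
                 range1 = range1, range2 = range2),
            class = "roi_spec")
}

# Linear voxel indices covered by an ROI on a given grid.
.roi_voxels <- function(roi, grid_shape) {
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$kind == "mask") {
    if (any(dim(roi$mask) != grid_shape)) stop("ROI mask grid mismatch")
    idx <- which(as.vector(roi$mask))
    if (length(idx) == 0L) stop("ROI is empty")
    return(idx)
  }
  if (roi$slice < 1L || roi$slice > grid_shape[roi$axis])
    stop("ROI slice index outside the grid")
  others <- setdiff(1:3, roi$axis)
  r1 <- if (is.null(roi$range1)) c(1L, grid_shape[others[1]]) else roi$range1
  r2 <- if (is.null(roi$range2)) c(1L, grid_shape[others[2]]) else roi$range2
  if (r1[1] > r1[2] || r2[1] > r2[2]) stop("ROI is empty")
  g <- expand.grid(a = r1[1]:r1[2], b = r2[1]:r2[2])
  v <- matrix(0L, nrow(g), 3L)
  v[, roi$axis] <- roi$slice
  v[, others[1]] <- g$a
  v[, others[2]] <- g$b
  v[, 1] + grid_shape[1] * (v[, 2] - 1L + grid_shape[2] * (v[, 3] - 1L))
}

# World-mm centroid of an ROI's voxels.
.roi_centroid <- function(roi, grid_shape, voxel_size) {
  idx <- .roi_voxels(roi, grid_shape)
  k <- (idx - 1L) %/% (grid_shape[1] * grid_shape[2])
  rem <- (idx - 1L) %% (grid_shape[1] * grid_shape[2])
  j <- rem %/% grid_shape[1]
  i <- rem %% grid_shape[1]
  c(mean(i + 0.5) * voxel_size[1], mean(j + 0.5) * voxel_size[2],
    mean(k + 0.5) * voxel_size[3])
}

# Linear indices of the voxels a polyline passes through, by densifying each
# segment at half-voxel steps (exact for FACT output, whose vertices sit on
# voxel boundaries).
.streamline_voxels <- function(points, grid_shape, voxel_size) {
  step <- 0.45 * min(voxel_size)
  segs <- diff(points)
  lens <- sqrt(rowSums(segs^2))
  samp <- list(points[1, , drop = FALSE])
  for (k in seq_along(lens)) {
    if (lens[k] == 0) next
    nstep <- max(2L, ceiling(lens[k] / step) + 1L)
    t <- seq(0, 1, length.out = nstep)[-1L]
    samp[[length(samp) + 1L]] <-
      cbind(points[k, 1] + t * segs[k, 1],
            points[k, 2] + t * segs[k, 2],
            points[k, 3] + t * segs[k, 3])
  }
  # only midpoints between consecutive samples are used: they identify the
  # traversed voxel unambiguously even when a vertex (e.g. a FACT
  # termination point) lies exactly on a voxel boundary
  sp <- do.call(rbind, samp)
  mid <- (sp[-1L, , drop = FALSE] + sp[-nrow(sp), , drop = FALSE]) / 2
  v <- floor(sweep(mid, 2L, voxel_size, "/")) + 1L
  ok <- v[, 1] >= 1L & v[, 1] <= grid_shape[1] &
    v[, 2] >= 1L & v[, 2] <= grid_shape[2] &
    v[, 3] >= 1L & v[, 3] <= grid_shape[3]
  v <- v[ok, , drop = FALSE]
  unique(v[, 1] + grid_shape[1] * (v[, 2] - 1L + grid_shape[2] * (v[, 3] - 1L)))
}

#' Extract a bundle with multi-ROI AND logic
#'
#' Keeps exactly the streamlines that intersect every ROI, the multi-ROI
#' protocol used to pick out the fornix and cingulum segments.
#'
#' @param streamlines List of streamline point matrices (world mm).
#' @param rois List of [roi_spec()] objects (all must be hit).
#' @param grid_shape Integer 3-vector.
#' @param voxel_size Voxel size in mm.
#' @param name Bundle name to record.
#' @return An object of class `bundle`: list with `name` and `streamlines`.
#' @export
select_by_rois <- function(streamlines, rois, grid_shape,
                           voxel_size = c(2, 2, 2), name = "bundle") {
  if (length(rois) < 1L) stop("need at least one ROI")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  roi_idx <- lapply(rois, .roi_voxels, grid_shape = grid_shape)
  keep <- vapply(streamlines, function(pts) {
    vox <- .streamline_voxels(pts, grid_shape, voxel_size)
    all(vapply(roi_idx, function(r) any(vox %in% r), logical(1)))
  }, logical(1))
  structure(list(name = name, streamlines = streamlines[keep]),
            class = "bundle")
}

#' @export
print.bundle <- function(x, ...) {
  cat(sprintf("Bundle '%s': %d streamlines\n", x$name, length(x$streamlines)))
  invisible(x)
}

#' Split a cingulum-like bundle into anterior / middle / posterior thirds
#'
#' Clips every streamline at two coronal (constant-y) planes and groups the
#' resulting pieces by region, emulating the tripartition of the cingulate
#' cingulum at the corpus callosum's anterior and posterior projections.
#'
#' @param bundle A [select_by_rois()] bundle.
#' @param coronal_planes `c(y_post, y_ant)` world-mm plane positions,
#'   `y_post < y_ant`.
#' @return Named list of three bundles: `anterior` (y > y_ant), `middle`,
#'   `posterior` (y < y_post). Warns if a plane misses the bundle extent.
#' @export
partition_cgc <- function(bundle, coronal_planes) {
  stopifnot(inherits(bundle, "bundle"))
  y_post <- coronal_planes[1]
  y_ant <- coronal_planes[2]
  if (!(y_post < y_ant)) stop("require y_post < y_ant")
  ys <- unlist(lapply(bundle$streamlines, function(p) range(p[, 2])))
  if (length(ys) && (y_post < min(ys) || y_ant > max(ys)))
    warning("partition plane(s) outside the bundle extent; some partitions may be empty")

  region_of <- function(y) if (y > y_ant) 3L else if (y < y_post) 1L else 2L
  pieces <- list(`1` = list(), `2` = list(), `3` = list())
  for (pts in bundle$streamlines) {
    # insert exact crossing points at both planes
    aug <- list(pts[1, ])
    for (k in 2:nrow(pts)) {
      a <- pts[k - 1, ]; b <- pts[k, ]
      crossings <- c()
      for (plane in c(y_post, y_ant)) {
        if ((a[2] - plane) * (b[2] - plane) < 0) {
          t <- (plane - a[2]) / (b[2] - a[2])
          crossings <- c(crossings, t)
        }
      }
      for (t in sort(crossings)) aug[[length(aug) + 1L]] <- a + t * (b - a)
      aug[[length(aug) + 1L]] <- b
    }
    aug <- do.call(rbind, aug)
    # assign each segment by its midpoint, collect contiguous runs
    mids <- (aug[-1L, 2] + aug[-nrow(aug), 2]) / 2
    reg <- vapply(mids, region_of, integer(1))
    run_start <- 1L
    for (k in seq_along(reg)) {
      end_run <- k == length(reg) || reg[k + 1L] != reg[k]
      if (end_run) {
        piece <- aug[run_start:(k + 1L), , drop = FALSE]
        if (nrow(piece) >= 2L && polyline_length(piece) > 1e-9) {
          r <- as.character(reg[k])
          pieces[[r]][[length(pieces[[r]]) + 1L]] <- piece
        }
        run_start <- k + 1L
      }
    }
  }
  mk <- function(r, suffix) structure(
    list(name = paste0(bundle$name, "_", suffix), streamlines = pieces[[r]]),
    class = "bundle")
  list(anterior = mk("3", "anterior"), middle = mk("2", "middle"),
       posterior = mk("1", "posterior"))
}

#' Volume overlap ratio between two binary masks
#'
#' Reliability measure comparing an automatically extracted bundle volume
#' with a reference segmentation.
#'
#' @param maskA,maskB Logical arrays on the same grid.
#' @param method `"dice"` (default): `2|A&B| / (|A| + |B|)`; `"jaccard"`:
#'   `|A&B| / |A or B|`.
#' @return A value in `[0, 1]`.
#' @export
overlap_ratio <- function(maskA, maskB, method = c("dice", "jaccard")) {
  method <- match.arg(method)
  if (any(dim(maskA) != dim(maskB))) stop("masks are on different grids")
  a <- as.logical(maskA); b <- as.logical(maskB)
  nA <- sum(a); nB <- sum(b)
  if (nA == 0L && nB == 0L) stop("both masks are empty")
  nAB <- sum(a & b)
  if (method == "dice") 2 * nAB / (nA + nB) else nAB / sum(a | b)
}

#' Voxel mask traversed by a bundle
#'
#' @param bundle A non-empty bundle.
#' @param grid_shape Integer 3-vector.
#' @param voxel_size Voxel size in mm.
#' @return Logical 3D array marking every voxel any streamline passes
#'   through.
#' @export
bundle_mask <- function(bundle, grid_shape, voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(bundle, "bundle"))
  if (length(bundle$streamlines) == 0L) stop("bundle is empty")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  m <- array(FALSE, grid_shape)
  for (pts in bundle$streamlines)
    m[.streamline_voxels(pts, grid_shape, voxel_size)] <- TRUE
  m
}

#' Atlas-space ROI protocol for the limbic bundles
#'
#' The recorded slice indices (in Mori DTI atlas space) of the plane ROIs
#' that delineate the fornix, the hippocampal cingulum (CGH), the cingulate
#' cingulum (CGC) and the coronal planes of the CGC tripartition. Intended
#' for real atlas-aligned data; phantom tests define analogous ROIs on their
#' own grids. The same protocol ships as a YAML config in
#' `system.file("extdata", "limbic_rois.yaml", package = "alongtract")`.
#'
#' @return A nested list, one entry per bundle, naming each ROI's plane and
#'   slice index.
#' @export
limbic_roi_protocol <- function() {
  list(
    fornix = list(roi1 = list(plane = "coronal", slice = 150L),
                  roi2 = list(plane = "axial", slice = 108L)),
    cgh = list(roi1 = list(plane = "axial", slice = 126L),
               roi2 = list(plane = "coronal", slice = 125L)),
    cgc = list(roi1 = list(plane = "axial", slice = 126L),
               roi2 = list(plane = "coronal", slice = 183L)),
    cgc_partition = list(posterior_plane = list(plane = "coronal", slice = 127L),
                         anterior_plane = list(plane = "coronal", slice = 162L))
  )
}
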