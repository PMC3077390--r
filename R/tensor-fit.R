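# Per-voxel diffusion tensor estimation by log-linear least squares and the
# scalar maps (FA, RD, AD) derived from its eigenvalues.

#' Fit the diffusion tensor in every voxel
#'
#' Solves, voxel by voxel, the log-linearized tensor model
#' `ln(S_i / S0) = -b_i g_i' D g_i` by ordinary least squares over the six
#' unique tensor coefficients. Multiple baseline volumes are averaged before
#' the log ratio. Voxels with nonpositive baseline signal get a zero tensor
#' and are flagged.
#'
#' @param dwi 4D signal array (x, y, z, volume).
#' @param scheme The [gradient_scheme()] describing the volumes.
#' @param min_signal Floor applied to the measured signal before the log.
#' @return An object of class `tensor_volume`: a list with `tensors`
#'   (4D array, 6 coefficient planes Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in
#'   mm^2/s), `s0` (fitted baseline, 3D), `bad` (logical 3D array flagging
#'   voxels that could not be fitted) and `voxel_size` if present on input.
#' @export
fit_tensor <- function(dwi, scheme, min_signal = 1e-6) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  dims <- dim(dwi)
  if (length(dims) != 4L || dims[4] != length(scheme$bvals))
    stop("volume count of dwi does not match the gradient scheme")
  if (any(!is.finite(dwi))) stop("dwi contains non-finite values")
  dw <- scheme$bvals > 0
  if (sum(dw) < 6L) stop("need at least 6 diffusion-weighted volumes")
  B <- .bmatrix(scheme)[dw, , drop = FALSE]
  if (qr(B)$rank < 6L)
    stop("gradient directions are collinear: rank-deficient design")
  P <- solve(crossprod(B), t(B))         # 6 x nd pseudoinverse

  nvox <- prod(dims[1:3])
  S <- matrix(dwi, nvox, dims[4])
  s0 <- if (sum(!dw) > 1L) rowMeans(S[, !dw, drop = FALSE]) else S[, !dw]
  bad <- s0 <= 0
  s0safe <- ifelse(bad, 1, s0)
  Y <- log(pmax(S[, dw, drop = FALSE], min_signal) / s0safe)
  D <- -Y %*% t(P)                       # nvox x 6
  D[bad, ] <- 0
  structure(list(tensors = array(D, c(dims[1:3], 6L)),
                 s0 = array(s0, dims[1:3]),
                 bad = array(bad, dims[1:3])),
            class = "tensor_volume")
}

#' Eigendecompose a single diffusion tensor
#'
#' @param tensor Either the 6 unique coefficients (Dxx, Dyy, Dzz, Dxy, Dxz,
#'   Dyz) or a symmetric 3x3 matrix.
#' @return A list with `values` (raw eigenvalues, descending),
#'   `values_clamped` (negatives set to 0, for metric computation),
#'   `vectors` (columns e1, e2, e3, unit norm) and `clamped` (logical).
#' @export
eigendecompose <- function(tensor) {
  if (is.matrix(tensor)) {
    M <- tensor
    if (any(dim(M) != c(3L, 3L)) || any(abs(M - t(M)) > 1e-12))
      stop("tensor must be a symmetric 3x3 matrix")
  } else {
    if (length(tensor) != 6L) stop("tensor must have 6 coefficients")
    M <- matrix(c(tensor[1], tensor[4], tensor[5],
                  tensor[4], tensor[2], tensor[6],
                  tensor[5], tensor[6], tensor[3]), 3L, 3L)
  }
  if (any(!is.finite(M))) stop("tensor contains non-finite values")
  e <- eigen(M, symmetric = TRUE)
  list(values = e$values,
       values_clamped = pmax(e$values, 0),
       vectors = e$vectors,
       clamped = any(e$values < 0))
}

# Closed-form eigenvalues of many symmetric 3x3 matrices at once
# (trigonometric/Cardano method). `D` is nvox x 6. Returns nvox x 3, sorted
# descending. Fully vectorized; the workhorse behind scalar_maps().
.eigenvalues3 <- function(D) {
  xx <- D[, 1]; yy <- D[, 2]; zz <- D[, 3]
  xy <- D[, 4]; xz <- D[, 5]; yz <- D[, 6]
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * (xy^2 + xz^2 + yz^2)
  p <- sqrt(p2 / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    bxx <- (xx - q) / p; byy <- (yy - q) / p; bzz <- (zz - q) / p
    bxy <- xy / p; bxz <- xz / p; byz <- yz / p
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- (q + 2 * p * cos(phi))[nz]
    l3[nz] <- (q + 2 * p * cos(phi + 2 * pi / 3))[nz]
    l2[nz] <- (3 * q - l1 - l3)[nz]
  }
  cbind(l1, l2, l3, deparse.level = 0)
}

#' Fractional anisotropy from sorted eigenvalues
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`; the all-zero
#' tensor is assigned FA = 0. Vectorized over voxels.
#'
#' @param l1,l2,l3 Nonnegative eigenvalues (any order).
#' @return FA values in `[0, 1]`.
#' @export
fa_value <- function(l1, l2, l3) {
  m <- (l1 + l2 + l3) / 3
  den <- l1^2 + l2^2 + l3^2
  num <- (l1 - m)^2 + (l2 - m)^2 + (l3 - m)^2
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  pmin(pmax(fa, 0), 1)
}

#' Radial diffusivity: mean of the two minor eigenvalues
#' @param l2,l3 The two minor eigenvalues (mm^2/s), clamped nonnegative.
#' @return `(l2 + l3) / 2`.
#' @export
rd_value <- function(l2, l3) (l2 + l3) / 2

#' Axial diffusivity: the major eigenvalue
#' @param l1 The major eigenvalue (mm^2/s), clamped nonnegative.
#' @return `l1`.
#' @export
ad_value <- function(l1) l1

#' FA, RD and AD maps from a tensor volume
#'
#' Eigenvalues are computed per voxel in closed form; negative eigenvalues
#' (noise-driven) are clamped to zero before the metric formulas and the
#' affected voxels flagged.
#'
#' @param tensors A `tensor_volume` from [fit_tensor()], the list from
#'   [make_phantom()], or a bare 4D coefficient array.
#' @return A list with 3D arrays `fa`, `rd`, `ad` and the logical clamp-flag
#'   array `clamped`.
#' @export
scalar_maps <- function(tensors) {
  if (is.list(tensors)) tensors <- tensors$tensors
  dims <- dim(tensors)
  if (length(dims) != 4L || dims[4] != 6L)
    stop("expected a 4D array with 6 coefficient planes")
  if (any(!is.finite(tensors))) stop("tensors contain non-finite values")
  D <- matrix(tensors, prod(dims[1:3]), 6L)
  ev <- .eigenvalues3(D)
  clamped <- ev[, 3] < 0 | ev[, 2] < 0 | ev[, 1] < 0
  ev[ev < 0] <- 0
  g3 <- dims[1:3]
  list(fa = array(fa_value(ev[, 1], ev[, 2], ev[, 3]), g3),
       rd = array(rd_value(ev[, 2], ev[, 3]), g3),
       ad = array(ad_value(ev[, 1]), g3),
       clamped = array(clamped, g3))
}

#' Principal eigenvector field for tractography
#'
#' Computes the unit principal eigenvector in the requested voxels (by
#' default those at or above an FA floor, which is all FACT ever consults).
#'
#' @param tensors A `tensor_volume`, [make_phantom()] list, or 4D array.
#' @param mask Optional logical 3D array restricting computation.
#' @return 4D array (x, y, z, 3) of principal directions, NA outside `mask`.
#' @export
principal_directions <- function(tensors, mask = NULL) {
  if (is.list(tensors)) tensors <- tensors$tensors
  dims <- dim(tensors)
  nvox <- prod(dims[1:3])
  D <- matrix(tensors, nvox, 6L)
  idx <- if (is.null(mask)) seq_len(nvox) else which(as.vector(mask))
  E <- matrix(NA_real_, nvox, 3L)
  for (v in idx) {
    M <- matrix(c(D[v, 1], D[v, 4], D[v, 5],
                  D[v, 4], D[v, 2], D[v, 6],
                  D[v, 5], D[v, 6], D[v, 3]), 3L, 3L)
    E[v, ] <- eigen(M, symmetric = TRUE)$vectors[, 1]
  }
  array(E, c(dims[1:3], 3L))
}
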