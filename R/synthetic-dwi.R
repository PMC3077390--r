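# Synthetic diffusion-weighted phantoms: tube geometries with anisotropic
# interior tensors, the 16-volume acquisition scheme, Rician noise, and
# multi-subject cohorts with a localized group effect and clinical couplings.

# 15 unit directions from electrostatic (antipodal Coulomb) repulsion,
# frozen for reproducibility; min pairwise angle 36.95 degrees.
.DIRECTIONS15 <- matrix(c(
  0.395742, -0.770553, 0.499637,
  -0.519331, 0.609642, 0.598859,
  0.655594, 0.363236, 0.662009,
  -0.884948, 0.083976, 0.458056,
  0.792322, -0.267779, 0.548198,
  -0.720340, -0.536491, 0.439644,
  -0.807389, 0.589977, 0.007114,
  0.970741, 0.217067, 0.102682,
  0.535088, 0.812465, 0.231477,
  -0.211210, -0.930118, 0.300451,
  -0.185420, 0.963570, 0.192750,
  0.087093, 0.615937, 0.782966,
  -0.385262, 0.051487, 0.921370,
  0.276789, -0.087367, 0.956951,
  -0.157945, -0.541468, 0.825752
), ncol = 3, byrow = TRUE)
# re-normalize the tabulated values so each direction is unit to machine
# precision (the table is printed to 6 decimals)
.DIRECTIONS15 <- .DIRECTIONS15 / sqrt(rowSums(.DIRECTIONS15^2))

#' Gradient scheme for a diffusion acquisition
#'
#' Bundles b-values and unit gradient directions, one row per acquired
#' volume. Baseline volumes carry b = 0 and a zero direction.
#'
#' @param bvals Numeric vector of b-values in s/mm^2 (0 for baselines).
#' @param bvecs Numeric matrix, one unit 3-vector per row (rows with b = 0
#'   may be zero).
#' @return An object of class `gradient_scheme`: a list with elements
#'   `bvals` and `bvecs`.
#' @seealso [default_scheme()]
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals))
    stop("bvals and bvecs describe different numbers of volumes")
  if (ncol(bvecs) != 3L) stop("bvecs must have 3 columns")
  dw <- bvals > 0
  if (sum(dw) < 6L)
    stop("need at least 6 diffusion-weighted directions")
  if (sum(!dw) < 1L)
    stop("need at least one baseline (b = 0) volume")
  nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("diffusion-weighted directions must be unit vectors (within 1e-6)")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("Gradient scheme: %d volumes (%d baseline, %d diffusion-weighted; b = %s s/mm^2)\n",
              length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = ", ")))
  invisible(x)
}

#' Default single-shell acquisition scheme
#'
#' One baseline (b = 0) followed by 15 diffusion-weighted volumes at
#' b = 800 s/mm^2 along a fixed electrostatic-repulsion direction set.
#'
#' @param b Diffusion weighting in s/mm^2 for the non-baseline volumes.
#' @return A [gradient_scheme()].
#' @export
default_scheme <- function(b = 800) {
  gradient_scheme(c(0, rep(b, 15L)), rbind(c(0, 0, 0), .DIRECTIONS15))
}

#' Specification of a curved-tube diffusion phantom
#'
#' Describes a tube of anisotropic tensors following a centerline through an
#' otherwise isotropic volume, plus an optional group effect: an additive
#' increase of the two minor eigenvalues (raising RD, lowering FA, leaving AD
#' unchanged) confined to an arc-length segment of the tube.
#'
#' @param grid_shape Integer 3-vector, voxels per axis.
#' @param voxel_size Voxel edge length(s) in mm (scalar or length 3).
#' @param centerline Matrix of 3D points (mm) tracing the tube axis, or one
#'   of the builders [centerline_straight()], [centerline_arc()].
#' @param tube_radius Tube radius in mm.
#' @param inside_eigenvalues Sorted tensor eigenvalues (lambda1 >= lambda2 >=
#'   lambda3 > 0) inside the tube, mm^2/s.
#' @param outside_eigenvalue Isotropic diffusivity outside the tube, mm^2/s.
#' @param effect_segment Arc-length fraction interval `c(s_lo, s_hi)` within
#'   `[0, 1]` where the group effect applies.
#' @param effect_delta Additive change to (lambda2, lambda3) inside the
#'   segment for affected subjects, mm^2/s.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 10L, 10L),
                         voxel_size = 2,
                         centerline = centerline_arc(grid_shape, voxel_size),
                         tube_radius = 3,
                         inside_eigenvalues = c(1.5e-3, 0.3e-3, 0.3e-3),
                         outside_eigenvalue = 0.7e-3,
                         effect_segment = c(11 / 29, 17 / 29),
                         effect_delta = 1.89e-5) {
  grid_shape <- as.integer(grid_shape)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  centerline <- as.matrix(centerline)
  l <- inside_eigenvalues
  if (!(l[1] >= l[2] && l[2] >= l[3] && l[3] > 0))
    stop("inside_eigenvalues must satisfy lambda1 >= lambda2 >= lambda3 > 0")
  if (outside_eigenvalue <= 0) stop("outside_eigenvalue must be positive")
  if (!(effect_segment[1] >= 0 && effect_segment[1] < effect_segment[2] &&
        effect_segment[2] <= 1))
    stop("effect_segment must satisfy 0 <= s_lo < s_hi <= 1")
  extent <- grid_shape * voxel_size
  for (a in 1:3) {
    if (any(centerline[, a] - tube_radius < 0) ||
        any(centerline[, a] + tube_radius > extent[a]))
      stop("tube exits the grid: enlarge grid_shape or shrink the tube")
  }
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 centerline = centerline, tube_radius = tube_radius,
                 inside_eigenvalues = l,
                 outside_eigenvalue = outside_eigenvalue,
                 effect_segment = effect_segment,
                 effect_delta = effect_delta),
            class = "phantom_spec")
}

#' Straight centerline along the x axis
#'
#' @param grid_shape,voxel_size Grid geometry as in [phantom_spec()].
#' @param margin Distance in mm between the tube caps and the grid faces.
#' @param n Number of polyline points.
#' @return A matrix of 3D points in mm.
#' @export
centerline_straight <- function(grid_shape, voxel_size = 2, margin = 4,
                                n = 100L) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  extent <- grid_shape * voxel_size
  x <- seq(margin, extent[1] - margin, length.out = n)
  cbind(x, rep(extent[2] / 2, n), rep(extent[3] / 2, n))
}

#' Gently curved (arc) centerline in the x-y plane
#'
#' A half sine-wave bow: the tube bends in y while running along x, the kind
#' of smooth curvature FACT follows comfortably (max tangent tilt ~11 deg
#' at the default amplitude).
#'
#' @inheritParams centerline_straight
#' @param amplitude Peak lateral excursion in mm.
#' @return A matrix of 3D points in mm.
#' @export
centerline_arc <- function(grid_shape, voxel_size = 2, margin = 4,
                           amplitude = 2.5, n = 100L) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  extent <- grid_shape * voxel_size
  x <- seq(margin, extent[1] - margin, length.out = n)
  y <- extent[2] / 2 + amplitude * sin(pi * (x - x[1]) / (x[n] - x[1])) -
    amplitude / 2
  cbind(x, y, rep(extent[3] / 2, n))
}

# Nearest point on a polyline for every query point. Returns the distance,
# the arc-length fraction s in [0,1] of the projection, and the local unit
# tangent. Vectorized over query points, looping only over segments.
.project_polyline <- function(pts, line) {
  nseg <- nrow(line) - 1L
  seg <- line[-1L, , drop = FALSE] - line[-nrow(line), , drop = FALSE]
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[nseg + 1L]
  m <- nrow(pts)
  best_d2 <- rep(Inf, m)
  best_s <- numeric(m)
  best_t <- matrix(0, m, 3L)
  for (k in seq_len(nseg)) {
    if (seglen[k] == 0) next
    a <- line[k, ]
    d <- seg[k, ] / seglen[k]
    rel <- sweep(pts, 2L, a)
    t <- pmin(pmax(rel %*% d, 0), seglen[k])
    dx <- rel - tcrossprod(as.vector(t), d)
    d2 <- rowSums(dx^2)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_s[upd] <- (cum[k] + t[upd]) / total
      best_t[upd, ] <- matrix(d, sum(upd), 3L, byrow = TRUE)
    }
  }
  list(dist = sqrt(best_d2), s = best_s, tangent = best_t)
}

# World coordinates of all voxel centers, one row per voxel in array order.
.voxel_centers <- function(grid_shape, voxel_size) {
  g <- expand.grid(i = seq_len(grid_shape[1]), j = seq_len(grid_shape[2]),
                   k = seq_len(grid_shape[3]))
  cbind((g$i - 0.5) * voxel_size[1],
        (g$j - 0.5) * voxel_size[2],
        (g$k - 0.5) * voxel_size[3])
}

#' Build the ground-truth tensor field of a tube phantom
#'
#' Voxels whose centers lie within `tube_radius` of the centerline receive an
#' anisotropic tensor whose principal axis is the local centerline tangent;
#' all other voxels are isotropic. With `effect = TRUE` the two minor
#' eigenvalues are raised by `effect_delta` for voxels whose arc-length
#' position falls inside `effect_segment`.
#'
#' @param spec A [phantom_spec()].
#' @param effect Logical; apply the group effect (patient field)?
#' @return A list with `tensors` (4D array, last dim the 6 unique
#'   coefficients Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `mask` (logical 3D array of
#'   tube voxels), `centerline` (the spec's polyline), `arc_pos` (3D array of
#'   arc fractions, NA outside the tube) and `voxel_size`.
#' @export
make_phantom <- function(spec, effect = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  vs <- spec$voxel_size
  nvox <- prod(gs)
  centers <- .voxel_centers(gs, vs)
  pr <- .project_polyline(centers, spec$centerline)
  inside <- pr$dist <= spec$tube_radius

  l <- spec$inside_eigenvalues
  if (effect) {
    in_seg <- inside & pr$s >= spec$effect_segment[1] &
      pr$s <= spec$effect_segment[2]
    if (l[2] + spec$effect_delta > l[1])
      stop("effect_delta drives lambda2 above lambda1")
  } else {
    in_seg <- rep(FALSE, nvox)
  }

  D <- matrix(0, nvox, 6L)
  iso <- spec$outside_eigenvalue
  D[!inside, 1:3] <- iso
  if (any(inside)) {
    t1 <- pr$tangent[inside, , drop = FALSE]
    # complete an orthonormal frame around the tangent
    ref <- matrix(rep(c(0, 0, 1), each = sum(inside)), ncol = 3L)
    near_z <- abs(t1[, 3]) > 0.9
    ref[near_z, ] <- matrix(rep(c(0, 1, 0), each = sum(near_z)), ncol = 3L)
    u <- cbind(t1[, 2] * ref[, 3] - t1[, 3] * ref[, 2],
               t1[, 3] * ref[, 1] - t1[, 1] * ref[, 3],
               t1[, 1] * ref[, 2] - t1[, 2] * ref[, 1])
    u <- u / sqrt(rowSums(u^2))
    v <- cbind(t1[, 2] * u[, 3] - t1[, 3] * u[, 2],
               t1[, 3] * u[, 1] - t1[, 1] * u[, 3],
               t1[, 1] * u[, 2] - t1[, 2] * u[, 1])
    l2 <- rep(l[2], sum(inside))
    l3 <- rep(l[3], sum(inside))
    seg_in <- in_seg[inside]
    l2[seg_in] <- l2[seg_in] + spec$effect_delta
    l3[seg_in] <- l3[seg_in] + spec$effect_delta
    Din <- matrix(0, sum(inside), 6L)
    for (comp in list(c(1L, 1L, 1L), c(2L, 2L, 2L), c(3L, 3L, 3L),
                      c(4L, 1L, 2L), c(5L, 1L, 3L), c(6L, 2L, 3L))) {
      a <- comp[2]; b <- comp[3]
      Din[, comp[1]] <- l[1] * t1[, a] * t1[, b] + l2 * u[, a] * u[, b] +
        l3 * v[, a] * v[, b]
    }
    D[inside, ] <- Din
  }

  arc <- rep(NA_real_, nvox)
  arc[inside] <- pr$s[inside]
  list(tensors = array(D, c(gs, 6L)),
       mask = array(inside, gs),
       centerline = spec$centerline,
       arc_pos = array(arc, gs),
       voxel_size = vs)
}

#' Simulate a diffusion-weighted acquisition of a tensor field
#'
#' Applies the monoexponential tensor signal model
#' `S = s0 * exp(-b * g' D g)` volume by volume, then (optionally) Rician
#' noise: `sqrt((S + e1)^2 + e2^2)` with independent Gaussian `e1`, `e2`.
#'
#' @param tensors 4D tensor coefficient array as from [make_phantom()], or
#'   the list returned by it.
#' @param scheme A [gradient_scheme()].
#' @param s0 Baseline (b = 0) signal, arbitrary units.
#' @param noise_sigma Rician sigma in the same units as `s0` (0 disables
#'   noise).
#' @param seed Optional integer seed making the noise reproducible.
#' @return 4D array (x, y, z, volume) of signal.
#' @export
simulate_dwi <- function(tensors, scheme, s0 = 1000, noise_sigma = 0,
                         seed = NULL) {
  if (is.list(tensors)) tensors <- tensors$tensors
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (s0 < 0) stop("s0 must be nonnegative")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  dims <- dim(tensors)
  if (length(dims) != 4L || dims[4] != 6L)
    stop("tensors must be a 4D array with 6 coefficient planes")
  nvox <- prod(dims[1:3])
  Dmat <- matrix(tensors, nvox, 6L)
  B <- .bmatrix(scheme)                    # nvol x 6
  S <- s0 * exp(-tcrossprod(Dmat, B))      # nvox x nvol
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(S)
    S <- sqrt((S + rnorm(n, 0, noise_sigma))^2 + rnorm(n, 0, noise_sigma)^2)
  }
  array(S, c(dims[1:3], length(scheme$bvals)))
}

# b-matrix rows b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)
.bmatrix <- function(scheme) {
  g <- scheme$bvecs
  scheme$bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                       2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                       2 * g[, 2] * g[, 3])
}

#' Specification of a simulated two-group cohort
#'
#' Group sizes, covariate distributions and clinical-score couplings default
#' to the demographics of the schizophrenia study the pipeline emulates:
#' 31 controls and 33 patients; age 35.4 (8.82) / 39.4 (8.82) years; years of
#' education 13.9 (2.50) / 11.6 (2.40); illness duration 12.7 (8.99) years in
#' patients and 0 in controls; PANSS positive 10.1 (3.28), negative
#' 8.7 (2.68), general 19.9 (4.17); GAF 53.6 (17.5).
#'
#' @param n_control,n_patient Subjects per group (each >= 2).
#' @param covariates Named list of `c(mean, sd)` pairs per group; see
#'   defaults.
#' @param panss_coupling Target correlation (in `[-1, 1]`) between the
#'   measured smoothed FA at the effect-locus profile point and the PANSS
#'   total score in patients; 0 decouples them.
#' @param noise_sigma Rician sigma as a fraction of the baseline signal s0.
#' @param seed Integer seed for all randomness in [make_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 31L, n_patient = 33L,
                        covariates = list(
                          age_control = c(35.4, 8.82),
                          age_patient = c(39.4, 8.82),
                          education_control = c(13.9, 2.50),
                          education_patient = c(11.6, 2.40),
                          duration_patient = c(12.7, 8.99),
                          panss_positive = c(10.1, 3.28),
                          panss_negative = c(8.7, 2.68),
                          panss_general = c(19.9, 4.17),
                          gaf = c(53.6, 17.5)),
                        panss_coupling = 0,
                        noise_sigma = 0.03,
                        seed = 1L) {
  if (n_control < 2L || n_patient < 2L)
    stop("need at least 2 subjects per group")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (abs(panss_coupling) > 1)
    stop("panss_coupling is a correlation and must lie in [-1, 1]")
  structure(list(n_control = as.integer(n_control),
                 n_patient = as.integer(n_patient),
                 covariates = covariates,
                 panss_coupling = panss_coupling,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a multi-subject DWI cohort with a localized group effect
#'
#' Controls are imaged from the unmodified phantom tensor field; patients
#' from the field with (lambda2, lambda3) raised by `effect_delta` inside
#' `effect_segment` (RD up, FA down, AD unchanged there). Each subject gets
#' an independent Rician-noise acquisition, a tensor fit, FA/RD/AD maps, and
#' 30-point profiles along the ground-truth centerline. PANSS total is
#' coupled to the subject's measured smoothed FA at the effect-locus profile
#' point with correlation `panss_coupling`.
#'
#' @param phantom A [phantom_spec()].
#' @param cohort A [cohort_spec()].
#' @param scheme A [gradient_scheme()].
#' @param s0 Baseline signal.
#' @param keep_dwi Keep every subject's raw 4D DWI array (memory permitting)?
#' @return An object of class `cohort` with elements `subjects` (data frame
#'   of covariates and scores), `maps` (per-subject list of FA/RD/AD arrays),
#'   `mean_dwi` (cohort-average 4D DWI for tract reconstruction), `truth`
#'   (ground-truth curve, per-point arc fractions, affected point indices and
#'   locus index), `scheme`, `phantom`, and optionally `dwi`.
#' @export
make_cohort <- function(phantom, cohort, scheme = default_scheme(),
                        s0 = 1000, keep_dwi = FALSE) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(cohort, "cohort_spec"))
  set.seed(cohort$seed)
  nC <- cohort$n_control
  nP <- cohort$n_patient
  n <- nC + nP
  group <- c(rep("control", nC), rep("patient", nP))

  cv <- cohort$covariates
  draw <- function(ms, k) rnorm(k, ms[1], ms[2])
  age <- c(draw(cv$age_control, nC), draw(cv$age_patient, nP))
  education <- pmax(0, c(draw(cv$education_control, nC),
                         draw(cv$education_patient, nP)))
  duration <- c(rep(0, nC), pmax(0, draw(cv$duration_patient, nP)))

  fields <- list(control = make_phantom(phantom, effect = FALSE),
                 patient = make_phantom(phantom, effect = TRUE))

  curve <- resample_arclength(phantom$centerline, 30L)
  s_pts <- seq(0, 1, length.out = 30L)
  affected <- which(s_pts >= phantom$effect_segment[1] &
                    s_pts <= phantom$effect_segment[2])
  locus <- affected[ceiling(length(affected) / 2)]
  if (length(affected) == 0L) locus <- 15L

  sigma_abs <- cohort$noise_sigma * s0
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  maps <- vector("list", n)
  dwis <- if (keep_dwi) vector("list", n) else NULL
  mean_dwi <- NULL
  fa_locus <- numeric(n)
  prof <- list(fa = matrix(NA_real_, n, 30L),
               rd = matrix(NA_real_, n, 30L),
               ad = matrix(NA_real_, n, 30L))
  for (i in seq_len(n)) {
    fld <- fields[[group[i]]]
    dwi <- simulate_dwi(fld$tensors, scheme, s0 = s0,
                        noise_sigma = sigma_abs, seed = subj_seeds[i])
    fit <- fit_tensor(dwi, scheme)
    sm <- scalar_maps(fit)
    maps[[i]] <- sm
    for (m in c("fa", "rd", "ad"))
      prof[[m]][i, ] <- extract_profile(sm[[m]], curve, phantom$voxel_size)
    fa_locus[i] <- smooth_profile(prof$fa[i, ])[locus]
    if (keep_dwi) dwis[[i]] <- dwi
    mean_dwi <- if (is.null(mean_dwi)) dwi / n else mean_dwi + dwi / n
  }

  pat <- group == "patient"
  gen_score <- function(ms, couple_rho = 0) {
    sc <- rep(NA_real_, n)
    if (couple_rho != 0) {
      z <- scale(fa_locus[pat])[, 1]
      eps <- rnorm(nP)
      sc[pat] <- ms[1] + ms[2] * (couple_rho * z +
                                  sqrt(1 - couple_rho^2) * eps)
    } else {
      sc[pat] <- draw(ms, nP)
    }
    sc
  }
  panss_positive <- gen_score(cv$panss_positive)
  panss_negative <- gen_score(cv$panss_negative)
  panss_general <- gen_score(cv$panss_general)
  tot_ms <- c(cv$panss_positive[1] + cv$panss_negative[1] + cv$panss_general[1],
              sqrt(cv$panss_positive[2]^2 + cv$panss_negative[2]^2 +
                   cv$panss_general[2]^2))
  panss_total <- gen_score(tot_ms, cohort$panss_coupling)
  gaf <- gen_score(cv$gaf)

  subjects <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    group = group,
    age = age,
    education = education,
    duration = duration,
    panss_positive = panss_positive,
    panss_negative = panss_negative,
    panss_general = panss_general,
    panss_total = panss_total,
    gaf = gaf,
    stringsAsFactors = FALSE)

  structure(list(subjects = subjects,
                 maps = maps,
                 mean_dwi = mean_dwi,
                 profiles_truth = prof,
                 truth = list(curve = curve, arc = s_pts,
                              affected_points = affected,
                              locus_index = locus,
                              effect_delta = phantom$effect_delta,
                              mask = fields$control$mask),
                 scheme = scheme,
                 phantom = phantom,
                 s0 = s0,
                 dwi = dwis),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tb <- table(x$subjects$group)
  cat(sprintf("Simulated cohort: %d controls, %d patients; grid %s\n",
              tb[["control"]], tb[["patient"]],
              paste(x$phantom$grid_shape, collapse = "x")))
  invisible(x)
}
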