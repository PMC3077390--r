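# Shared phantom builders for the tests: all fixtures are generated in code.

# Straight tube along x on the default small grid.
straight_spec <- function(grid = c(24L, 10L, 10L), vs = 2) {
  phantom_spec(grid_shape = grid, voxel_size = vs,
               centerline = centerline_straight(grid, vs))
}

# Two orthogonal straight tubes crossing at 90 degrees in one plane.
# Voxels in the overlap keep tube A's tensor, so any streamline changing
# tubes would have to turn ~90 degrees.
crossing_fields <- function(vs = 2) {
  grid <- c(16L, 16L, 8L)
  extent <- grid * vs
  n <- 60L
  clA <- cbind(seq(4, extent[1] - 4, length.out = n),
               rep(extent[2] / 2, n), rep(extent[3] / 2, n))
  clB <- cbind(rep(extent[1] / 2, n),
               seq(4, extent[2] - 4, length.out = n), rep(extent[3] / 2, n))
  spA <- phantom_spec(grid, vs, clA, tube_radius = 3)
  spB <- phantom_spec(grid, vs, clB, tube_radius = 3)
  phA <- make_phantom(spA)
  phB <- make_phantom(spB)
  tens <- phB$tensors
  idxA <- which(phA$mask)
  for (c6 in 1:6) {
    plane <- (c6 - 1L) * prod(grid)
    tens[plane + idxA] <- phA$tensors[plane + idxA]
  }
  mask <- phA$mask | phB$mask
  sm <- scalar_maps(tens)
  e1 <- principal_directions(tens, mask = mask)
  list(fa = sm$fa, e1 = e1, voxel_size = rep(vs, 3L), grid = grid,
       maskA = phA$mask, maskB = phB$mask)
}

# Noise-free straight-tube FA map + principal directions, shared by several
# tracking tests.
straight_fields <- function(grid = c(24L, 10L, 10L), vs = 2) {
  sp <- straight_spec(grid, vs)
  ph <- make_phantom(sp)
  sm <- scalar_maps(ph)
  e1 <- principal_directions(ph, mask = ph$mask)
  list(spec = sp, phantom = ph, fa = sm$fa, e1 = e1,
       voxel_size = rep(vs, 3L), grid = grid)
}

# Ground-truth centerline extended by the tube radius along the end
# tangents: the voxelized tube (with its spherical caps) reaches one radius
# beyond the parametric centerline, and tracked streamlines legitimately
# run to the voxelized end. Projecting onto the extended line measures
# lateral fidelity rather than cap overshoot.
extended_centerline <- function(cl, radius = 3) {
  t1 <- cl[1, ] - cl[2, ]
  t1 <- t1 / sqrt(sum(t1^2))
  tn <- cl[nrow(cl), ] - cl[nrow(cl) - 1, ]
  tn <- tn / sqrt(sum(tn^2))
  rbind(cl[1, ] + radius * t1, cl, cl[nrow(cl), ] + radius * tn)
}

# Maximum turning angle (degrees) along a polyline.
max_turning_angle <- function(pts) {
  if (nrow(pts) < 3L) return(0)
  d <- diff(pts)
  d <- d / sqrt(rowSums(d^2))
  dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1L, , drop = FALSE])
  max(acos(pmin(pmax(dots, -1), 1))) * 180 / pi
}
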