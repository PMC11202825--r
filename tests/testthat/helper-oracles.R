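# Independent oracles and small programmatic fixtures. These deliberately
# re-derive quantities by brute force or direct counting, independent of the
# package code paths they are used to check.

# AUC by exhaustive pair counting (ties count 1/2).
auc_bruteforce <- function(cases, controls) {
  mean(outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b)))
}

# A straight vertical tube of constant radius rasterized directly from the
# circle equation (dural label only).
make_tube_labels <- function(r = 8, center = c(20.3, 20.3),
                             dims = c(40L, 40L, 130L), spacing = 1) {
  xs <- (seq_len(dims[1]) - 0.5) * spacing
  ys <- (seq_len(dims[2]) - 0.5) * spacing
  circ <- outer((xs - center[1])^2, (ys - center[2])^2, `+`) <= r^2
  g <- array(0L, dims)
  for (k in seq_len(dims[3])) g[, , k][circ] <- 10L
  label_volume(g, spacing = spacing)
}

# Elliptic cylinder (AP semi-axis a along y, lateral semi-axis b along x),
# rasterized directly; labelled as L3 (id 1).
make_ellipse_labels <- function(a_ap = 9, b_lat = 12, center = c(20.3, 20.3),
                                dims = c(40L, 40L, 20L), spacing = 1) {
  xs <- (seq_len(dims[1]) - 0.5) * spacing
  ys <- (seq_len(dims[2]) - 0.5) * spacing
  ell <- outer(((xs - center[1]) / b_lat)^2,
               ((ys - center[2]) / a_ap)^2, `+`) <= 1
  g <- array(0L, dims)
  for (k in seq_len(dims[3])) g[, , k][ell] <- 1L
  label_volume(g, spacing = spacing)
}

# Fine-grid volume oracle (mL): voxel centres at spacing `h` inside the
# constant-radius tube and between two planes (signed distance to the upper
# plane <= 0, to the lower plane > 0). Chunked over z to bound memory.
tube_segment_fine_oracle <- function(r, center, xy_max, z_max, upper, lower,
                                     h = 0.25) {
  xs <- seq(h / 2, xy_max, by = h)
  ys <- xs
  circ <- which(outer((xs - center[1])^2, (ys - center[2])^2, `+`) <= r^2,
                arr.ind = TRUE)
  cx <- xs[circ[, 1]]
  cy <- ys[circ[, 2]]
  zs <- seq(h / 2, z_max, by = h)
  total <- 0
  for (z in zs) {
    pts <- cbind(cx, cy, z)
    su <- plane_signed_distance(upper, pts)
    sl <- plane_signed_distance(lower, pts)
    total <- total + sum(su <= 0 & sl > 0)
  }
  total * h^3 / 1000
}

# Phantom spec with straight constant-radius tube and 30 mm level spacing,
# for closed-form segment checks (pi r^2 L).
straight_tube_spec <- function(r = 8, concavity = 0) {
  v <- data.frame(
    level = c("L3", "L4", "L5", "S1"),
    center_x = 48.2, center_y = 58.3,
    center_z = c(133, 103, 73, 43),
    height = 22, ap_semi = c(15.7, 15.7, 14.7, 12.2), lat_semi = 23.2,
    concavity = concavity, scallop = 0)
  phantom_spec(
    vertebrae = v, disc_gap = 8,
    dural_centerline = data.frame(z = c(0, 160), y = c(26.3, 26.3)),
    dural_radius = data.frame(z = c(0, 160), r = r),
    noise_sigma = 0)
}
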