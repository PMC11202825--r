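# Synthetic lumbosacral phantom: analytic vertebral bodies (elliptic
# cylinders with concave lateral surfaces, and an optionally scalloped S1)
# and a curved, conically tapering dural tube, rasterized onto an isotropic
# voxel grid with analytically known volumes, diameters and disc planes.
#
# Axis convention (right-handed): x = left->right, y = posterior->anterior,
# z = caudal->cranial; anteroposterior (AP) measurements run along +y.
# A voxel belongs to a structure iff its centre lies inside the analytic
# surface, which makes voxel-count volumetry convergent with resolution.

.default_label_map <- c(L3 = 1L, L4 = 2L, L5 = 3L, S1 = 4L, dural_sac = 10L)

#' Construct a label volume
#'
#' A 3D integer grid with voxel spacing (mm), an axis-orientation tag and a
#' label map. Voxel indexing is 0-based with the centre of voxel (0,0,0) at
#' `spacing/2`.
#'
#' @param grid 3D integer array (0 = background).
#' @param spacing Voxel spacing in mm, length 1 (isotropic) or 3.
#' @param orientation Axis convention tag; the package convention is
#'   `"RAS"` (x left->right, y posterior->anterior, z caudal->cranial).
#' @param labels Named integer label map.
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(grid, spacing = c(1, 1, 1), orientation = "RAS",
                         labels = .default_label_map) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(dim(grid)) == 3, all(spacing > 0), length(spacing) == 3)
  if (!is.integer(grid)) {
    if (any(grid != round(grid))) stop("label grid must hold integer values")
    grid <- array(as.integer(grid), dim(grid))
  }
  present <- setdiff(unique(as.vector(grid)), 0L)
  if (length(setdiff(present, labels)))
    stop("grid contains label ids not in the declared label map")
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 orientation = orientation, labels = labels),
            class = "label_volume")
}

#' Construct an intensity volume
#'
#' @param grid 3D non-negative finite numeric array.
#' @inheritParams label_volume
#' @return Object of class `intensity_volume`.
#' @export
intensity_volume <- function(grid, spacing = c(1, 1, 1), orientation = "RAS") {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(dim(grid)) == 3, all(spacing > 0))
  if (!all(is.finite(grid)) || any(grid < 0))
    stop("intensity values must be finite and non-negative")
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 orientation = orientation),
            class = "intensity_volume")
}

.default_vertebrae <- function() {
  data.frame(
    level     = c("L3", "L4", "L5", "S1"),
    center_x  = 48.2, center_y = 58.3,
    center_z  = c(132, 96, 60, 24),
    height    = 28,
    ap_semi   = c(15.7, 15.7, 14.7, 12.2),  # AP semi-axis (mm)
    lat_semi  = 23.2,                        # lateral semi-axis (mm)
    concavity = 3,                           # lateral waist depth (mm)
    scallop   = c(0, 0, 0, 2.5)              # mid-body AP recession (mm)
  )
}

#' Phantom geometry specification
#'
#' Defaults describe an adult-sized lumbosacral segment on an isotropic 1 mm
#' grid: four vertebral bodies L3-S1 (height 28 mm, disc gap 8 mm, AP
#' diameters 29-31 mm with a scalloped S1), and a dural tube whose sagittal
#' centerline bows ventrally over the lumbar levels, with radius tapering
#' from 8.2 mm cranially to 5 mm at the caudal end. Structure centres sit at
#' generic (off-lattice) positions, as anatomy does. An `ectasia_factor`
#' > 1 widens the tube caudal of the L5/S1 disc (blended over
#' `ectasia_ramp` mm) to emulate dural ectasia.
#'
#' @param voxel_spacing Isotropic voxel spacing in mm (default 1).
#' @param grid_shape Grid size in voxels, c(nx, ny, nz).
#' @param vertebrae Data frame with one row per vertebra: `level`,
#'   `center_x/y/z` (mm), `height`, `ap_semi`, `lat_semi`, `concavity`,
#'   `scallop`.
#' @param disc_gap Intervertebral disc space height (mm).
#' @param dural_center_x Sagittal plane of the dural centerline (mm).
#' @param dural_centerline Data frame `z`, `y`: control points of the
#'   sagittal centerline curve (natural spline interpolation).
#' @param dural_radius Data frame `z`, `r`: piecewise-linear radius profile
#'   (mm).
#' @param ectasia_factor Radius multiplier (>= 1) applied caudal of the
#'   L5/S1 disc.
#' @param ectasia_ramp Blend length of the ectasia transition (mm).
#' @param noise_sigma Rician noise sigma for the intensity image (default
#'   5% of the dural signal).
#' @param signal Named base signals for `background`, `bone`, `dural`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_spacing = 1,
                         grid_shape = c(96L, 96L, 160L),
                         vertebrae = .default_vertebrae(),
                         disc_gap = 8,
                         dural_center_x = 48.2,
                         dural_centerline = data.frame(
                           z = c(0, 42, 100, 160),
                           y = c(26.3, 29.3, 32.3, 28.3)),
                         dural_radius = data.frame(
                           z = c(0, 42, 160), r = c(5, 7, 8.2)),
                         ectasia_factor = 1,
                         ectasia_ramp = 12,
                         noise_sigma = 5,
                         signal = c(background = 5, bone = 60, dural = 100)) {
  stopifnot(voxel_spacing > 0, length(grid_shape) == 3, all(grid_shape > 0),
            ectasia_factor >= 1, ectasia_ramp > 0, noise_sigma >= 0,
            disc_gap > 0)
  geom_cols <- c("height", "ap_semi", "lat_semi")
  if (any(vertebrae[, geom_cols] <= 0) || any(vertebrae$concavity < 0) ||
      any(vertebrae$scallop < 0))
    stop("vertebral geometric extents must be positive")
  if (any(dural_radius$r <= 0)) stop("dural radii must be positive")
  structure(list(voxel_spacing = voxel_spacing,
                 grid_shape = as.integer(grid_shape),
                 vertebrae = vertebrae[order(-vertebrae$center_z), ],
                 disc_gap = disc_gap,
                 dural_center_x = dural_center_x,
                 dural_centerline = dural_centerline,
                 dural_radius = dural_radius,
                 ectasia_factor = ectasia_factor,
                 ectasia_ramp = ectasia_ramp,
                 noise_sigma = noise_sigma,
                 signal = signal),
            class = "phantom_spec")
}

# Centerline y(z), radius r(z) (with ectasia applied), and the z of the
# L5/S1 disc mid-plane.
.dural_geometry <- function(spec) {
  yc <- stats::splinefun(spec$dural_centerline$z, spec$dural_centerline$y,
                         method = "natural")
  rbase <- stats::approxfun(spec$dural_radius$z, spec$dural_radius$r,
                            rule = 2)
  v <- spec$vertebrae  # sorted cranial -> caudal
  n <- nrow(v)
  z_ls <- if (n >= 2) {
    lower_face_upper <- v$center_z[n - 1] - v$height[n - 1] / 2
    upper_face_lower <- v$center_z[n] + v$height[n] / 2
    (lower_face_upper + upper_face_lower) / 2
  } else -Inf
  reff <- function(z) {
    f <- 1 + (spec$ectasia_factor - 1) *
      pmin(1, pmax(0, (z_ls - z) / spec$ectasia_ramp))
    rbase(z) * f
  }
  list(yc = yc, reff = reff, z_ls = z_ls)
}

# Disc mid-plane and outer boundary z positions implied by the spec.
.true_plane_z <- function(spec) {
  v <- spec$vertebrae
  tops <- v$center_z + v$height / 2
  bots <- v$center_z - v$height / 2
  n <- nrow(v)
  zs <- c(tops[1] + spec$disc_gap / 2,
          (bots[-n] + tops[-1]) / 2,
          bots[n] - spec$disc_gap / 2)
  names(zs) <- c(paste0("above_", v$level[1]),
                 paste(v$level[-n], v$level[-1], sep = "_"),
                 paste0("below_", v$level[n]))
  zs
}

# Closed-form vertebral body volume (mL): AP semi-axis a(t) = a - s*sin(pi t),
# lateral semi-axis b(t) = b - c*sin(pi t) over relative height t in [0,1].
.vertebra_volume_ml <- function(a, b, h, conc, scallop) {
  (pi * a * b * h - 2 * h * (a * conc + scallop * b) +
     pi * h * scallop * conc / 2) / 1000
}

# High-accuracy 1D quadrature of the tube volume between two horizontal
# planes (mL); exact for the phantom tube, whose axial cross-sections are
# circles of radius reff(z) regardless of centerline curvature.
.tube_volume_ml <- function(reff, z1, z2, n = 20001L) {
  z <- seq(z1, z2, length.out = n)
  f <- pi * reff(z)^2
  sum((f[-1] + f[-n]) / 2) * (z[2] - z[1]) / 1000
}

#' Build a synthetic lumbosacral phantom
#'
#' Rasterizes the analytic geometry of a [phantom_spec] into a ground-truth
#' label volume and a matching intensity image (bright dural sac,
#' intermediate bone, dark background, Rician noise), and returns the
#' analytically known ground truth: per-structure volumes, per-level dural
#' segment volumes and AP diameters, S1 endplate diameters and scalloping,
#' and the true disc mid-planes. Volumes are closed-form for the vertebrae
#' and 1D-quadrature-exact for the tube.
#'
#' @param spec A [phantom_spec].
#' @param seed Integer seed for the intensity noise.
#' @return List of class `dural_phantom` with elements `intensity`
#'   ([intensity_volume]), `labels` ([label_volume]) and `truth` (list).
#' @examples
#' ph <- build_phantom(phantom_spec(noise_sigma = 0), seed = 1)
#' ph$truth$vertebral_volume
#' @export
build_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_spacing
  d <- spec$grid_shape
  ext <- d * h
  v <- spec$vertebrae
  # bounds check: structures inside grid
  if (any(v$center_x - v$lat_semi < 0) || any(v$center_x + v$lat_semi > ext[1]) ||
      any(v$center_y - v$ap_semi < 0) || any(v$center_y + v$ap_semi > ext[2]) ||
      any(v$center_z - v$height / 2 < 0) || any(v$center_z + v$height / 2 > ext[3]))
    stop("structure exceeds grid: vertebral body out of bounds")
  geom <- .dural_geometry(spec)
  zs_all <- (seq_len(d[3]) - 0.5) * h
  rmax <- max(geom$reff(zs_all))
  ymax <- max(geom$yc(zs_all)); ymin <- min(geom$yc(zs_all))
  if (spec$dural_center_x - rmax < 0 || spec$dural_center_x + rmax > ext[1] ||
      ymin - rmax < 0 || ymax + rmax > ext[2])
    stop("structure exceeds grid: dural sac out of bounds")

  xs <- (seq_len(d[1]) - 0.5) * h
  ys <- (seq_len(d[2]) - 0.5) * h
  grid <- array(0L, d)
  lab_ids <- .default_label_map
  for (k in seq_len(d[3])) {
    zc <- zs_all[k]
    sl <- matrix(0L, d[1], d[2])
    for (i in seq_len(nrow(v))) {
      z0 <- v$center_z[i] - v$height[i] / 2
      if (zc < z0 || zc > z0 + v$height[i]) next
      t <- (zc - z0) / v$height[i]
      az <- v$ap_semi[i] - v$scallop[i] * sin(pi * t)
      bz <- v$lat_semi[i] - v$concavity[i] * sin(pi * t)
      m <- outer(((xs - v$center_x[i]) / bz)^2,
                 ((ys - v$center_y[i]) / az)^2, `+`) <= 1
      sl[m] <- lab_ids[[v$level[i]]]
    }
    r <- geom$reff(zc)
    dm <- outer((xs - spec$dural_center_x)^2,
                (ys - geom$yc(zc))^2, `+`) <= r^2
    if (any(sl[dm] != 0L)) stop("dural sac overlaps vertebral body")
    sl[dm] <- lab_ids[["dural_sac"]]
    grid[, , k] <- sl
  }

  labels <- label_volume(grid, spacing = h)

  base <- array(spec$signal[["background"]], d)
  base[grid %in% lab_ids[v$level]] <- spec$signal[["bone"]]
  base[grid == lab_ids[["dural_sac"]]] <- spec$signal[["dural"]]
  sig <- spec$noise_sigma
  img <- if (sig > 0) {
    .with_seed(seed, {
      n1 <- array(rnorm(prod(d), sd = sig), d)
      n2 <- array(rnorm(prod(d), sd = sig), d)
      sqrt((base + n1)^2 + n2^2)
    })
  } else base
  intensity <- intensity_volume(img, spacing = h)

  # ---- analytic ground truth ----
  zpl <- .true_plane_z(spec)
  planes <- lapply(zpl, function(z)
    clip_plane(point = c(spec$dural_center_x, geom$yc(z), z),
               normal = c(0, 0, 1)))
  seg_lv <- v$level
  seg_vol <- vapply(seq_along(seg_lv), function(i)
    .tube_volume_ml(geom$reff, zpl[i + 1], zpl[i]), 0)
  names(seg_vol) <- seg_lv
  mid_z <- vapply(seq_along(seg_lv), function(i) (zpl[i] + zpl[i + 1]) / 2, 0)
  dural_diam <- setNames(2 * geom$reff(mid_z), seg_lv)
  vert_vol <- setNames(.vertebra_volume_ml(v$ap_semi, v$lat_semi, v$height,
                                           v$concavity, v$scallop), v$level)
  vert_diam <- setNames(2 * (v$ap_semi - v$scallop), v$level)
  s1 <- v[v$level == "S1", ]
  truth <- list(
    vertebral_volume = vert_vol,
    dural_volume = seg_vol,
    dural_volume_total = .tube_volume_ml(geom$reff, min(zpl), max(zpl)),
    dural_diameter = dural_diam,
    vertebral_diameter = vert_diam,
    s1_endplate_upper_diameter = if (nrow(s1)) 2 * s1$ap_semi else NA_real_,
    s1_endplate_lower_diameter = if (nrow(s1)) 2 * s1$ap_semi else NA_real_,
    s1_scalloping = if (nrow(s1)) 2 * s1$scallop else NA_real_,
    planes = planes
  )
  structure(list(intensity = intensity, labels = labels, truth = truth,
                 spec = spec, seed = seed),
            class = "dural_phantom")
}

#' Perturb label boundaries with spatially smooth noise
#'
#' Displaces each structure's surface by a smooth zero-mean random field
#' with standard deviation `boundary_noise_mm`, emulating the segmentation
#' imperfections that motivate manual correction in practice. Structures
#' are processed in label order and remain mutually exclusive; the caller's
#' RNG state is untouched.
#'
#' @param labels A [label_volume].
#' @param boundary_noise_mm Boundary displacement SD in mm (>= 0; 0 returns
#'   the input unchanged).
#' @param seed Integer seed.
#' @return A perturbed [label_volume].
#' @export
perturb_labels <- function(labels, boundary_noise_mm, seed) {
  stopifnot(inherits(labels, "label_volume"), boundary_noise_mm >= 0)
  if (boundary_noise_mm == 0) return(labels)
  h <- mean(labels$spacing)
  K <- max(1L, min(4L, as.integer(ceiling(2 * boundary_noise_mm / h))))
  ids <- sort(setdiff(unique(as.vector(labels$grid)), 0L))
  d <- dim(labels$grid)
  out <- array(0L, d)
  .with_seed(seed, {
    for (id in ids) {
      mask <- labels$grid == id
      ai <- arrayInd(which(mask), d)
      lo <- pmax(apply(ai, 2, min) - (K + 2L), 1L)
      hi <- pmin(apply(ai, 2, max) + (K + 2L), d)
      sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      steps <- .signed_shells(sub, K)
      d_mm <- sign(steps) * (abs(steps) - 0.5) * h
      field <- .smooth_noise_field(dim(sub), boundary_noise_mm)
      dest <- out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      take <- (d_mm > field) & dest == 0L
      dest[take] <- id
      out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- dest
    }
  })
  labels$grid <- out
  labels
}

#' Threshold-based phantom segmenter
#'
#' A plumbing-level stand-in for a full segmentation algorithm, sufficient
#' to exercise the measurement pipeline on phantom images: per structure,
#' intensity thresholding, largest connected components (6-connectivity)
#' and hole filling. `"dural_sac"` takes the single largest component
#' (label 10); `"vertebrae"` takes the four largest, assigned L3..S1 from
#' cranial to caudal (labels 1-4).
#'
#' @param intensity An [intensity_volume].
#' @param thresholds Named list of `c(low, high)` intensity bounds for
#'   `"dural_sac"` and/or `"vertebrae"`; defaults match the phantom's
#'   signal model.
#' @return A [label_volume].
#' @export
simple_segment <- function(intensity,
                           thresholds = list(dural_sac = c(82, Inf),
                                             vertebrae = c(35, 80))) {
  stopifnot(inherits(intensity, "intensity_volume"))
  unknown <- setdiff(names(thresholds), c("dural_sac", "vertebrae"))
  if (length(unknown)) stop("unknown structure: ", paste(unknown, collapse = ", "))
  for (nm in names(thresholds))
    if (!(length(thresholds[[nm]]) == 2 &&
          thresholds[[nm]][1] < thresholds[[nm]][2]))
      stop("thresholds must be ordered c(low, high)")
  g <- intensity$grid
  out <- array(0L, dim(g))
  if ("dural_sac" %in% names(thresholds)) {
    th <- thresholds$dural_sac
    m <- g >= th[1] & g <= th[2]
    if (!any(m)) stop("empty component: dural_sac")
    comp <- .components3d(m)
    best <- which.max(tabulate(comp))
    out[.fill_holes3d(comp == best)] <- 10L
  }
  if ("vertebrae" %in% names(thresholds)) {
    th <- thresholds$vertebrae
    m <- g >= th[1] & g <= th[2]
    m[out > 0L] <- FALSE
    if (!any(m)) stop("empty component: vertebrae")
    comp <- .components3d(m)
    sizes <- tabulate(comp)
    if (sum(sizes > 0) < 4)
      stop("empty component: expected 4 vertebral bodies, found ",
           sum(sizes > 0))
    top4 <- order(sizes, decreasing = TRUE)[1:4]
    zc <- vapply(top4, function(ci)
      mean(arrayInd(which(comp == ci), dim(comp))[, 3]), 0)
    for (i in seq_along(top4)) {
      filled <- .fill_holes3d(comp == top4[order(-zc)][i])
      filled[out > 0L] <- FALSE
      out[filled] <- i
    }
  }
  label_volume(out, spacing = intensity$spacing,
               orientation = intensity$orientation)
}
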