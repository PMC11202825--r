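# Clipping planes through the intervertebral disc spaces, and partition of
# the dural sac into level segments L3-S1.

#' Construct an oriented clipping plane
#'
#' @param point A point on the plane (mm, length 3).
#' @param normal Plane normal; rescaled to unit length, must have a positive
#'   z component (planes are oriented cranially).
#' @return Object of class `clip_plane`.
#' @export
clip_plane <- function(point, normal) {
  stopifnot(length(point) == 3, length(normal) == 3)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("normal must be non-zero")
  normal <- normal / nn
  if (normal[3] <= 0) stop("plane normal must point cranially (positive z)")
  structure(list(point = as.numeric(point), normal = as.numeric(normal)),
            class = "clip_plane")
}

#' Signed distance from points to a clipping plane
#'
#' Positive on the cranial side (the side the unit normal points to).
#'
#' @param plane A [clip_plane].
#' @param coords Numeric matrix of points (n x 3, mm).
#' @return Numeric vector of signed distances (mm).
#' @export
plane_signed_distance <- function(plane, coords) {
  stopifnot(inherits(plane, "clip_plane"))
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  drop(coords %*% plane$normal) - sum(plane$point * plane$normal)
}

# Per-vertebra summary used for plane fitting: voxel centroid, cranially
# oriented principal axis, and the centroids of the outermost `slab_mm`
# slabs along that axis (the endplate slabs).
.vertebra_axis <- function(labels, id, slab_mm = 2) {
  idx <- which(labels$grid == id)
  if (!length(idx)) return(NULL)
  co <- .voxel_coords(idx, dim(labels$grid), labels$spacing)
  ctr <- colMeans(co)
  pr <- prcomp(co, center = TRUE, scale. = FALSE)
  ax <- pr$rotation[, which.max(abs(pr$rotation[3, ]))]
  if (ax[3] < 0) ax <- -ax
  p <- drop(sweep(co, 2, ctr) %*% ax)
  upper <- colMeans(co[p >= max(p) - slab_mm, , drop = FALSE])
  lower <- colMeans(co[p <= min(p) + slab_mm, , drop = FALSE])
  list(centroid = ctr, axis = ax, upper_ep = upper, lower_ep = lower)
}

#' Fit clipping planes through the intervertebral disc spaces
#'
#' For each adjacent vertebra pair, the plane point is the midpoint between
#' the facing endplate-slab centroids (centroid of each body's extreme 2 mm
#' slab along its principal axis) and the plane normal is the unit vector
#' from the lower to the upper body centroid — a centroid-axis convention
#' that is stable on noisy masks. The outer boundary planes above L3 and
#' below S1 are placed at the outer endplate-slab centroids offset outward
#' by half the estimated disc gap, with the adjacent inter-centroid axis as
#' normal.
#'
#' @param labels A [label_volume] containing all four vertebral bodies
#'   (labels L3, L4, L5, S1).
#' @param slab_mm Endplate slab thickness (default 2 mm).
#' @return Named list of five [clip_plane]s ordered cranial to caudal:
#'   `above_L3`, `L3_L4`, `L4_L5`, `L5_S1`, `below_S1`.
#' @export
fit_clipping_planes <- function(labels, slab_mm = 2) {
  stopifnot(inherits(labels, "label_volume"))
  lvls <- c("L3", "L4", "L5", "S1")
  info <- lapply(lvls, function(lv)
    .vertebra_axis(labels, labels$labels[[lv]], slab_mm))
  missing <- lvls[vapply(info, is.null, TRUE)]
  if (length(missing))
    stop("missing label: ", paste(missing, collapse = ", "))
  names(info) <- lvls
  axes <- lapply(seq_len(3), function(i) {
    ax <- info[[i]]$centroid - info[[i + 1]]$centroid
    ax / sqrt(sum(ax^2))
  })
  gaps <- vapply(seq_len(3), function(i) {
    g <- sum((info[[i]]$lower_ep - info[[i + 1]]$upper_ep) * axes[[i]])
    if (g <= 0) stop("degenerate (overlapping) vertebral masks between ",
                     lvls[i], " and ", lvls[i + 1])
    g
  }, 0)
  gap <- mean(gaps)
  inner <- lapply(seq_len(3), function(i)
    clip_plane(point = (info[[i]]$lower_ep + info[[i + 1]]$upper_ep) / 2,
               normal = axes[[i]]))
  names(inner) <- paste(lvls[-4], lvls[-1], sep = "_")
  above <- clip_plane(point = info$L3$upper_ep + axes[[1]] * gap / 2,
                      normal = axes[[1]])
  below <- clip_plane(point = info$S1$lower_ep - axes[[3]] * gap / 2,
                      normal = axes[[3]])
  c(list(above_L3 = above), inner, list(below_S1 = below))
}

#' Partition the dural sac into level segments
#'
#' Assigns each dural voxel (by its centre coordinate) to the level whose
#' bounding planes enclose it: signed distance to the level's upper plane
#' <= 0 and to its lower plane > 0. The half-open (upper-closed) membership
#' rule guarantees that no voxel is double-counted, so segment volumes sum
#' exactly to the dural volume between the outermost planes. Voxels outside
#' the outermost planes remain unassigned.
#'
#' @param labels A [label_volume] with a dural sac label.
#' @param planes Ordered cranial-to-caudal list of five [clip_plane]s, as
#'   returned by [fit_clipping_planes()].
#' @return Object of class `level_partition`: the planes and, per level
#'   (L3, L4, L5, S1), the linear voxel indices of its segment.
#' @export
partition_dural_sac <- function(labels, planes) {
  stopifnot(inherits(labels, "label_volume"), length(planes) == 5)
  lapply(planes, function(p) stopifnot(inherits(p, "clip_plane")))
  zs <- vapply(planes, function(p) p$point[3], 0)
  if (any(diff(zs) >= 0))
    stop("unordered planes: points must have strictly decreasing z")
  idx <- which(labels$grid == labels$labels[["dural_sac"]])
  if (!length(idx)) stop("missing label: dural_sac")
  co <- .voxel_coords(idx, dim(labels$grid), labels$spacing)
  sd <- vapply(planes, plane_signed_distance, numeric(length(idx)),
               coords = co)
  lvls <- c("L3", "L4", "L5", "S1")
  assigned <- rep(FALSE, length(idx))
  segs <- vector("list", 4)
  names(segs) <- lvls
  for (i in seq_len(4)) {
    sel <- !assigned & sd[, i] <= 0 & sd[, i + 1] > 0
    if (!any(sel))
      stop("planes not intersecting the dural extent at level ", lvls[i])
    segs[[i]] <- idx[sel]
    assigned <- assigned | sel
  }
  structure(list(planes = planes, levels = segs,
                 dim = dim(labels$grid), spacing = labels$spacing),
            class = "level_partition")
}
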