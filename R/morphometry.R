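# Volumes (mL), anteroposterior diameters (mm) and S1 scalloping from label
# volumes and level partitions.

#' Voxel-count volume of a labelled structure
#'
#' @param labels A [label_volume].
#' @param label_id Integer label id.
#' @return Volume in mL: voxel count times voxel volume (mm^3) / 1000.
#' @export
label_volume_ml <- function(labels, label_id) {
  stopifnot(inherits(labels, "label_volume"))
  n <- sum(labels$grid == label_id)
  if (n == 0) stop("absent label: ", label_id)
  n * prod(labels$spacing) / 1000
}

# AP (y) extent of the given voxel-centre coordinates within a one-voxel
# slab at the reference plane and within the midsagittal slab (+/- one
# voxel of the sagittal plane through the structure centroid).
.ap_extent <- function(coords, plane, spacing, sag_x = NULL) {
  half <- sum(abs(plane$normal) * spacing) / 2
  s <- plane_signed_distance(plane, coords)
  sel <- abs(s) <= half
  if (!any(sel)) stop("empty intersection: plane outside structure")
  co <- coords[sel, , drop = FALSE]
  sag_x <- sag_x %||% mean(co[, 1])
  co <- co[abs(co[, 1] - sag_x) <= spacing[1], , drop = FALSE]
  if (!nrow(co)) stop("empty intersection: plane outside structure")
  diff(range(co[, 2])) + spacing[2]
}

#' Anteroposterior diameter of a structure at a reference plane
#'
#' The AP extent of the structure's voxels within a one-voxel slab at the
#' reference plane, restricted to the midsagittal slab (within one voxel of
#' the sagittal plane through the structure centroid) — the mid-level
#' sagittal measurement convention of the dural-ectasia literature.
#'
#' @param labels A [label_volume].
#' @param structure Integer label id.
#' @param reference_plane A [clip_plane] at the measurement level.
#' @return Diameter in mm.
#' @export
ap_diameter <- function(labels, structure, reference_plane) {
  stopifnot(inherits(labels, "label_volume"))
  idx <- which(labels$grid == structure)
  if (!length(idx)) stop("absent label: ", structure)
  co <- .voxel_coords(idx, dim(labels$grid), labels$spacing)
  .ap_extent(co, reference_plane, labels$spacing, sag_x = mean(co[, 1]))
}

#' S1 scalloping
#'
#' Posterior erosion of the S1 vertebral body, quantified as the mean of
#' the upper and lower endplate-level diameters minus the mid-body
#' diameter; positive values indicate scalloping.
#'
#' @param d_mid_s1 Mid-body S1 AP diameter (mm, > 0).
#' @param d_upper_endplate,d_lower_endplate Endplate-level AP diameters
#'   (mm, > 0).
#' @return Scalloping in mm.
#' @examples
#' s1_scalloping(20, 24, 25)  # 4.5
#' @export
s1_scalloping <- function(d_mid_s1, d_upper_endplate, d_lower_endplate) {
  if (any(c(d_mid_s1, d_upper_endplate, d_lower_endplate) <= 0))
    stop("diameters must be > 0")
  (d_upper_endplate + d_lower_endplate) / 2 - d_mid_s1
}

# Mid-plane between a level's bounding planes.
.mid_plane <- function(upper, lower) {
  n <- upper$normal + lower$normal
  clip_plane(point = (upper$point + lower$point) / 2, normal = n)
}

#' Measure all image-derivable quantities
#'
#' Fills the full per-patient measurement row from a label volume and its
#' level partition: dural segment volumes L3-S1, vertebral body volumes
#' L3-L5, dural AP diameters at each level's mid-plane, vertebral AP
#' diameters at each body's centroid (normal to the body's principal
#' axis), S1 endplate diameters (2 mm slabs at the body's cranial and
#' caudal extremes) and S1 scalloping. Demographics are not image-derived
#' and are returned as NA. The function is a pure function of its inputs.
#'
#' @param labels A [label_volume].
#' @param partition A [level_partition] of the same volume.
#' @param patient_id Identifier carried into the output row.
#' @return One-row data frame (a measurement set).
#' @export
measure_all <- function(labels, partition, patient_id = "phantom") {
  stopifnot(inherits(labels, "label_volume"),
            inherits(partition, "level_partition"))
  lvls <- c("L3", "L4", "L5", "S1")
  if (!all(lvls %in% names(partition$levels)) ||
      any(vapply(partition$levels[lvls], length, 0L) == 0))
    stop("partition missing a level")
  sp <- labels$spacing
  vox_ml <- prod(sp) / 1000
  out <- data.frame(patient_id = patient_id)
  for (lv in lvls)
    out[[paste0("dural_volume_", lv)]] <-
      length(partition$levels[[lv]]) * vox_ml
  for (lv in c("L3", "L4", "L5"))
    out[[paste0("vertebral_volume_", lv)]] <-
      label_volume_ml(labels, labels$labels[[lv]])
  # dural diameters at the mid-plane between each level's bounding planes
  for (i in seq_along(lvls)) {
    co <- .voxel_coords(partition$levels[[i]], dim(labels$grid), sp)
    mp <- .mid_plane(partition$planes[[i]], partition$planes[[i + 1]])
    out[[paste0("dural_diameter_", lvls[i])]] <-
      .ap_extent(co, mp, sp, sag_x = mean(co[, 1]))
  }
  # vertebral diameters at the body centroid, normal to the principal axis
  for (lv in lvls) {
    va <- .vertebra_axis(labels, labels$labels[[lv]])
    if (is.null(va)) stop("missing label: ", lv)
    idx <- which(labels$grid == labels$labels[[lv]])
    co <- .voxel_coords(idx, dim(labels$grid), sp)
    pl <- clip_plane(point = va$centroid, normal = va$axis)
    out[[paste0("vertebral_diameter_", lv)]] <-
      .ap_extent(co, pl, sp, sag_x = va$centroid[1])
    if (lv == "S1") {
      p <- drop(sweep(co, 2, va$centroid) %*% va$axis)
      for (side in c("upper", "lower")) {
        slab <- if (side == "upper") p >= max(p) - 2 else p <= min(p) + 2
        cs <- co[slab, , drop = FALSE]
        cs <- cs[abs(cs[, 1] - va$centroid[1]) <= sp[1], , drop = FALSE]
        out[[paste0("s1_endplate_", side, "_diameter")]] <-
          diff(range(cs[, 2])) + sp[2]
      }
    }
  }
  out$s1_scalloping <- s1_scalloping(out$vertebral_diameter_S1,
                                     out$s1_endplate_upper_diameter,
                                     out$s1_endplate_lower_diameter)
  out$height <- NA_real_
  out$weight <- NA_real_
  out
}
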