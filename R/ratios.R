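# Derived indices: dural sac volume ratio (DSVR), dural sac diameter ratio
# (DSDR), S1 scalloping support, Du Bois body surface area and BMI, and
# BMI-corrected measurement columns.

#' Dural sac volume ratio
#'
#' DSVR at a level is the dural sac segment volume divided by the vertebral
#' body volume at that level. At S1 the convention is to divide by the L5
#' vertebral body volume, because the S1 body is not measured volumetrically
#' (see [compute_ratio_table()]).
#'
#' @param dural_volume Dural sac segment volume (mL).
#' @param vertebral_volume Vertebral body volume (mL), must be positive.
#' @return Dimensionless ratio.
#' @examples
#' dsvr(13.3, 33.2)  # ~0.40, an MFS-typical S1 value
#' @export
dsvr <- function(dural_volume, vertebral_volume) {
  if (any(vertebral_volume <= 0)) stop("vertebral_volume must be > 0")
  if (any(dural_volume < 0)) stop("dural_volume must be >= 0")
  dural_volume / vertebral_volume
}

#' Du Bois body surface area
#'
#' BSA = 0.007184 * weight^0.425 * height^0.725 (weight kg, height cm),
#' the Du Bois & Du Bois formula.
#'
#' @param height Height in cm (> 0).
#' @param weight Weight in kg (> 0).
#' @return Body surface area in m^2.
#' @examples
#' du_bois_bsa(182.0, 70.8)  # ~1.91
#' @export
du_bois_bsa <- function(height, weight) {
  if (any(height <= 0) || any(weight <= 0))
    stop("height and weight must be > 0")
  0.007184 * weight^0.425 * height^0.725
}

#' Body mass index
#'
#' @param height Height in cm (> 0).
#' @param weight Weight in kg (> 0).
#' @return BMI in kg/m^2.
#' @export
bmi <- function(height, weight) {
  if (any(height <= 0) || any(weight <= 0))
    stop("height and weight must be > 0")
  weight / (height / 100)^2
}

# Variables reported BMI-corrected (value per kg/m^2 BMI) when present.
.bmi_corrected_vars <- function(nm) {
  grep("^(dural_volume|vertebral_volume|dural_diameter|vertebral_diameter)_|^nerve_root_sleeve_L5$|^s1_scalloping$",
       nm, value = TRUE)
}

#' Compute the ratio table for one or more measurement rows
#'
#' Fills every derived index obtainable from a measurement table:
#' `dsvr_L3..dsvr_S1` (with `dsvr_S1 = dural_volume_S1 / vertebral_volume_L5`
#' — the S1 vertebral body volume is never used, even if a column of that
#' name exists), `dsdr_L1..dsdr_S1` for every level where both diameters are
#' present (the S1 DSDR denominator is the mid-body S1 diameter), and, when
#' height and weight are available, `bmi`, `bsa` and BMI-corrected copies of
#' the measurement columns (suffix `_per_bmi`).
#'
#' @param m Data frame (one row per patient) with measurement columns named
#'   `dural_volume_<level>`, `vertebral_volume_<level>`,
#'   `dural_diameter_<level>`, `vertebral_diameter_<level>`, and optionally
#'   `height`, `weight`.
#' @return Data frame with the derived columns, one row per input row;
#'   `patient_id` and `group` are carried through when present.
#' @export
compute_ratio_table <- function(m) {
  stopifnot(is.data.frame(m))
  out <- m[, intersect(c("patient_id", "group"), names(m)), drop = FALSE]
  for (lv in c("L3", "L4", "L5", "S1")) {
    dc <- paste0("dural_volume_", lv)
    vc <- paste0("vertebral_volume_", if (lv == "S1") "L5" else lv)
    if (dc %in% names(m)) {
      if (!vc %in% names(m)) stop("missing field: ", vc)
      out[[paste0("dsvr_", lv)]] <- dsvr(m[[dc]], m[[vc]])
    }
  }
  for (lv in c("L1", "L2", "L3", "L4", "L5", "S1")) {
    dc <- paste0("dural_diameter_", lv)
    vc <- paste0("vertebral_diameter_", lv)
    if (dc %in% names(m) && vc %in% names(m)) {
      if (any(m[[vc]] <= 0)) stop("non-positive vertebral diameter at ", lv)
      out[[paste0("dsdr_", lv)]] <- m[[dc]] / m[[vc]]
    }
  }
  if (all(c("height", "weight") %in% names(m)) &&
      !anyNA(m$height) && !anyNA(m$weight) && nrow(m) > 0) {
    out$bmi <- bmi(m$height, m$weight)
    out$bsa <- du_bois_bsa(m$height, m$weight)
    for (v in .bmi_corrected_vars(names(m)))
      out[[paste0(v, "_per_bmi")]] <- m[[v]] / out$bmi
  }
  out
}
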