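# NIfTI-1 and CSV/JSON I/O, pipeline configuration and the end-to-end
# driver. Report rounding: ratios and AUCs to 3 decimals, mm/mL to 1
# decimal; internal computation is never rounded.

#' Read a label volume from a NIfTI-1 file
#'
#' @param path Path to a NIfTI file with integer data.
#' @param labels Label map to attach (default the package's lumbosacral
#'   map).
#' @return A [label_volume] with spacing taken from the header.
#' @export
read_label_volume <- function(path, labels = .default_label_map) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) stop("missing or invalid spacing")
  a <- as.array(img)
  if (any(a != round(a))) stop("non-integer data: not a label volume")
  label_volume(array(as.integer(a), dim(a)), spacing = sp, labels = labels)
}

#' Write a label volume to a NIfTI-1 file
#'
#' @param v A [label_volume].
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(v, path) {
  stopifnot(inherits(v, "label_volume"))
  img <- RNifti::asNifti(v$grid)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Write an intensity volume to a NIfTI-1 file
#'
#' @param v An [intensity_volume].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_intensity_volume <- function(v, path) {
  stopifnot(inherits(v, "intensity_volume"))
  img <- RNifti::asNifti(v$grid)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

.round_cols <- function(df, digits3 = "^(ds[vd]r_|auc_|bmi$|bsa$|.*_per_bmi$|sens_|spec_|cutoff_|mcnemar_p$|youden)",
                        digits1 = "^(dural_|vertebral_|s1_|nerve_|height$|weight$)") {
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) next
    if (grepl(digits3, nm)) df[[nm]] <- round(df[[nm]], 3)
    else if (grepl(digits1, nm)) df[[nm]] <- round(df[[nm]], 1)
  }
  df
}

.read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

.stage <- function(name, t0, ...) {
  message(sprintf("[%s] %s (%.1fs)", name, paste0(..., collapse = ""),
                  as.numeric(Sys.time()) - t0))
}

#' Run the measurement / evaluation pipeline
#'
#' Executes the requested stages end to end and writes CSV/JSON reports to
#' `out_dir`. Two stage graphs exist: the image route (phantom ->
#' optional boundary perturbation or threshold segmentation -> clipping
#' planes -> partition -> morphometry -> ratio table) and the cohort route
#' (cohort simulation -> per-level ROC report). Outputs are byte-identical
#' for identical configurations.
#'
#' @param config A list, or path to a JSON/YAML file, with entries:
#'   \describe{
#'     \item{mode}{`"phantom"`, `"cohort"` or `"both"` (default
#'       `"both"`).}
#'     \item{seed}{Integer seed used for every stochastic stage (required).}
#'     \item{out_dir}{Output directory (created if needed).}
#'     \item{phantom}{Optional list: `boundary_noise_mm` (default 0),
#'       `use_segmenter` (default `FALSE`: measure the ground-truth
#'       labels), `ectasia_factor`, `noise_sigma`, `voxel_spacing`.}
#'     \item{cohort}{Optional list: `n_mfs` (default 63), `n_non`
#'       (default 81).}
#'   }
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config) {
  config <- .read_config(config)
  if (is.null(config$seed)) stop("config must set an explicit seed")
  seed <- as.integer(config$seed)
  mode <- config$mode %||% "both"
  stopifnot(mode %in% c("phantom", "cohort", "both"))
  out_dir <- config$out_dir %||% stop("config must set out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  paths <- list()

  if (mode %in% c("phantom", "both")) {
    pc <- config$phantom %||% list()
    sargs <- pc[intersect(names(pc),
                          c("ectasia_factor", "noise_sigma", "voxel_spacing",
                            "grid_shape"))]
    spec <- do.call(phantom_spec, sargs)
    ph <- tryCatch(build_phantom(spec, seed = seed),
                   error = function(e) stop("stage phantom failed: ",
                                            conditionMessage(e)))
    .stage("phantom", t0, "built ", paste(spec$grid_shape, collapse = "x"),
           " grid, seed ", seed)
    labels <- ph$labels
    if (isTRUE(pc$use_segmenter)) {
      labels <- tryCatch(simple_segment(ph$intensity),
                         error = function(e) stop("stage segment failed: ",
                                                  conditionMessage(e)))
      .stage("segment", t0, "threshold segmentation")
    }
    noise <- pc$boundary_noise_mm %||% 0
    if (noise > 0) {
      labels <- perturb_labels(labels, noise, seed = seed)
      .stage("perturb", t0, "boundary noise ", noise, " mm")
    }
    meas <- tryCatch({
      planes <- fit_clipping_planes(labels)
      part <- partition_dural_sac(labels, planes)
      measure_all(labels, part)
    }, error = function(e) stop("stage measure failed: ",
                                conditionMessage(e)))
    .stage("measure", t0, "4 dural segments, 3 vertebral volumes")
    rat <- compute_ratio_table(meas)
    paths$measurements <- file.path(out_dir, "measurements.csv")
    paths$ratios <- file.path(out_dir, "ratios.csv")
    write.csv(.round_cols(meas), paths$measurements, row.names = FALSE)
    write.csv(.round_cols(rat), paths$ratios, row.names = FALSE)
  }

  if (mode %in% c("cohort", "both")) {
    cc <- config$cohort %||% list()
    specs <- default_group_specs()
    coh <- tryCatch(
      sample_cohort(specs$mfs, specs$non_mfs,
                    cc$n_mfs %||% 63, cc$n_non %||% 81, seed = seed),
      error = function(e) stop("stage cohort failed: ", conditionMessage(e)))
    .stage("cohort", t0, nrow(coh), " patients, seed ", seed)
    rep2 <- tryCatch(evaluate_table2(coh),
                     error = function(e) stop("stage evaluate failed: ",
                                              conditionMessage(e)))
    .stage("evaluate", t0, nrow(rep2), " levels")
    paths$cohort <- file.path(out_dir, "cohort.csv")
    paths$table2_csv <- file.path(out_dir, "table2.csv")
    paths$table2_json <- file.path(out_dir, "table2.json")
    write.csv(.round_cols(as.data.frame(coh)), paths$cohort,
              row.names = FALSE)
    rep2r <- .round_cols(as.data.frame(rep2))
    write.csv(rep2r, paths$table2_csv, row.names = FALSE)
    jsonlite::write_json(rep2r, paths$table2_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(paths)
}
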