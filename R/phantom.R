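#' Phantom specification for annular myocardial-like parametric maps
#'
#' Describes a 2D scalar phantom: an annulus ("LV ring") of elevated map
#' values (T1-like, in ms) with spatially correlated texture and white noise,
#' on a low constant background plateau. The annulus stands in for the
#' short-axis left-ventricular myocardium on which texture features are
#' extracted.
#'
#' @param grid_shape integer (rows, cols) of the pixel grid.
#' @param pixel_spacing mm per pixel, (row, col).
#' @param ring_center pixel coordinates (row, col) of the annulus center;
#'   defaults to the grid center.
#' @param ring_radii inner/outer annulus radii in mm (inner < outer).
#' @param base_value mean myocardial map value (map units, e.g. T1 ms).
#' @param texture_amplitude standard deviation (map units) of the smooth
#'   correlated texture field added inside the ROI.
#' @param texture_correlation_length correlation length (mm) of the texture.
#' @param noise_sd standard deviation (map units) of white pixel noise.
#' @param background_value constant plateau outside the annulus (map units).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96),
                         pixel_spacing = c(1, 1),
                         ring_center = NULL,
                         ring_radii = c(inner = 18, outer = 30),
                         base_value = 950,
                         texture_amplitude = 60,
                         texture_correlation_length = 4,
                         noise_sd = 20,
                         background_value = 100) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 8),
            length(pixel_spacing) == 2, all(pixel_spacing > 0),
            length(ring_radii) == 2)
  if (is.null(ring_center)) ring_center <- (grid_shape + 1) / 2
  ri <- unname(ring_radii[1]); ro <- unname(ring_radii[2])
  if (!(ri > 0 && ro > ri)) stop("ring radii must satisfy 0 < inner < outer")
  .assert_scalar_num(texture_amplitude, "texture_amplitude", lower = 0)
  .assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  .assert_scalar_num(texture_correlation_length, "texture_correlation_length",
                     lower = 0)
  # the outer ring must fit inside the grid (pixel centers, physical units)
  ext_r <- c(ring_center[1] - 1, grid_shape[1] - ring_center[1]) * pixel_spacing[1]
  ext_c <- c(ring_center[2] - 1, grid_shape[2] - ring_center[2]) * pixel_spacing[2]
  if (ro >= min(c(ext_r, ext_c)))
    stop("outer ring radius does not fit inside the grid")
  structure(list(grid_shape = as.integer(grid_shape),
                 pixel_spacing = as.numeric(pixel_spacing),
                 ring_center = as.numeric(ring_center),
                 ring_radii = c(inner = ri, outer = ro),
                 base_value = base_value,
                 texture_amplitude = texture_amplitude,
                 texture_correlation_length = texture_correlation_length,
                 noise_sd = noise_sd,
                 background_value = background_value),
            class = "phantom_spec")
}

#' Reference annulus mask of a phantom specification
#'
#' A pixel belongs to the ROI when its center lies at a physical distance
#' within [inner, outer] of the ring center.
#'
#' @param spec a [phantom_spec()].
#' @return logical matrix of the grid shape.
#' @export
annulus_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- (seq_len(spec$grid_shape[1]) - spec$ring_center[1]) * spec$pixel_spacing[1]
  c_ <- (seq_len(spec$grid_shape[2]) - spec$ring_center[2]) * spec$pixel_spacing[2]
  d <- sqrt(outer(r^2, c_^2, "+"))
  d >= spec$ring_radii["inner"] & d <= spec$ring_radii["outer"]
}

#' Construct a parametric map object
#'
#' @param values numeric matrix of map values.
#' @param pixel_spacing mm per pixel (row, col).
#' @param subject,slice,field identifying labels carried through the pipeline.
#' @return an object of class `parametric_map`.
#' @export
parametric_map <- function(values, pixel_spacing = c(1, 1),
                           subject = NA, slice = NA, field = NA) {
  stopifnot(is.matrix(values), is.numeric(values), all(pixel_spacing > 0))
  structure(list(values = values, pixel_spacing = as.numeric(pixel_spacing),
                 subject = subject, slice = slice, field = field),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("parametric_map %dx%d @ %.3gx%.3g mm (subject=%s slice=%s field=%s)\n",
              nrow(x$values), ncol(x$values), x$pixel_spacing[1],
              x$pixel_spacing[2], x$subject, x$slice, x$field))
  invisible(x)
}

# Noise-free in-ROI field for one map realization: base + subject effect +
# correlated texture. Texture is drawn from its own derived seed so paired
# field strengths can share it.
.noisefree_field <- function(spec, subject_effect, texture_seed) {
  tex <- withr::with_seed(texture_seed,
    .grf(spec$grid_shape[1], spec$grid_shape[2],
         spec$texture_correlation_length, spec$pixel_spacing))
  field <- matrix(spec$background_value, spec$grid_shape[1], spec$grid_shape[2])
  m <- annulus_mask(spec)
  field[m] <- spec$base_value + subject_effect +
    spec$texture_amplitude * tex[m]
  list(field = field, mask = m)
}

.add_roi_noise <- function(field, mask, noise_sd, seed) {
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, rnorm(sum(mask), sd = noise_sd))
    field[mask] <- field[mask] + noise
  }
  field
}

#' Generate one phantom parametric map and its reference ROI mask
#'
#' In-ROI values are `base_value + subject_effect + texture + noise`; the
#' background is the constant plateau. Deterministic given `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param subject_effect additive between-subject offset (map units).
#' @param seed integer seed; texture and noise use child seeds derived from it.
#' @param subject,slice,field labels attached to the map.
#' @return list with elements `map` ([parametric_map()]) and `mask` (logical
#'   matrix, the reference annulus).
#' @export
generate_map <- function(spec, subject_effect = 0, seed = 1,
                         subject = NA, slice = NA, field = NA) {
  stopifnot(inherits(spec, "phantom_spec"))
  nf <- .noisefree_field(spec, subject_effect, derive_seed(seed, 1))
  vals <- .add_roi_noise(nf$field, nf$mask, spec$noise_sd, derive_seed(seed, 2))
  list(map = parametric_map(vals, spec$pixel_spacing, subject, slice, field),
       mask = nf$mask)
}

#' Cohort configuration
#'
#' Describes the synthetic study: subjects, slices per subject, two field
#' strengths related by an affine intensity shift, and the master seed from
#' which every per-map seed is derived.
#'
#' @param n_subjects number of subjects (>= 1; reliability estimation itself
#'   refuses cohorts with fewer than 2 targets).
#' @param slices_per_subject short-axis slices per subject.
#' @param field_labels two labels, first = reference field.
#' @param field_gain,field_offset affine map applied to the noise-free field
#'   of field 1 to obtain field 2 (`gain * x + offset`). Defaults give a
#'   second-field myocardial base near 1200 map units from 950, emulating the
#'   higher signal level of a stronger magnet.
#' @param field_noise_ratio multiplier on `noise_sd` for the second field.
#' @param subject_sd standard deviation (map units) of the additive
#'   between-subject effect.
#' @param share_field_noise if TRUE both fields reuse one noise draw, so an
#'   identity field shift makes the paired maps identical (a limit useful for
#'   validating the reproducibility analysis).
#' @param master_seed integer master seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 15, slices_per_subject = 3,
                          field_labels = c("1p5T", "3T"),
                          field_gain = 1.25, field_offset = 12.5,
                          field_noise_ratio = 1.2,
                          subject_sd = 40, share_field_noise = FALSE,
                          master_seed = 1L) {
  stopifnot(n_subjects >= 1, slices_per_subject >= 1,
            length(field_labels) == 2, field_gain > 0,
            field_noise_ratio >= 0, subject_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 slices_per_subject = as.integer(slices_per_subject),
                 field_labels = as.character(field_labels),
                 field_gain = field_gain, field_offset = field_offset,
                 field_noise_ratio = field_noise_ratio,
                 subject_sd = subject_sd,
                 share_field_noise = isTRUE(share_field_noise),
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

#' Generate a paired-field-strength map pair sharing one texture realization
#'
#' Both maps share the same spatial texture field; the second map's noise-free
#' intensities are `field_gain * x + field_offset` of the first's, and each
#' map receives independently drawn white noise (the second scaled by
#' `field_noise_ratio`) unless `share_noise = TRUE`.
#'
#' @param spec a [phantom_spec()].
#' @param config a [cohort_config()].
#' @param subject_effect additive subject offset (map units).
#' @param seed integer seed.
#' @param subject,slice labels attached to both maps.
#' @param share_noise if TRUE the second map reuses the first map's noise draw
#'   (before the affine shift), so an identity shift yields identical maps.
#' @return list with `maps` (named list of two [parametric_map()]s keyed by
#'   field label) and `mask` (shared reference annulus).
#' @export
generate_field_pair <- function(spec, config, subject_effect = 0, seed = 1,
                                subject = NA, slice = NA, share_noise = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(config, "cohort_config"))
  nf <- .noisefree_field(spec, subject_effect, derive_seed(seed, 1))
  f2 <- config$field_gain * nf$field + config$field_offset
  s1 <- derive_seed(seed, 2)
  s2 <- if (share_noise) s1 else derive_seed(seed, 3)
  sd2 <- if (share_noise) spec$noise_sd else spec$noise_sd * config$field_noise_ratio
  v1 <- .add_roi_noise(nf$field, nf$mask, spec$noise_sd, s1)
  v2 <- .add_roi_noise(f2, nf$mask, sd2, s2)
  maps <- list(
    parametric_map(v1, spec$pixel_spacing, subject, slice, config$field_labels[1]),
    parametric_map(v2, spec$pixel_spacing, subject, slice, config$field_labels[2]))
  names(maps) <- config$field_labels
  list(maps = maps, mask = nf$mask)
}

#' Generate a synthetic cohort of paired parametric maps
#'
#' Produces `n_subjects x slices_per_subject` records, each holding the two
#' field-strength maps sharing one texture realization plus the reference
#' annulus mask. Subject effects are drawn once per subject from
#' `N(0, subject_sd)`. Per-map seeds are derived from the master seed and the
#' (subject, slice) indices, so the cohort is fully reproducible and any map
#' can be regenerated in isolation. Optionally writes every map and mask as
#' NIfTI plus an index table.
#'
#' @param config a [cohort_config()].
#' @param spec a [phantom_spec()].
#' @param dir optional output directory; when given, NIfTI files and
#'   `index.csv` are written there.
#' @return an object of class `rtf_cohort`: list with `records` (one per
#'   subject-slice), `index` (data.frame: one row per map file), `config`,
#'   `spec`.
#' @export
generate_cohort <- function(config, spec = phantom_spec(), dir = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(spec, "phantom_spec"))
  records <- list()
  index <- list()
  for (s in seq_len(config$n_subjects)) {
    eff <- withr::with_seed(derive_seed(config$master_seed, 0, s),
                            rnorm(1, sd = config$subject_sd))
    for (sl in seq_len(config$slices_per_subject)) {
      seed <- derive_seed(config$master_seed, s, sl)
      pair <- generate_field_pair(spec, config, subject_effect = eff,
                                  seed = seed, subject = s, slice = sl,
                                  share_noise = config$share_field_noise)
      rec <- list(subject = s, slice = sl, maps = pair$maps, mask = pair$mask,
                  seed = seed)
      records[[length(records) + 1L]] <- rec
      for (fl in config$field_labels) {
        index[[length(index) + 1L]] <- data.frame(
          subject = s, slice = sl, field = fl,
          path = sprintf("map_s%02d_sl%d_%s.nii.gz", s, sl, fl),
          mask_path = sprintf("mask_s%02d_sl%d.nii.gz", s, sl),
          seed = seed, stringsAsFactors = FALSE)
      }
    }
  }
  index <- do.call(rbind, index)
  cohort <- structure(list(records = records, index = index,
                           config = config, spec = spec),
                      class = "rtf_cohort")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (rec in records) {
      for (fl in config$field_labels) {
        m <- rec$maps[[fl]]
        fn <- file.path(dir, sprintf("map_s%02d_sl%d_%s.nii.gz",
                                     rec$subject, rec$slice, fl))
        RNifti::writeNifti(
          RNifti::asNifti(m$values, pixdim = m$pixel_spacing), fn)
      }
      fnm <- file.path(dir, sprintf("mask_s%02d_sl%d.nii.gz",
                                    rec$subject, rec$slice))
      RNifti::writeNifti(
        RNifti::asNifti(matrix(as.integer(rec$mask), nrow(rec$mask)),
                        pixdim = spec$pixel_spacing, datatype = "uint8"), fnm)
    }
    write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  }
  cohort
}

#' @export
print.rtf_cohort <- function(x, ...) {
  cat(sprintf("rtf_cohort: %d subjects x %d slices x 2 fields (%s) = %d maps\n",
              x$config$n_subjects, x$config$slices_per_subject,
              paste(x$config$field_labels, collapse = "/"), nrow(x$index)))
  invisible(x)
}
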