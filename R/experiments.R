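# One record's repeatability unit: masks for the three runs at a level.
# Run seeds are derived from (master seed, record index, run index) only —
# not from the level — so a sweep over levels scales the *same* displacement
# fields (common random numbers), which makes level comparisons low-noise.
.run_masks <- function(cohort, rec_idx, level, n_runs,
                       displacement_scale, smoothness) {
  rec <- cohort$records[[rec_idx]]
  sp <- cohort$spec$pixel_spacing
  lapply(seq_len(n_runs), function(run) {
    cfg <- perturbation_config(level, displacement_scale, smoothness,
      seed = derive_seed(cohort$config$master_seed, 7, rec_idx, run))
    perturb_mask(rec$mask, cfg, sp)
  })
}

.long_row <- function(target, rater, values) {
  data.frame(target = target, rater = rater,
             feature = names(values), value = unname(values),
             stringsAsFactors = FALSE)
}

#' Repeatability study across segmentation runs
#'
#' For every map of one field strength, `n_runs` segmentation masks are
#' generated at the stated perturbation level (distinct derived seeds), the
#' 1023 features are extracted per run, and per kept feature the
#' targets-by-runs table (one target per subject-slice) is scored with
#' ICC(2,1). Zero-variance features are screened out first. The mean IoU
#' decomposition of the run triplets is reported alongside.
#'
#' @param cohort an `rtf_cohort` from [generate_cohort()].
#' @param level perturbation level in [0, 0.3]; 0 replicates the reference
#'   mask, so every kept feature is exactly repeatable.
#' @param field field label to analyze (default: first configured field).
#' @param n_runs segmentation runs per map.
#' @param settings an [extraction_settings()].
#' @param displacement_scale,smoothness perturbation model constants
#'   (see [perturbation_config()]).
#' @param model ICC model (repeatability uses absolute agreement, `icc2_1`).
#' @return list with `estimates` (per-feature ICC data.frame), `screen`
#'   (kept/excluded), `breakdown_filter`, `breakdown_class`, `iou`
#'   (mean [iou_decomposition()]), `features` (long table), `level`, `field`.
#' @export
run_repeatability <- function(cohort, level = 0, field = NULL, n_runs = 3,
                              settings = extraction_settings(),
                              displacement_scale = 9.5, smoothness = 6,
                              model = "icc2_1") {
  stopifnot(inherits(cohort, "rtf_cohort"))
  if (length(cohort$records) < 2)
    stop("repeatability needs at least 2 targets (subject-slices)")
  if (is.null(field)) field <- cohort$config$field_labels[1]
  stopifnot(field %in% cohort$config$field_labels)
  rows <- list()
  decomps <- list()
  for (ri in seq_along(cohort$records)) {
    rec <- cohort$records[[ri]]
    masks <- .run_masks(cohort, ri, level, n_runs,
                        displacement_scale, smoothness)
    if (n_runs >= 3)
      decomps[[length(decomps) + 1L]] <- decompose_triplet(masks[1:3])
    target <- sprintf("s%02d_sl%d", rec$subject, rec$slice)
    for (run in seq_len(n_runs)) {
      fv <- extract_features(rec$maps[[field]], masks[[run]], settings)
      rows[[length(rows) + 1L]] <- .long_row(target, paste0("run", run), fv)
    }
  }
  long <- do.call(rbind, rows)
  scr <- screen_degenerate(long)
  est <- icc_by_feature(long[long$feature %in% scr$kept, ], model = model)
  list(estimates = est, screen = scr,
       breakdown_filter = reliability_breakdown(est, "filter"),
       breakdown_class = reliability_breakdown(est, "class"),
       iou = if (length(decomps)) mean_decomposition(decomps) else NULL,
       features = long, level = level, field = field, model = model)
}

#' Reproducibility study across field strengths
#'
#' For every map pair the features are extracted at both field strengths from
#' the reference mask (the single-expert segmentation), and per kept feature
#' the targets-by-fields table is scored with the consistency model ICC(3,1).
#'
#' @param cohort an `rtf_cohort`.
#' @param settings an [extraction_settings()].
#' @param model ICC model (reproducibility uses consistency, `icc3_1`).
#' @return list with `estimates`, `screen`, `breakdown_filter`,
#'   `breakdown_class`, `features` (long table).
#' @export
run_reproducibility <- function(cohort, settings = extraction_settings(),
                                model = "icc3_1") {
  stopifnot(inherits(cohort, "rtf_cohort"))
  if (length(cohort$records) < 2)
    stop("reproducibility needs at least 2 targets (subject-slices)")
  rows <- list()
  for (rec in cohort$records) {
    target <- sprintf("s%02d_sl%d", rec$subject, rec$slice)
    for (fl in cohort$config$field_labels) {
      fv <- extract_features(rec$maps[[fl]], rec$mask, settings)
      rows[[length(rows) + 1L]] <- .long_row(target, fl, fv)
    }
  }
  long <- do.call(rbind, rows)
  scr <- screen_degenerate(long)
  est <- icc_by_feature(long[long$feature %in% scr$kept, ], model = model)
  list(estimates = est, screen = scr,
       breakdown_filter = reliability_breakdown(est, "filter"),
       breakdown_class = reliability_breakdown(est, "class"),
       features = long, model = model)
}

#' Segmentation-variability sweep
#'
#' Runs the repeatability analysis at every perturbation level of the grid
#' (default 0 to 0.3 in steps of 0.02, 16 levels) with common random numbers
#' across levels, and reports per level the cohort-mean IoU decomposition of
#' the mask triplets and the proportion of kept features in each reliability
#' category.
#'
#' @param cohort an `rtf_cohort`.
#' @param levels numeric grid of perturbation levels within [0, 0.3].
#' @param field field label to sweep.
#' @param settings an [extraction_settings()].
#' @param displacement_scale,smoothness perturbation model constants.
#' @return data.frame of class `sweep_result`: one row per level with
#'   `level`, `iou3`, `iou2`, `iou1`, `prop_excellent`, `prop_good`,
#'   `prop_moderate`, `prop_poor`, `n_kept`.
#' @export
run_dp_sweep <- function(cohort, levels = seq(0, 0.3, by = 0.02),
                         field = NULL, settings = extraction_settings(),
                         displacement_scale = 9.5, smoothness = 6) {
  stopifnot(all(levels >= 0 & levels <= 0.3))
  out <- lapply(levels, function(lv) {
    rep_ <- run_repeatability(cohort, level = lv, field = field,
                              settings = settings,
                              displacement_scale = displacement_scale,
                              smoothness = smoothness)
    ov <- reliability_breakdown(rep_$estimates, "overall")$proportions
    pr <- function(categ) ov$proportion[ov$category == categ]
    data.frame(level = lv,
               iou3 = rep_$iou["iou3"], iou2 = rep_$iou["iou2"],
               iou1 = rep_$iou["iou1"],
               prop_excellent = pr("excellent"), prop_good = pr("good"),
               prop_moderate = pr("moderate"), prop_poor = pr("poor"),
               n_kept = sum(!is.na(rep_$estimates$icc)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Write a report bundle of study results
#'
#' Writes per-feature estimate CSVs, breakdown CSVs, the sweep CSV and a JSON
#' run-metadata file. Errors on empty results; no partial bundle is left
#' behind.
#'
#' @param results named list; recognized elements: `repeatability`,
#'   `reproducibility` (outputs of the respective run functions), `sweep`
#'   (a `sweep_result`), `metadata` (list serialized to JSON).
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(results, dir) {
  stopifnot(is.list(results))
  known <- intersect(names(results),
                     c("repeatability", "reproducibility", "sweep"))
  if (length(known) == 0) stop("no results to report")
  tmp <- tempfile("report_")
  dir.create(tmp)
  files <- character(0)
  put <- function(df, name) {
    fn <- file.path(tmp, name)
    write.csv(df, fn, row.names = FALSE)
    files <<- c(files, name)
  }
  for (nm in c("repeatability", "reproducibility")) {
    r <- results[[nm]]
    if (is.null(r)) next
    put(r$estimates, paste0(nm, "_estimates.csv"))
    put(r$breakdown_filter$proportions, paste0(nm, "_by_filter.csv"))
    put(r$breakdown_class$proportions, paste0(nm, "_by_class.csv"))
    put(r$breakdown_filter$top_features, paste0(nm, "_top_features.csv"))
    if (nrow(r$screen$excluded))
      put(r$screen$excluded, paste0(nm, "_excluded.csv"))
  }
  if (!is.null(results$sweep)) put(as.data.frame(results$sweep), "sweep.csv")
  meta <- results$metadata
  if (is.null(meta)) meta <- list()
  meta$written <- files
  jsonlite::write_json(meta, file.path(tmp, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "run_metadata.json")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- file.copy(file.path(tmp, files), file.path(dir, files),
                  overwrite = TRUE)
  unlink(tmp, recursive = TRUE)
  if (!all(ok)) stop("failed to write report bundle")
  invisible(file.path(dir, files))
}
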