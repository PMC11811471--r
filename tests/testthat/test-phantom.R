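spec_small <- phantom_spec(grid_shape = c(64, 64), ring_radii = c(10, 16),
                           base_value = 950, texture_amplitude = 40,
                           noise_sd = 15)

test_that("noiseless map equals base + subject effect exactly inside the ROI", {
  sp <- phantom_spec(texture_amplitude = 0, noise_sd = 0)
  g <- generate_map(sp, subject_effect = 37.5, seed = 11)
  expect_true(all(g$map$values[g$mask] == sp$base_value + 37.5))
  expect_true(all(g$map$values[!g$mask] == sp$background_value))
})

test_that("map generation is a pure function of (spec, effect, seed)", {
  g1 <- generate_map(spec_small, subject_effect = 5, seed = 99)
  g2 <- generate_map(spec_small, subject_effect = 5, seed = 99)
  expect_identical(g1$map$values, g2$map$values)
  expect_identical(g1$mask, g2$mask)
  g3 <- generate_map(spec_small, subject_effect = 5, seed = 100)
  expect_false(identical(g1$map$values, g3$map$values))
})

test_that("annulus membership matches a brute-force per-pixel distance test", {
  sp <- phantom_spec(grid_shape = c(80, 80), pixel_spacing = c(1, 1),
                     ring_radii = c(18, 30))
  m <- annulus_mask(sp)
  cnt <- 0
  for (r in 1:80) for (c in 1:80) {
    d <- sqrt(((r - sp$ring_center[1]))^2 + ((c - sp$ring_center[2]))^2)
    inside <- d >= 18 && d <= 30
    expect_identical(m[r, c], inside)
    cnt <- cnt + inside
  }
  expect_equal(sum(m), cnt)
})

test_that("degenerate ring geometry is rejected", {
  expect_error(phantom_spec(grid_shape = c(40, 40), ring_radii = c(10, 30)),
               "fit")
  expect_error(phantom_spec(ring_radii = c(20, 10)), "inner")
})

test_that("field pair: identity shift with shared noise gives identical maps", {
  cfg <- cohort_config(field_gain = 1, field_offset = 0, field_noise_ratio = 1)
  p <- generate_field_pair(spec_small, cfg, subject_effect = 3, seed = 5,
                           share_noise = TRUE)
  expect_identical(p$maps[[1]]$values, p$maps[[2]]$values)
})

test_that("field pair: affine shift propagates exactly without noise", {
  sp <- phantom_spec(texture_amplitude = 30, noise_sd = 0)
  cfg <- cohort_config(field_gain = 1.25, field_offset = 12.5)
  p <- generate_field_pair(sp, cfg, subject_effect = 7, seed = 2)
  v1 <- p$maps[[1]]$values[p$mask]
  v2 <- p$maps[[2]]$values[p$mask]
  expect_equal(v2, 1.25 * v1 + 12.5, tolerance = 1e-12)
  expect_equal(mean(v2), 1.25 * mean(v1) + 12.5, tolerance = 1e-12)
  # shared spatial texture: noise-free fields correlate perfectly
  expect_equal(cor(v1, v2), 1, tolerance = 1e-12)
})

test_that("cohort has the right size, labels and full determinism", {
  cfg <- cohort_config(n_subjects = 15, slices_per_subject = 3,
                       master_seed = 123)
  co <- generate_cohort(cfg, spec_small)
  expect_equal(length(co$records), 45)          # 45 map pairs
  expect_equal(nrow(co$index), 90)              # 90 map files listed
  expect_setequal(unique(co$index$field), c("1p5T", "3T"))
  co2 <- generate_cohort(cfg, spec_small)
  expect_identical(co$index, co2$index)
  expect_identical(co$records[[17]]$maps[[2]]$values,
                   co2$records[[17]]$maps[[2]]$values)
})

test_that("between-subject variance of mean ROI value is positive", {
  cfg <- cohort_config(n_subjects = 6, slices_per_subject = 1,
                       subject_sd = 40, master_seed = 77)
  co <- generate_cohort(cfg, spec_small)
  means <- vapply(co$records,
                  function(r) mean(r$maps[[1]]$values[r$mask]), numeric(1))
  expect_gt(var(means), 0)
})

test_that("single-subject cohorts are generable but refused downstream", {
  cfg <- cohort_config(n_subjects = 1, slices_per_subject = 1)
  co <- generate_cohort(cfg, spec_small)
  expect_equal(length(co$records), 1)
  expect_error(run_repeatability(co), "at least 2")
})

test_that("cohort writes NIfTI maps, masks and an index that round-trips", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_subjects = 2, slices_per_subject = 1,
                       master_seed = 9)
  co <- generate_cohort(cfg, spec_small, dir = dir)
  idx <- read.csv(file.path(dir, "index.csv"))
  expect_equal(nrow(idx), 4)
  img <- RNifti::readNifti(file.path(dir, idx$path[1]))
  expect_equal(dim(img), c(64, 64))
  expect_equal(as.vector(img), as.vector(co$records[[1]]$maps[[1]]$values),
               tolerance = 1e-6)
  msk <- RNifti::readNifti(file.path(dir, idx$mask_path[1]))
  expect_setequal(unique(as.vector(msk)), c(0, 1))
})

test_that("perturbation level 0 is the identity and high levels disagree", {
  m <- annulus_mask(spec_small)
  cfg0 <- perturbation_config(0, seed = 4)
  expect_identical(perturb_mask(m, cfg0), m)
  tri <- perturb_triplet(m, 0.3, seed = 21)
  expect_lt(decompose_triplet(tri)["iou3"], 1)
  # determinism
  expect_identical(perturb_triplet(m, 0.2, seed = 8),
                   perturb_triplet(m, 0.2, seed = 8))
})

test_that("mean pairwise mask agreement decreases with perturbation level", {
  m <- annulus_mask(spec_small)
  iou_pair <- function(a, b) sum(a & b) / sum(a | b)
  mean_iou <- function(level) {
    mean(vapply(1:30, function(s) {
      a <- perturb_mask(m, perturbation_config(level, seed = derive_seed(s, 1)))
      b <- perturb_mask(m, perturbation_config(level, seed = derive_seed(s, 2)))
      iou_pair(a, b)
    }, numeric(1)))
  }
  expect_lt(mean_iou(0.3), mean_iou(0.1))
})

test_that("derived seeds are valid integers and distinct across paths", {
  s <- derive_seed(2147483646, 15, 3, 2)
  expect_true(is.integer(s) && s > 0)
  seeds <- vapply(1:500, function(i) derive_seed(1, i), integer(1))
  expect_equal(length(unique(seeds)), 500)
})
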