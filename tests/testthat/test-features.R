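test_that("in-plane resampling handles the no-op, upsampling and binarity", {
  set.seed(1)
  x <- matrix(runif(100), 10, 10)
  m <- matrix(TRUE, 10, 10)
  r <- resample_inplane(x, m, c(1, 1))
  expect_identical(r$values, x)
  r2 <- resample_inplane(x, m, c(2, 2))
  expect_equal(dim(r2$values), c(20L, 20L))
  expect_equal(r2$pixel_spacing, c(1, 1))
  chk <- matrix((row(x) + col(x)) %% 2 == 0, 10, 10)
  r3 <- resample_inplane(x, chk, c(2, 2))
  expect_true(all(r3$mask %in% c(TRUE, FALSE)))
  expect_error(resample_inplane(x, matrix(FALSE, 10, 10), c(2, 2)), "empty")
})

test_that("discretization follows the anchored floor rule", {
  v <- matrix(c(0, 24.9, 25, 50), 2, 2)
  m <- matrix(TRUE, 2, 2)
  d <- discretize_roi(v, m, 25)
  expect_equal(sort(d$levels[m]), c(1, 1, 2, 3))
  expect_equal(d$ng, 3)
  dc <- discretize_roi(matrix(5, 3, 3), matrix(TRUE, 3, 3), 25)
  expect_equal(dc$ng, 1)
  expect_true(all(dc$levels == 1))
  # histogram of levels equals a loop-computed histogram
  set.seed(2)
  v2 <- matrix(runif(100, 0, 90), 10, 10)
  d2 <- discretize_roi(v2, matrix(TRUE, 10, 10), 10)
  h <- numeric(d2$ng)
  for (x in v2) h[floor((x - min(v2)) / 10) + 1] <- h[floor((x - min(v2)) / 10) + 1] + 1
  expect_equal(tabulate(d2$levels, d2$ng), as.integer(h))
  expect_error(discretize_roi(matrix(NA_real_, 2, 2), matrix(TRUE, 2, 2), 1),
               "non-finite")
})

test_that("GLCM handles constant ROIs, stripes and is symmetric", {
  d1 <- discretize_roi(matrix(1, 2, 2), matrix(TRUE, 2, 2), 25)
  g1 <- build_glcm(d1)
  for (P in g1$matrices) expect_equal(P, matrix(1, 1, 1))
  # two-level vertical stripes: horizontal offset sees only transitions
  v <- matrix(rep(c(0, 30), each = 4), 4, 2)   # col 1 = 0, col 2 = 30
  d2 <- discretize_roi(v, matrix(TRUE, 4, 2), 25)
  g2 <- build_glcm(d2)
  Ph <- g2$matrices[[1]]                        # offset (0,1)
  expect_equal(diag(Ph), c(0, 0))
  expect_equal(Ph[1, 2], 0.5)
  for (P in g2$matrices) expect_equal(P, t(P))
})

test_that("constant-region run, zone and single-pixel conventions hold", {
  d <- discretize_roi(matrix(5, 3, 3), matrix(TRUE, 3, 3), 25)
  rl <- build_glrlm(d)
  expect_equal(rl$matrices[[1]][1, 3], 3)       # 3 horizontal runs of length 3
  sz <- build_glszm(d)
  expect_equal(sz$matrices[[1]][1, 9], 1)       # one zone of size 9
  m1 <- matrix(FALSE, 3, 3); m1[2, 2] <- TRUE
  d1 <- discretize_roi(matrix(5, 3, 3), m1, 25)
  expect_equal(build_glszm(d1)$matrices[[1]][1, 1], 1)
  expect_equal(build_ngtdm(d1)$matrices[[1]][1, "s"], c(s = 0))
})

test_that("every texture matrix matches its brute-force oracle on random ROIs", {
  for (s in 1:12) {
    roi <- random_small_roi(s)
    d <- roi$d
    L <- d$levels
    g <- build_glcm(d)
    og <- o_glcm(L, d$ng)
    expect_equal(length(g$matrices), length(og))
    for (i in seq_along(og)) expect_equal(g$matrices[[i]], og[[i]])
    rl <- build_glrlm(d)
    orl <- o_glrlm(L, d$ng)
    for (i in 1:4) expect_equal(rl$matrices[[i]], orl[[i]])
    expect_equal(build_glszm(d)$matrices[[1]], o_glszm(L, d$ng))
    expect_equal(build_gldm(d)$matrices[[1]], o_gldm(L, d$ng))
    expect_equal(build_ngtdm(d)$matrices[[1]], o_ngtdm(L, d$ng))
  }
})

test_that("first-order statistics match closed forms and a loop oracle", {
  dc <- discretize_roi(matrix(7, 4, 4), matrix(TRUE, 4, 4), 25)
  fo <- firstorder_features(dc)
  expect_equal(unname(fo[c("Mean", "Median", "Minimum", "Maximum")]),
               rep(7, 4))
  expect_equal(unname(fo["Variance"]), 0)
  expect_equal(unname(fo["Uniformity"]), 1)
  expect_equal(unname(fo["Energy"]), 16 * 49)
  expect_equal(unname(fo[c("Skewness", "Kurtosis")]), c(0, 0))
  v <- matrix(c(1, 2, 3, 4), 2, 2)
  fo2 <- firstorder_features(discretize_roi(v, matrix(TRUE, 2, 2), 1))
  expect_equal(unname(fo2["Mean"]), 2.5)
  expect_equal(unname(fo2["Range"]), 3)
  expect_equal(unname(fo2["Variance"]), 1.25)
  set.seed(9)
  v3 <- matrix(rnorm(1000, 100, 30), 40, 25)
  d3 <- discretize_roi(v3, matrix(TRUE, 40, 25), 25)
  expect_equal(firstorder_features(d3),
               o_firstorder(d3$values, d3$levels[d3$mask], d3$ng),
               tolerance = 1e-12)
})

test_that("degenerate matrices fall back to the documented values", {
  d <- discretize_roi(matrix(5, 3, 3), matrix(TRUE, 3, 3), 25)
  gf <- family_features(build_glcm(d))
  expect_equal(unname(gf["Contrast"]), 0)
  expect_equal(unname(gf["Correlation"]), 1)
  expect_equal(unname(gf["JointEntropy"]), 0)
  # single run per angle: both non-uniformities are 1
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  dr <- discretize_roi(matrix(5, 3, 3), m, 25)
  for (rf in build_glrlm(dr)$matrices) expect_equal(sum(rf), 1)
  rff <- family_features(build_glrlm(dr))
  expect_equal(unname(rff["GrayLevelNonUniformity"]), 1)
  expect_equal(unname(rff["RunLengthNonUniformity"]), 1)
})

test_that("all 93 features match the definition-literal oracles on random ROIs", {
  for (s in 1:50) {
    roi <- random_small_roi(s)
    d <- roi$d
    L <- d$levels
    rel_eq <- function(a, b) {
      expect_equal(a[sort(names(a))], b[sort(names(b))], tolerance = 1e-9)
    }
    rel_eq(firstorder_features(d),
           o_firstorder(d$values, d$levels[d$mask], d$ng))
    og <- o_glcm(L, d$ng)
    rel_eq(family_features(build_glcm(d)),
           rowMeans(vapply(og, o_glcm_features, numeric(24))))
    orl <- o_glrlm(L, d$ng)
    rel_eq(family_features(build_glrlm(d)),
           rowMeans(vapply(orl, function(R) o_rl_features(R, d$np, TRUE),
                           numeric(16))))
    rel_eq(family_features(build_glszm(d)),
           o_rl_features(o_glszm(L, d$ng), d$np, FALSE))
    rel_eq(family_features(build_gldm(d)),
           o_gldm_features(o_gldm(L, d$ng), d$np))
    rel_eq(family_features(build_ngtdm(d)),
           o_ngtdm_features(o_ngtdm(L, d$ng), d$np))
  }
})

test_that("extraction yields 1023 deterministic, translation-consistent values", {
  sp <- phantom_spec(grid_shape = c(48, 48), ring_radii = c(8, 14))
  g <- generate_map(sp, subject_effect = 0, seed = 31)
  fv <- extract_features(g$map, g$mask)
  expect_equal(length(fv), 1023)
  expect_identical(names(fv), full_feature_names())
  expect_identical(fv, extract_features(g$map, g$mask))
  # same texture under a translated ROI: first-order features unchanged
  shift <- function(m, dr, dc) {
    out <- m * 0
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  vals2 <- shift(g$map$values, 3, 5)
  mask2 <- shift(g$mask * 1, 3, 5) > 0
  fv2 <- extract_features(parametric_map(vals2), mask2)
  fo_names <- grep("^original_firstorder_", names(fv), value = TRUE)
  expect_equal(fv[fo_names], fv2[fo_names], tolerance = 1e-12)
})

test_that("the manifest enforces the class counts 18/24/16/16/14/5", {
  fm <- feature_manifest()
  expect_equal(nrow(fm), 93)
  cnt <- table(fm$class)
  expect_equal(as.integer(cnt[c("firstorder", "glcm", "glrlm", "glszm",
                                "gldm", "ngtdm")]),
               c(18L, 24L, 16L, 16L, 14L, 5L))
  expect_equal(length(full_feature_names()), 1023)
  # the shipped manifest file pins the same universe
  mf <- jsonlite::read_json(system.file("extdata", "feature_manifest.json",
                                        package = "rtfrel"),
                            simplifyVector = TRUE)
  expect_equal(mf$filters, filter_labels())
  for (cl in names(mf$classes))
    expect_equal(mf$classes[[cl]],
                 fm$feature[fm$class == cl])
})
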