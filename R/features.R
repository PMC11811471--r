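# Canonical feature names per class (18 + 24 + 16 + 16 + 14 + 5 = 93).
.FEATURE_NAMES <- list(
  firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum",
                 "10Percentile", "90Percentile", "Maximum", "Mean", "Median",
                 "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                 "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
                 "Kurtosis", "Variance", "Uniformity"),
  glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
           "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
           "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
           "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
           "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
           "SumAverage", "SumEntropy", "SumSquares"),
  glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelRunEmphasis",
            "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
            "RunEntropy", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "RunVariance", "ShortRunEmphasis",
            "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis"),
  glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
            "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
            "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
            "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
            "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
            "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy", "ZonePercentage",
            "ZoneVariance"),
  gldm = c("DependenceEntropy", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "DependenceVariance",
           "GrayLevelNonUniformity", "GrayLevelVariance",
           "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
           "LargeDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
           "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
           "SmallDependenceLowGrayLevelEmphasis"),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"))

.plog2 <- function(p) ifelse(p > 0, log2(p), 0)

#' The 93-feature manifest
#'
#' @return data.frame with columns `class` and `feature` (93 rows).
#' @export
feature_manifest <- function() {
  data.frame(class = rep(names(.FEATURE_NAMES),
                         vapply(.FEATURE_NAMES, length, integer(1))),
             feature = unlist(.FEATURE_NAMES, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Full 1023-name manifest across the eleven image versions
#'
#' Names follow the `"(filter)_(class)_(feature)"` convention, e.g.
#' `"lbp-2D_firstorder_Maximum"`.
#'
#' @return character vector of length 1023.
#' @export
full_feature_names <- function() {
  fm <- feature_manifest()
  unlist(lapply(filter_labels(),
                function(f) paste(f, fm$class, fm$feature, sep = "_")),
         use.names = FALSE)
}

#' First-order intensity statistics (18 features)
#'
#' Statistics over the original (not discretized) ROI intensities, except
#' Entropy and Uniformity which use the discretized level probabilities.
#' Variance, Skewness and Kurtosis use population moments; Kurtosis is not
#' excess-corrected (a normal sample gives ~3). A constant ROI returns 0 for
#' both Skewness and Kurtosis. TotalEnergy scales Energy by the pixel area
#' (mm^2). Percentiles use linear interpolation (R quantile type 7).
#'
#' @param d a [discretize_roi()] result.
#' @param pixel_area physical pixel area in mm^2 (1 after 1 mm resampling).
#' @return named numeric vector of length 18.
#' @export
firstorder_features <- function(d, pixel_area = 1) {
  stopifnot(inherits(d, "discretized_roi"))
  x <- d$values
  n <- length(x)
  p <- tabulate(d$levels[d$mask], nbins = d$ng) / n
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- unname(quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7))
  sub <- x[x >= qs[1] & x <= qs[5]]
  rmad <- if (length(sub)) mean(abs(sub - mean(sub))) else 0
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(Energy = sum(x^2),
    TotalEnergy = pixel_area * sum(x^2),
    Entropy = -sum(p * .plog2(p)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(x),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}

# ---- per-family feature computations ---------------------------------------

.glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  lev <- seq_len(ng)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sigx2 <- sum((lev - mux)^2 * px); sigy2 <- sum((lev - muy)^2 * py)
  # diagonal (difference) and cross-diagonal (sum) probabilities
  kd <- 0:(ng - 1)
  pdiff <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * ng)
  psum <- vapply(ks, function(k) sum(P[(i + j) == k]), numeric(1))
  autoc <- sum(i * j * P)
  da <- sum(kd * pdiff)
  hxy <- -sum(P * .plog2(P))
  hx <- -sum(px * .plog2(px)); hy <- -sum(py * .plog2(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * .plog2(pxpy))
  hxy2 <- -sum(pxpy * .plog2(pxpy))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sigx2 * sigy2 > 0) (autoc - mux * muy) / sqrt(sigx2 * sigy2) else 1
  mcc <- {
    ix <- which(px > 0); ik <- which(py > 0)
    if (length(ix) <= 1) 1 else {
      A <- P[ix, ik, drop = FALSE] / px[ix]
      B <- P[ix, ik, drop = FALSE] / rep(py[ik], each = length(ix))
      ev <- sort(Re(eigen(A %*% t(B), only.values = TRUE)$values),
                 decreasing = TRUE)
      sqrt(pmax(0, ev[2]))
    }
  }
  c(Autocorrelation = autoc,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdiff * .plog2(pdiff)),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum((P / pmax((i - j)^2, 1))[i != j]),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * psum),
    SumEntropy = -sum(psum * .plog2(psum)),
    SumSquares = sigx2)
}

.rl_features_one <- function(R, np, kind = c("glrlm", "glszm")) {
  kind <- match.arg(kind)
  nr <- sum(R)
  i <- row(R); j <- col(R)
  p <- R / nr
  lev <- seq_len(nrow(R)); jl <- seq_len(ncol(R))
  pg <- rowSums(p); pr <- colSums(p)
  mug <- sum(lev * pg); muj <- sum(jl * pr)
  vals <- c(
    sum(rowSums(R)^2) / nr,                      # GrayLevelNonUniformity
    sum(rowSums(R)^2) / nr^2,                    # ...Normalized
    sum(p * (i - mug)^2),                        # GrayLevelVariance
    sum(R * i^2) / nr,                           # High gray level emphasis
    sum(R * j^2) / nr,                           # long run / large area
    sum(R * i^2 * j^2) / nr,                     # long+high / large+high
    sum(R * j^2 / i^2) / nr,                     # long+low / large+low
    sum(R / i^2) / nr,                           # low gray level emphasis
    -sum(p * .plog2(p)),                         # run/zone entropy
    sum(colSums(R)^2) / nr,                      # RLN / SZN
    sum(colSums(R)^2) / nr^2,                    # normalized
    nr / np,                                     # run/zone percentage
    sum(p * (j - muj)^2),                        # run/zone variance
    sum(R / j^2) / nr,                           # short run / small area
    sum(R * i^2 / j^2) / nr,                     # short+high / small+high
    sum(R / (i^2 * j^2)) / nr)                   # short+low / small+low
  if (kind == "glrlm") {
    names(vals) <- c("GrayLevelNonUniformity",
                     "GrayLevelNonUniformityNormalized", "GrayLevelVariance",
                     "HighGrayLevelRunEmphasis", "LongRunEmphasis",
                     "LongRunHighGrayLevelEmphasis",
                     "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
                     "RunEntropy", "RunLengthNonUniformity",
                     "RunLengthNonUniformityNormalized", "RunPercentage",
                     "RunVariance", "ShortRunEmphasis",
                     "ShortRunHighGrayLevelEmphasis",
                     "ShortRunLowGrayLevelEmphasis")
  } else {
    names(vals) <- c("GrayLevelNonUniformity",
                     "GrayLevelNonUniformityNormalized", "GrayLevelVariance",
                     "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
                     "LargeAreaHighGrayLevelEmphasis",
                     "LargeAreaLowGrayLevelEmphasis",
                     "LowGrayLevelZoneEmphasis", "ZoneEntropy",
                     "SizeZoneNonUniformity",
                     "SizeZoneNonUniformityNormalized", "ZonePercentage",
                     "ZoneVariance", "SmallAreaEmphasis",
                     "SmallAreaHighGrayLevelEmphasis",
                     "SmallAreaLowGrayLevelEmphasis")
  }
  vals[.FEATURE_NAMES[[kind]]]
}

.gldm_features_one <- function(D, np) {
  nz <- sum(D)
  i <- row(D); j <- col(D)
  p <- D / nz
  lev <- seq_len(nrow(D)); jl <- seq_len(ncol(D))
  pg <- rowSums(p); pd <- colSums(p)
  mug <- sum(lev * pg); mud <- sum(jl * pd)
  c(DependenceEntropy = -sum(p * .plog2(p)),
    DependenceNonUniformity = sum(colSums(D)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(D)^2) / nz^2,
    DependenceVariance = sum(p * (j - mud)^2),
    GrayLevelNonUniformity = sum(rowSums(D)^2) / nz,
    GrayLevelVariance = sum(p * (i - mug)^2),
    HighGrayLevelEmphasis = sum(D * i^2) / nz,
    LargeDependenceEmphasis = sum(D * j^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(D * i^2 * j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(D * j^2 / i^2) / nz,
    LowGrayLevelEmphasis = sum(D / i^2) / nz,
    SmallDependenceEmphasis = sum(D / j^2) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(D * i^2 / j^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(D / (i^2 * j^2)) / nz)
}

.ngtdm_features_one <- function(tab, np) {
  n <- tab[, "n"]; p <- tab[, "p"]; s <- tab[, "s"]
  I <- which(n > 0)
  ngp <- length(I)
  lev <- seq_along(n)
  ps <- sum(p * s)
  coarse <- if (ps > 0) 1 / ps else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p[I], p[I]) * outer(lev[I], lev[I], "-")^2) /
       (ngp * (ngp - 1))) * (sum(s) / np)
  } else 0
  ipi <- lev[I] * p[I]
  bus_den <- sum(abs(outer(ipi, ipi, "-")))
  busy <- if (bus_den > 0) ps / bus_den else 0
  cplx <- if (np > 0) {
    sum(abs(outer(lev[I], lev[I], "-")) *
          (outer(p[I] * s[I], p[I] * s[I], "+")) /
          outer(p[I], p[I], "+")) / np
  } else 0
  strg_den <- sum(s)
  strg <- if (strg_den > 0)
    sum(outer(p[I], p[I], "+") * outer(lev[I], lev[I], "-")^2) / strg_den
  else 0
  c(Busyness = busy, Coarseness = coarse, Complexity = cplx,
    Contrast = contrast, Strength = strg)
}

#' Texture features of one matrix family
#'
#' Computes the standardized definitional features of the family held by a
#' `texture_matrix` (24 GLCM / 16 GLRLM / 16 GLSZM / 14 GLDM / 5 NGTDM).
#' Angle-dependent families (GLCM, GLRLM) report the mean over the per-angle
#' feature values. Degenerate matrices use documented fallbacks: Correlation
#' and MCC of a single-level GLCM are 1, entropy terms use `0 log 0 = 0`,
#' NGTDM Coarseness of a zero-deviation ROI is 1e6, Busyness/Strength with a
#' zero denominator are 0.
#'
#' @param tm a `texture_matrix` from one of the `build_*` functions.
#' @return named numeric vector.
#' @export
family_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix"))
  switch(tm$family,
    GLCM = {
      if (length(tm$matrices) == 0)
        stop("GLCM has no valid angle")
      rowMeans(vapply(tm$matrices, .glcm_features_one,
                      numeric(length(.FEATURE_NAMES$glcm))))
    },
    GLRLM = rowMeans(vapply(tm$matrices,
                            function(R) .rl_features_one(R, tm$np, "glrlm"),
                            numeric(16))),
    GLSZM = .rl_features_one(tm$matrices[[1]], tm$np, "glszm"),
    GLDM = .gldm_features_one(tm$matrices[[1]], tm$np),
    NGTDM = .ngtdm_features_one(tm$matrices[[1]], tm$np),
    stop("unknown family"))
}

#' Extraction settings
#'
#' @param bin_width fixed gray-level bin width in map units (applied to every
#'   image version).
#' @param glcm_distance pixel distance for GLCM offsets.
#' @param gldm_alpha level-difference cutoff for GLDM dependence.
#' @param target_spacing in-plane resampling target (mm).
#' @param filter a [filter_settings()].
#' @return an object of class `extraction_settings`.
#' @export
extraction_settings <- function(bin_width = 25, glcm_distance = 1,
                                gldm_alpha = 0, target_spacing = c(1, 1),
                                filter = filter_settings()) {
  stopifnot(bin_width > 0, inherits(filter, "filter_settings"))
  structure(list(bin_width = bin_width, glcm_distance = glcm_distance,
                 gldm_alpha = gldm_alpha,
                 target_spacing = as.numeric(target_spacing),
                 filter = filter),
            class = "extraction_settings")
}

#' Extract the full 1023-value radiomic feature vector
#'
#' Pipeline per (map, mask): resample to the target in-plane resolution,
#' build the eleven-version filter stack on the full image, then per version
#' discretize the ROI, build the five texture matrices and compute the 93
#' features. Feature names follow `"(filter)_(class)_(feature)"`.
#'
#' @param map a [parametric_map()] or a numeric matrix.
#' @param mask logical ROI matrix on the map grid.
#' @param settings an [extraction_settings()].
#' @param pixel_spacing used when `map` is a bare matrix.
#' @return named numeric vector of length 1023 (11 versions x 93 features).
#' @export
extract_features <- function(map, mask, settings = extraction_settings(),
                             pixel_spacing = c(1, 1)) {
  if (inherits(map, "parametric_map")) {
    values <- map$values
    pixel_spacing <- map$pixel_spacing
  } else {
    values <- map
  }
  stopifnot(is.matrix(values), inherits(settings, "extraction_settings"))
  rs <- resample_inplane(values, mask, pixel_spacing, settings$target_spacing)
  stack <- build_filter_stack(rs$values, rs$pixel_spacing, settings$filter)
  pixel_area <- prod(rs$pixel_spacing)
  out <- numeric(0)
  for (fl in filter_labels()) {
    d <- discretize_roi(stack[[fl]], rs$mask, settings$bin_width)
    vals <- c(
      firstorder_features(d, pixel_area),
      family_features(build_glcm(d, settings$glcm_distance)),
      family_features(build_glrlm(d)),
      family_features(build_glszm(d)),
      family_features(build_gldm(d, settings$gldm_alpha)),
      family_features(build_ngtdm(d)))
    fm <- feature_manifest()
    names(vals) <- paste(fl, fm$class, fm$feature, sep = "_")
    out <- c(out, vals)
  }
  out
}
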