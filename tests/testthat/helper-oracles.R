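# Definition-literal brute-force oracles. Everything here is written as
# explicit per-pixel / per-cell loops, independent of the vectorized
# implementation paths in the package.

o_log2 <- function(p) if (p > 0) log2(p) else 0

# ---- first-order ------------------------------------------------------------

# type-7 quantile, computed literally from the order statistics
o_quantile <- function(x, p) {
  xs <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo >= length(x)) return(xs[length(x)])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

o_firstorder <- function(x, levels, ng, pixel_area = 1) {
  n <- length(x)
  p <- numeric(ng)
  for (l in levels) p[l] <- p[l] + 1 / n
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  p10 <- o_quantile(x, 0.10); p90 <- o_quantile(x, 0.90)
  sub <- x[x >= p10 & x <= p90]
  ent <- 0; unif <- 0
  for (q in p) { ent <- ent - q * o_log2(q); unif <- unif + q^2 }
  c(Energy = sum(x^2),
    TotalEnergy = pixel_area * sum(x^2),
    Entropy = ent,
    Minimum = min(x),
    `10Percentile` = p10,
    `90Percentile` = p90,
    Maximum = max(x),
    Mean = mu,
    Median = o_quantile(x, 0.5),
    InterquartileRange = o_quantile(x, 0.75) - o_quantile(x, 0.25),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = sum(abs(sub - mean(sub))) / length(sub),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) (sum((x - mu)^3) / n) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) (sum((x - mu)^4) / n) / m2^2 else 0,
    Variance = m2,
    Uniformity = unif)
}

# ---- matrix builders --------------------------------------------------------

o_offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))

o_glcm <- function(L, ng) {
  nr <- nrow(L); nc <- ncol(L)
  lapply(o_offsets, function(off) {
    C <- matrix(0, ng, ng)
    for (r in 1:nr) for (c in 1:nc) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(L[r, c]) || is.na(L[r2, c2])) next
      C[L[r, c], L[r2, c2]] <- C[L[r, c], L[r2, c2]] + 1
      C[L[r2, c2], L[r, c]] <- C[L[r2, c2], L[r, c]] + 1  # symmetrize
    }
    C / sum(C)
  })
}

o_glrlm <- function(L, ng) {
  nr <- nrow(L); nc <- ncol(L)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  lapply(o_offsets, function(off) {
    runs <- list()
    for (r in 1:nr) for (c in 1:nc) {
      if (is.na(L[r, c])) next
      pr <- r - off[1]; pc <- c - off[2]
      # run start: predecessor along the direction absent or different
      if (inside(pr, pc) && !is.na(L[pr, pc]) && L[pr, pc] == L[r, c]) next
      len <- 1
      nr2 <- r + off[1]; nc2 <- c + off[2]
      while (inside(nr2, nc2) && !is.na(L[nr2, nc2]) &&
             L[nr2, nc2] == L[r, c]) {
        len <- len + 1
        nr2 <- nr2 + off[1]; nc2 <- nc2 + off[2]
      }
      runs[[length(runs) + 1]] <- c(L[r, c], len)
    }
    jmax <- max(1, vapply(runs, `[`, 0, 2))
    R <- matrix(0, ng, jmax)
    for (rn in runs) R[rn[1], rn[2]] <- R[rn[1], rn[2]] + 1
    R
  })
}

# flood fill with an explicit stack, 8-connectivity
o_glszm <- function(L, ng) {
  nr <- nrow(L); nc <- ncol(L)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(L[r, c]) || seen[r, c]) next
    lev <- L[r, c]
    stack <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (seen[r2, c2] || is.na(L[r2, c2]) || L[r2, c2] != lev) next
        seen[r2, c2] <- TRUE
        stack[[length(stack) + 1]] <- c(r2, c2)
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  smax <- max(vapply(zones, `[`, 0, 2))
  S <- matrix(0, ng, smax)
  for (z in zones) S[z[1], z[2]] <- S[z[1], z[2]] + 1
  S
}

o_gldm <- function(L, ng, alpha = 0) {
  nr <- nrow(L); nc <- ncol(L)
  entries <- list()
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(L[r, c])) next
    dep <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.na(L[r2, c2]) && abs(L[r2, c2] - L[r, c]) <= alpha)
        dep <- dep + 1
    }
    entries[[length(entries) + 1]] <- c(L[r, c], dep)
  }
  jmax <- max(vapply(entries, `[`, 0, 2))
  D <- matrix(0, ng, jmax)
  for (e in entries) D[e[1], e[2]] <- D[e[1], e[2]] + 1
  D
}

o_ngtdm <- function(L, ng) {
  nr <- nrow(L); nc <- ncol(L)
  n <- numeric(ng); s <- numeric(ng); np <- 0
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(L[r, c])) next
    np <- np + 1
    n[L[r, c]] <- n[L[r, c]] + 1
    tot <- 0; cnt <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.na(L[r2, c2])) { tot <- tot + L[r2, c2]; cnt <- cnt + 1 }
    }
    if (cnt > 0) s[L[r, c]] <- s[L[r, c]] + abs(L[r, c] - tot / cnt)
  }
  cbind(n = n, p = n / np, s = s)
}

# ---- family features (literal double loops) ---------------------------------

o_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx2 <- 0; sigy2 <- 0
  for (i in 1:ng) {
    sigx2 <- sigx2 + (i - mux)^2 * px[i]
    sigy2 <- sigy2 + (i - muy)^2 * py[i]
  }
  pdiff <- numeric(ng); psum <- numeric(2 * ng - 1)  # k = 0..ng-1 ; 2..2ng
  for (i in 1:ng) for (j in 1:ng) {
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
    psum[i + j - 1] <- psum[i + j - 1] + P[i, j]
  }
  acc <- function(f) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) s <- s + f(i, j, P[i, j])
    s
  }
  autoc <- acc(function(i, j, p) i * j * p)
  da <- 0
  for (k in 0:(ng - 1)) da <- da + k * pdiff[k + 1]
  hxy <- -acc(function(i, j, p) p * o_log2(p))
  hx <- 0; hy <- 0
  for (i in 1:ng) { hx <- hx - px[i] * o_log2(px[i]); hy <- hy - py[i] * o_log2(py[i]) }
  hxy1 <- -acc(function(i, j, p) p * o_log2(px[i] * py[j]))
  hxy2 <- -acc(function(i, j, p) px[i] * py[j] * o_log2(px[i] * py[j]))
  de <- 0; dv <- 0
  for (k in 0:(ng - 1)) {
    de <- de - pdiff[k + 1] * o_log2(pdiff[k + 1])
    dv <- dv + (k - da)^2 * pdiff[k + 1]
  }
  se <- 0; sa <- 0
  for (k in 2:(2 * ng)) {
    se <- se - psum[k - 1] * o_log2(psum[k - 1])
    sa <- sa + k * psum[k - 1]
  }
  mcc <- {
    ix <- which(px > 0); ik <- which(py > 0)
    if (length(ix) <= 1) 1 else {
      Q <- matrix(0, length(ix), length(ix))
      for (a in seq_along(ix)) for (b in seq_along(ix)) {
        for (kk in ik)
          Q[a, b] <- Q[a, b] +
            P[ix[a], kk] * P[ix[b], kk] / (px[ix[a]] * py[kk])
      }
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, ev[2]))
    }
  }
  c(Autocorrelation = autoc,
    ClusterProminence = acc(function(i, j, p) (i + j - mux - muy)^4 * p),
    ClusterShade = acc(function(i, j, p) (i + j - mux - muy)^3 * p),
    ClusterTendency = acc(function(i, j, p) (i + j - mux - muy)^2 * p),
    Contrast = acc(function(i, j, p) (i - j)^2 * p),
    Correlation = if (sigx2 * sigy2 > 0) (autoc - mux * muy) / sqrt(sigx2 * sigy2) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = de,
    DifferenceVariance = dv,
    Id = acc(function(i, j, p) p / (1 + abs(i - j))),
    Idm = acc(function(i, j, p) p / (1 + (i - j)^2)),
    Idmn = acc(function(i, j, p) p / (1 + (i - j)^2 / ng^2)),
    Idn = acc(function(i, j, p) p / (1 + abs(i - j) / ng)),
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = acc(function(i, j, p) if (i != j) p / (i - j)^2 else 0),
    JointAverage = mux,
    JointEnergy = acc(function(i, j, p) p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sa,
    SumEntropy = se,
    SumSquares = sigx2)
}

# shared run-length / size-zone feature formulas, literal loops
o_rl_features <- function(R, np, glrlm = TRUE) {
  ngr <- nrow(R); jm <- ncol(R)
  nr <- sum(R)
  gln <- 0; rln <- 0
  for (i in 1:ngr) gln <- gln + sum(R[i, ])^2
  for (j in 1:jm) rln <- rln + sum(R[, j])^2
  sums <- c(sre = 0, lre = 0, lgl = 0, hgl = 0, srl = 0, srh = 0,
            lrl = 0, lrh = 0, glv = 0, rv = 0, ent = 0)
  mug <- 0; muj <- 0
  for (i in 1:ngr) for (j in 1:jm) {
    p <- R[i, j] / nr
    mug <- mug + i * p; muj <- muj + j * p
  }
  for (i in 1:ngr) for (j in 1:jm) {
    x <- R[i, j]; p <- x / nr
    sums["sre"] <- sums["sre"] + x / j^2
    sums["lre"] <- sums["lre"] + x * j^2
    sums["lgl"] <- sums["lgl"] + x / i^2
    sums["hgl"] <- sums["hgl"] + x * i^2
    sums["srl"] <- sums["srl"] + x / (i^2 * j^2)
    sums["srh"] <- sums["srh"] + x * i^2 / j^2
    sums["lrl"] <- sums["lrl"] + x * j^2 / i^2
    sums["lrh"] <- sums["lrh"] + x * i^2 * j^2
    sums["glv"] <- sums["glv"] + p * (i - mug)^2
    sums["rv"] <- sums["rv"] + p * (j - muj)^2
    sums["ent"] <- sums["ent"] - p * o_log2(p)
  }
  v <- c(gln / nr, gln / nr^2, sums[["glv"]], sums[["hgl"]] / nr,
         sums[["lre"]] / nr, sums[["lrh"]] / nr, sums[["lrl"]] / nr,
         sums[["lgl"]] / nr, sums[["ent"]], rln / nr, rln / nr^2,
         nr / np, sums[["rv"]], sums[["sre"]] / nr, sums[["srh"]] / nr,
         sums[["srl"]] / nr)
  names(v) <- if (glrlm) {
    c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis")
  } else {
    c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "ZoneEntropy", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage", "ZoneVariance",
      "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "SmallAreaLowGrayLevelEmphasis")
  }
  v
}

o_gldm_features <- function(D, np) {
  ngr <- nrow(D); jm <- ncol(D)
  nz <- sum(D)
  gln <- 0; dn <- 0
  for (i in 1:ngr) gln <- gln + sum(D[i, ])^2
  for (j in 1:jm) dn <- dn + sum(D[, j])^2
  mug <- 0; mud <- 0
  for (i in 1:ngr) for (j in 1:jm) {
    p <- D[i, j] / nz
    mug <- mug + i * p; mud <- mud + j * p
  }
  s <- c(ent = 0, dv = 0, glv = 0, hgl = 0, lde = 0, ldh = 0, ldl = 0,
         lgl = 0, sde = 0, sdh = 0, sdl = 0)
  for (i in 1:ngr) for (j in 1:jm) {
    x <- D[i, j]; p <- x / nz
    s["ent"] <- s["ent"] - p * o_log2(p)
    s["dv"] <- s["dv"] + p * (j - mud)^2
    s["glv"] <- s["glv"] + p * (i - mug)^2
    s["hgl"] <- s["hgl"] + x * i^2
    s["lde"] <- s["lde"] + x * j^2
    s["ldh"] <- s["ldh"] + x * i^2 * j^2
    s["ldl"] <- s["ldl"] + x * j^2 / i^2
    s["lgl"] <- s["lgl"] + x / i^2
    s["sde"] <- s["sde"] + x / j^2
    s["sdh"] <- s["sdh"] + x * i^2 / j^2
    s["sdl"] <- s["sdl"] + x / (i^2 * j^2)
  }
  c(DependenceEntropy = s[["ent"]],
    DependenceNonUniformity = dn / nz,
    DependenceNonUniformityNormalized = dn / nz^2,
    DependenceVariance = s[["dv"]],
    GrayLevelNonUniformity = gln / nz,
    GrayLevelVariance = s[["glv"]],
    HighGrayLevelEmphasis = s[["hgl"]] / nz,
    LargeDependenceEmphasis = s[["lde"]] / nz,
    LargeDependenceHighGrayLevelEmphasis = s[["ldh"]] / nz,
    LargeDependenceLowGrayLevelEmphasis = s[["ldl"]] / nz,
    LowGrayLevelEmphasis = s[["lgl"]] / nz,
    SmallDependenceEmphasis = s[["sde"]] / nz,
    SmallDependenceHighGrayLevelEmphasis = s[["sdh"]] / nz,
    SmallDependenceLowGrayLevelEmphasis = s[["sdl"]] / nz)
}

o_ngtdm_features <- function(tab, np) {
  n <- tab[, "n"]; p <- tab[, "p"]; s <- tab[, "s"]
  I <- which(n > 0); ngp <- length(I)
  ps <- 0
  for (i in I) ps <- ps + p[i] * s[i]
  contrast <- 0; busy_den <- 0; cplx <- 0; strg <- 0
  for (i in I) for (j in I) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    cplx <- cplx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
    strg <- strg + (p[i] + p[j]) * (i - j)^2
  }
  c(Busyness = if (busy_den > 0) ps / busy_den else 0,
    Coarseness = if (ps > 0) 1 / ps else 1e6,
    Complexity = cplx / np,
    Contrast = if (ngp > 1) contrast / (ngp * (ngp - 1)) * sum(s) / np else 0,
    Strength = if (sum(s) > 0) strg / sum(s) else 0)
}

# ---- ANOVA ------------------------------------------------------------------

o_two_way_ss <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- sum(m) / (n * k)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in 1:n) ssr <- ssr + k * (sum(m[i, ]) / k - gm)^2
  for (j in 1:k) ssc <- ssc + n * (sum(m[, j]) / n - gm)^2
  for (i in 1:n) for (j in 1:k) sst <- sst + (m[i, j] - gm)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = (sst - ssr - ssc) / ((n - 1) * (k - 1)))
}

# ---- shared fixtures --------------------------------------------------------

# random discretized 8x8 ROI: returns a discretized_roi built by the package
# plus the raw ingredients for the oracles
random_small_roi <- function(seed, ng_target = 5) {
  set.seed(seed)
  vals <- matrix(runif(64, 0, ng_target * 10), 8, 8)
  mask <- matrix(runif(64) < 0.7, 8, 8)
  if (!any(mask)) mask[3, 3] <- TRUE
  d <- discretize_roi(vals, mask, bin_width = 10)
  list(d = d, vals = vals, mask = mask)
}
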