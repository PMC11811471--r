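#' Filter-bank settings
#'
#' Settings for the ten filters producing, together with the original image,
#' the eleven image versions from which features are extracted. Defaults
#' follow the conventions of the standard radiomics extraction tooling:
#' rotation-invariant uniform LBP with radius 1 and 9 samples, and a
#' single-level coiflet-1 wavelet decomposition kept at input resolution.
#'
#' @param lbp_radius circle radius of the local binary pattern, pixels.
#' @param lbp_samples number of circularly sampled neighbors (>= 4).
#' @param lbp_method only `"uniform"` (rotation-invariant uniform codes) is
#'   implemented.
#' @param wavelet_basis only `"coif1"` is implemented.
#' @return an object of class `filter_settings`.
#' @export
filter_settings <- function(lbp_radius = 1, lbp_samples = 9,
                            lbp_method = "uniform", wavelet_basis = "coif1") {
  stopifnot(lbp_radius >= 1, lbp_samples >= 4)
  lbp_method <- match.arg(lbp_method, "uniform")
  wavelet_basis <- match.arg(wavelet_basis, "coif1")
  structure(list(lbp_radius = lbp_radius, lbp_samples = as.integer(lbp_samples),
                 lbp_method = lbp_method, wavelet_basis = wavelet_basis),
            class = "filter_settings")
}

#' Canonical labels of the eleven image versions
#' @return character vector of length 11.
#' @export
filter_labels <- function() {
  c("original", "square", "squareroot", "logarithm", "exponential",
    "gradient", "lbp-2D", "wavelet-LL", "wavelet-LH", "wavelet-HL",
    "wavelet-HH")
}

#' Point (pixel-wise) intensity filters
#'
#' Element-wise monotone transforms with range-preserving scaling, with
#' `m = max(|x|)` over the image:
#' \itemize{
#'   \item square: `(x / sqrt(m))^2`
#'   \item squareroot: `sign(x) * sqrt(m * |x|)`
#'   \item logarithm: `sign(x) * c * log(1 + |x|)`, `c = m / log(1 + m)`
#'   \item exponential: `exp(c * x)`, `c = log(m) / m`
#' }
#' Each maps the extreme magnitude `m` back to `m`, so the output range
#' matches the input range. An all-zero image leaves the scaling constants
#' undefined; the input is then returned unchanged with a warning.
#'
#' @param x numeric matrix with finite entries.
#' @param kind one of `"square"`, `"squareroot"`, `"logarithm"`,
#'   `"exponential"`.
#' @return numeric matrix of the same shape.
#' @export
apply_point_filter <- function(x, kind) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  kind <- match.arg(kind, c("square", "squareroot", "logarithm", "exponential"))
  m <- max(abs(x))
  if (m == 0) {
    warning("all-zero image: point filter scaling undefined, returning input")
    return(x)
  }
  switch(kind,
    square = (x / sqrt(m))^2,
    squareroot = sign(x) * sqrt(m * abs(x)),
    logarithm = sign(x) * (m / log1p(m)) * log1p(abs(x)),
    exponential = exp((log(m) / m) * x))
}

#' Gradient magnitude filter
#'
#' Per-pixel gradient magnitude from finite differences scaled by the physical
#' pixel spacing: central differences in the interior, one-sided differences
#' at the edges.
#'
#' @param x numeric matrix, at least 2x2.
#' @param pixel_spacing mm per pixel (row, col).
#' @return nonnegative numeric matrix of the same shape.
#' @export
apply_gradient <- function(x, pixel_spacing = c(1, 1)) {
  stopifnot(is.matrix(x), nrow(x) >= 2, ncol(x) >= 2, all(pixel_spacing > 0))
  nr <- nrow(x); nc <- ncol(x)
  gr <- x; gc <- x
  gr[2:(nr - 1), ] <- (x[3:nr, ] - x[1:(nr - 2), ]) / 2
  gr[1, ] <- x[2, ] - x[1, ]
  gr[nr, ] <- x[nr, ] - x[nr - 1, ]
  gc[, 2:(nc - 1)] <- (x[, 3:nc] - x[, 1:(nc - 2)]) / 2
  gc[, 1] <- x[, 2] - x[, 1]
  gc[, nc] <- x[, nc] - x[, nc - 1]
  sqrt((gr / pixel_spacing[1])^2 + (gc / pixel_spacing[2])^2)
}

# Bilinear sample of x at fractional (row, col) offsets from every pixel,
# replicating edge values outside the grid.
.shift_bilinear <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  r <- seq_len(nr) + dr
  c_ <- seq_len(nc) + dc
  r0 <- clamp(floor(r), 1, nr); r1 <- clamp(r0 + 1, 1, nr)
  c0 <- clamp(floor(c_), 1, nc); c1 <- clamp(c0 + 1, 1, nc)
  fr <- clamp(r, 1, nr) - r0
  fc <- clamp(c_, 1, nc) - c0
  wr <- matrix(fr, nr, nc)
  wc <- matrix(fc, nr, nc, byrow = TRUE)
  x[r0, c0, drop = FALSE] * (1 - wr) * (1 - wc) +
    x[r1, c0, drop = FALSE] * wr * (1 - wc) +
    x[r0, c1, drop = FALSE] * (1 - wr) * wc +
    x[r1, c1, drop = FALSE] * wr * wc
}

#' Rotation-invariant uniform 2D local binary pattern
#'
#' For each pixel, `P` points are sampled (bilinearly, edge-replicated) on a
#' circle of radius `R`; sample `k` sits at angle `2*pi*k/P` with offset
#' `(R*sin, R*cos)`. Each sample is thresholded against the center value
#' (`>=`). If the circular bit pattern has at most two 0/1 transitions
#' (a "uniform" pattern) the code is the number of set bits, otherwise `P+1`,
#' so codes lie in `[0, P+1]`.
#'
#' @param x numeric matrix, at least `2*radius+1` in each dimension.
#' @param settings a [filter_settings()].
#' @return integer-valued numeric matrix of the same shape.
#' @export
apply_lbp2d <- function(x, settings = filter_settings()) {
  stopifnot(is.matrix(x), inherits(settings, "filter_settings"))
  P <- settings$lbp_samples
  R <- settings$lbp_radius
  if (nrow(x) < 2 * R + 1 || ncol(x) < 2 * R + 1)
    stop("image smaller than 2*radius+1")
  bits <- vector("list", P)
  for (k in 0:(P - 1)) {
    a <- 2 * pi * k / P
    s <- .shift_bilinear(x, R * sin(a), R * cos(a))
    bits[[k + 1]] <- (s >= x) * 1L
  }
  ones <- Reduce(`+`, bits)
  trans <- matrix(0L, nrow(x), ncol(x))
  for (k in seq_len(P)) {
    nxt <- if (k == P) 1L else k + 1L
    trans <- trans + (bits[[k]] != bits[[nxt]])
  }
  out <- ifelse(trans <= 2, ones, P + 1)
  storage.mode(out) <- "double"
  out
}

# coiflet-1 analysis filters (low-pass sums to sqrt(2), high-pass to 0)
.COIF1_LO <- c(-0.015655728135464787, -0.07273261951252645,
               0.3848648468648578, 0.8525720202116004,
               0.3378976624574811, -0.07273261951252645)
.COIF1_HI <- local({
  h <- rev(.COIF1_LO) * c(1, -1, 1, -1, 1, -1)
  h - sum(h) / length(h)  # enforce the vanishing moment exactly
})

# Circular 1D convolution of each column of x with filter h (undecimated
# analysis step; output y[i] = sum_k h[k] x[i + k - 1 mod n]).
.circ_filter_cols <- function(x, h) {
  n <- nrow(x)
  y <- matrix(0, n, ncol(x))
  for (k in seq_along(h)) {
    idx <- ((seq_len(n) - 1 + (k - 1)) %% n) + 1
    y <- y + h[k] * x[idx, , drop = FALSE]
  }
  y
}

#' Single-level undecimated 2D wavelet decomposition (coiflet-1)
#'
#' Stationary (a trous) single-level separable decomposition with circular
#' boundary handling; sub-bands are kept at the input grid size because
#' features are computed on the original ROI mask. Label convention `"XY"`:
#' filter `X` applied along columns (horizontal direction), `Y` along rows
#' (vertical). The low-pass filter sums to `sqrt(2)`, so the LL band of a
#' constant image is the constant scaled by 2 and the LH/HL/HH bands of a
#' constant image vanish.
#'
#' @param x numeric matrix.
#' @param basis only `"coif1"`.
#' @return named list of matrices `LL`, `LH`, `HL`, `HH`, each the input
#'   shape.
#' @export
apply_wavelet <- function(x, basis = "coif1") {
  stopifnot(is.matrix(x))
  basis <- match.arg(basis, "coif1")
  lo <- .COIF1_LO; hi <- .COIF1_HI
  # rows dimension = vertical; columns dimension = horizontal
  lo_r <- .circ_filter_cols(x, lo)      # low-pass along vertical
  hi_r <- .circ_filter_cols(x, hi)
  filt_h <- function(m, h) t(.circ_filter_cols(t(m), h))
  list(LL = filt_h(lo_r, lo),
       LH = filt_h(hi_r, lo),   # low horizontal, high vertical
       HL = filt_h(lo_r, hi),   # high horizontal, low vertical
       HH = filt_h(hi_r, hi))
}

#' Build the eleven-version filtered image stack
#'
#' Applies the four point filters, the gradient, the LBP and the four wavelet
#' sub-bands to one image and returns them together with the original as a
#' named list with the canonical labels of [filter_labels()]. Deterministic;
#' every output shares the input shape.
#'
#' @param x numeric matrix (the resampled map).
#' @param pixel_spacing mm per pixel (row, col).
#' @param settings a [filter_settings()].
#' @return named list of 11 matrices (class `filtered_stack`).
#' @export
build_filter_stack <- function(x, pixel_spacing = c(1, 1),
                               settings = filter_settings()) {
  stopifnot(is.matrix(x))
  wav <- apply_wavelet(x, settings$wavelet_basis)
  stack <- list(
    "original" = x,
    "square" = apply_point_filter(x, "square"),
    "squareroot" = apply_point_filter(x, "squareroot"),
    "logarithm" = apply_point_filter(x, "logarithm"),
    "exponential" = apply_point_filter(x, "exponential"),
    "gradient" = apply_gradient(x, pixel_spacing),
    "lbp-2D" = apply_lbp2d(x, settings),
    "wavelet-LL" = wav$LL, "wavelet-LH" = wav$LH,
    "wavelet-HL" = wav$HL, "wavelet-HH" = wav$HH)
  stack <- stack[filter_labels()]
  class(stack) <- "filtered_stack"
  stack
}
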