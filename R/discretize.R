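#' Resample a map and mask to a target in-plane resolution
#'
#' The image is resampled with bilinear interpolation and the mask with
#' nearest-neighbor interpolation onto a grid of exactly the target spacing
#' (default 1 mm x 1 mm), aligning pixel centers of the two grids over the
#' same physical extent. Inputs already at the target spacing are returned
#' unchanged.
#'
#' @param values numeric matrix of map values.
#' @param mask logical matrix on the same grid.
#' @param pixel_spacing current mm per pixel (row, col).
#' @param target_spacing desired mm per pixel, default `c(1, 1)`.
#' @return list `values`, `mask`, `pixel_spacing` (= target).
#' @export
resample_inplane <- function(values, mask, pixel_spacing,
                             target_spacing = c(1, 1)) {
  stopifnot(is.matrix(values), is.matrix(mask), all(dim(values) == dim(mask)),
            all(pixel_spacing > 0), all(target_spacing > 0))
  if (isTRUE(all.equal(as.numeric(pixel_spacing), as.numeric(target_spacing))))
    return(list(values = values, mask = mask > 0,
                pixel_spacing = as.numeric(target_spacing)))
  nr <- nrow(values); nc <- ncol(values)
  nr2 <- max(2L, as.integer(round(nr * pixel_spacing[1] / target_spacing[1])))
  nc2 <- max(2L, as.integer(round(nc * pixel_spacing[2] / target_spacing[2])))
  # physical coordinate of target pixel center -> fractional source index
  src_r <- ((seq_len(nr2) - 0.5) * target_spacing[1]) / pixel_spacing[1] + 0.5
  src_c <- ((seq_len(nc2) - 0.5) * target_spacing[2]) / pixel_spacing[2] + 0.5
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  r <- clamp(src_r, 1, nr); c_ <- clamp(src_c, 1, nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c_), nc - 1)
  fr <- r - r0; fc <- c_ - c0
  v <- values[r0, c0] * outer(1 - fr, 1 - fc) +
    values[r0 + 1, c0] * outer(fr, 1 - fc) +
    values[r0, c0 + 1] * outer(1 - fr, fc) +
    values[r0 + 1, c0 + 1] * outer(fr, fc)
  m <- (mask > 0)[clamp(round(r), 1, nr), clamp(round(c_), 1, nc)]
  if (!any(m)) stop("mask is empty after resampling")
  list(values = v, mask = m, pixel_spacing = as.numeric(target_spacing))
}

#' Discretize ROI intensities into fixed-width gray-level bins
#'
#' Levels are assigned as `floor((x - min_ROI) / bin_width) + 1`, anchoring
#' the bin grid at the ROI minimum. A constant ROI yields the single level 1.
#'
#' @param values numeric matrix of map values.
#' @param mask logical ROI matrix of the same shape, non-empty.
#' @param bin_width positive bin width in map units.
#' @return object of class `discretized_roi`: list with `levels` (integer
#'   matrix, NA outside the ROI), `values` (original ROI intensities in the
#'   same pixel order as `which(mask)`), `mask`, `ng` (number of levels),
#'   `np` (ROI pixel count), `bin_width`.
#' @export
discretize_roi <- function(values, mask, bin_width = 25) {
  stopifnot(is.matrix(values), is.matrix(mask), all(dim(values) == dim(mask)),
            bin_width > 0)
  mask <- mask > 0
  if (!any(mask)) stop("empty ROI")
  v <- values[mask]
  if (any(!is.finite(v))) stop("non-finite values inside the ROI")
  lv <- as.integer(floor((v - min(v)) / bin_width) + 1)
  levels <- matrix(NA_integer_, nrow(values), ncol(values))
  levels[mask] <- lv
  structure(list(levels = levels, values = v, mask = mask,
                 ng = max(lv), np = length(v), bin_width = bin_width),
            class = "discretized_roi")
}
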