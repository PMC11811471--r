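#' Consensus IoU decomposition of a segmentation mask triplet
#'
#' Partitions the union of three binary masks into the fractions of pixels on
#' which exactly three, exactly two, and exactly one mask agree:
#' \deqn{IoU_3 = |A_1 \cap A_2 \cap A_3| / |A_1 \cup A_2 \cup A_3|}
#' \deqn{IoU_2 = |\{x : x \in exactly two masks\}| / |A_1 \cup A_2 \cup A_3|}
#' \deqn{IoU_1 = 1 - IoU_2 - IoU_3}
#' The three components always sum to 1 and are invariant under permutation of
#' the masks. Area is pixel count (pixel spacing cancels in the ratios).
#'
#' @param a1,a2,a3 logical matrices of a common shape, or `a1` may be a list
#'   of three such matrices.
#' @return an object of class `iou_decomposition`: named numeric
#'   `c(iou3, iou2, iou1)`.
#' @export
decompose_triplet <- function(a1, a2 = NULL, a3 = NULL) {
  if (is.list(a1) && is.null(a2)) {
    stopifnot(length(a1) == 3)
    a2 <- a1[[2]]; a3 <- a1[[3]]; a1 <- a1[[1]]
  }
  stopifnot(is.matrix(a1), is.matrix(a2), is.matrix(a3))
  if (!all(dim(a1) == dim(a2)) || !all(dim(a1) == dim(a3)))
    stop("masks must share one grid")
  mult <- (a1 > 0) + (a2 > 0) + (a3 > 0)
  union <- sum(mult > 0)
  if (union == 0) stop("union of the mask triplet is empty")
  iou_decomposition(sum(mult == 3) / union, sum(mult == 2) / union,
                    sum(mult == 1) / union)
}

#' Construct an IoU decomposition
#'
#' @param iou3,iou2,iou1 fractions in [0, 1] summing to 1.
#' @return named numeric vector of class `iou_decomposition`.
#' @export
iou_decomposition <- function(iou3, iou2, iou1) {
  v <- c(iou3 = iou3, iou2 = iou2, iou1 = iou1)
  if (any(v < -1e-12 | v > 1 + 1e-12))
    stop("IoU components must lie in [0, 1]")
  if (abs(sum(v) - 1) > 1e-12)
    stop("IoU components must sum to 1")
  structure(v, class = "iou_decomposition")
}

#' Component-wise mean of IoU decompositions
#'
#' Dataset-level averaging of per-triplet consensus decompositions; the mean
#' still sums to 1.
#'
#' @param decompositions non-empty list of [iou_decomposition()] objects.
#' @return an [iou_decomposition()].
#' @export
mean_decomposition <- function(decompositions) {
  if (!is.list(decompositions) || length(decompositions) == 0)
    stop("need a non-empty list of decompositions")
  m <- colMeans(do.call(rbind, lapply(decompositions, unclass)))
  iou_decomposition(unname(m["iou3"]), unname(m["iou2"]), unname(m["iou1"]))
}

#' @export
print.iou_decomposition <- function(x, ...) {
  cat(sprintf("IoU3 = %.4f  IoU2 = %.4f  IoU1 = %.4f\n",
              x["iou3"], x["iou2"], x["iou1"]))
  invisible(x)
}
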