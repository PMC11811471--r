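# The four in-plane direction offsets (row, col) used at distance 1 for the
# angle-dependent families (GLCM, GLRLM).
.ANGLE_OFFSETS <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

# Shift an (NA-outside-ROI) level matrix by (dr, dc), NA-filling the border.
.shift_levels <- function(L, dr, dc) {
  nr <- nrow(L); nc <- ncol(L)
  out <- matrix(NA_integer_, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- L[rs[ok_r], cs[ok_c]]
  out
}

.texture_matrix <- function(family, matrices, ng, np, extra = list()) {
  structure(c(list(family = family, matrices = matrices,
                   ng = ng, np = np), extra),
            class = "texture_matrix")
}

#' Gray-level co-occurrence matrices (distance 1, four in-plane angles)
#'
#' For each angle offset, co-occurring level pairs among ROI-interior pixel
#' pairs are counted, symmetrized (`C + t(C)`) and normalized to a probability
#' matrix. Angles with no valid pixel pair are dropped with a warning.
#'
#' @param d a [discretize_roi()] result.
#' @param distance pixel distance of the offsets (only 1 is supported).
#' @return `texture_matrix` with one `ng x ng` probability matrix per angle.
#' @export
build_glcm <- function(d, distance = 1) {
  stopifnot(inherits(d, "discretized_roi"), distance == 1)
  ng <- d$ng
  mats <- list()
  for (off in .ANGLE_OFFSETS) {
    L2 <- .shift_levels(d$levels, off[1], off[2])
    ok <- !is.na(d$levels) & !is.na(L2)
    if (!any(ok)) next
    i <- d$levels[ok]; j <- L2[ok]
    cnt <- matrix(tabulate((j - 1L) * ng + i, nbins = ng * ng), ng, ng)
    P <- cnt + t(cnt)
    mats[[length(mats) + 1L]] <- P / sum(P)
  }
  if (length(mats) == 0)
    warning("no valid neighbor pair for any angle; GLCM is empty")
  .texture_matrix("GLCM", mats, ng, d$np)
}

#' Gray-level run-length matrices (four in-plane angles)
#'
#' Counts maximal runs of equal level along each direction's scan lines,
#' broken at ROI boundaries, as `R[level, run length]` per angle.
#'
#' @param d a [discretize_roi()] result.
#' @return `texture_matrix` with one count matrix per angle.
#' @export
build_glrlm <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  ng <- d$ng
  L <- d$levels
  nr <- nrow(L); nc <- ncol(L)
  lines_for <- function(off) {
    if (off[1] == 0L && off[2] == 1L) {
      split(L, row(L))
    } else if (off[1] == 1L && off[2] == 0L) {
      split(L, col(L))
    } else if (off[1] == 1L && off[2] == 1L) {
      split(L, col(L) - row(L))
    } else {
      split(L, col(L) + row(L))
    }
  }
  mats <- lapply(.ANGLE_OFFSETS, function(off) {
    runs_i <- integer(0); runs_j <- integer(0)
    for (v in lines_for(off)) {
      v[is.na(v)] <- 0L
      r <- rle(as.integer(v))
      keep <- r$values > 0L
      runs_i <- c(runs_i, r$values[keep])
      runs_j <- c(runs_j, r$lengths[keep])
    }
    jmax <- max(runs_j, 1L)
    matrix(tabulate((runs_j - 1L) * ng + runs_i, nbins = ng * jmax), ng, jmax)
  })
  .texture_matrix("GLRLM", mats, ng, d$np)
}

# Connected zones of equal level (8-connectivity) in one igraph pass.
.label_zones <- function(L) {
  idx <- which(!is.na(L))
  nr <- nrow(L); nc <- ncol(L)
  vid <- matrix(0L, nr, nc)
  vid[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    sub <- which(ok)
    same <- !is.na(L[cbind(r2[sub], c2[sub])]) &
      L[cbind(r2[sub], c2[sub])] == L[idx[sub]]
    sub <- sub[same]
    from <- c(from, vid[idx[sub]])
    to <- c(to, vid[cbind(r2[sub], c2[sub])])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  list(zone_level = tapply(L[idx], comp, function(x) x[1]),
       zone_size = as.integer(table(comp)))
}

#' Gray-level size-zone matrix (8-connected zones)
#'
#' Counts 8-connected zones of equal level as `S[level, zone size]`.
#'
#' @param d a [discretize_roi()] result.
#' @return `texture_matrix` with one count matrix; `nz` zones in total.
#' @export
build_glszm <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  z <- .label_zones(d$levels)
  ng <- d$ng
  smax <- max(z$zone_size)
  S <- matrix(tabulate((z$zone_size - 1L) * ng + as.integer(z$zone_level),
                       nbins = ng * smax), ng, smax)
  .texture_matrix("GLSZM", list(S), ng, d$np, extra = list(nz = sum(S)))
}

#' Gray-level dependence matrix
#'
#' For each ROI pixel, the dependence is 1 (the pixel itself) plus the number
#' of its 8-neighborhood ROI pixels whose level differs by at most `alpha`.
#' `D[level, dependence]` counts pixels, so the matrix total equals the ROI
#' pixel count.
#'
#' @param d a [discretize_roi()] result.
#' @param alpha nonnegative level-difference cutoff for dependence.
#' @return `texture_matrix` with one count matrix.
#' @export
build_gldm <- function(d, alpha = 0) {
  stopifnot(inherits(d, "discretized_roi"), alpha >= 0)
  L <- d$levels
  dep <- matrix(0L, nrow(L), ncol(L))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    L2 <- .shift_levels(L, dr, dc)
    dep <- dep + (!is.na(L) & !is.na(L2) & abs(L - L2) <= alpha)
  }
  ok <- !is.na(L)
  i <- L[ok]; j <- dep[ok] + 1L
  ng <- d$ng
  jmax <- max(j)
  D <- matrix(tabulate((j - 1L) * ng + i, nbins = ng * jmax), ng, jmax)
  .texture_matrix("GLDM", list(D), ng, d$np)
}

#' Neighboring gray-tone difference matrix
#'
#' For each occurring level `i`: the pixel count `n_i`, the probability
#' `p_i = n_i / N_p`, and `s_i`, the summed absolute differences between `i`
#' and the mean level of each pixel's 8-neighborhood ROI pixels. Pixels with
#' no ROI neighbor contribute 0 to `s` but still count in `n`.
#'
#' @param d a [discretize_roi()] result.
#' @return `texture_matrix` whose `matrices` slot holds the columns
#'   `cbind(n, p, s)` indexed by level.
#' @export
build_ngtdm <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  L <- d$levels
  nbr_sum <- matrix(0, nrow(L), ncol(L))
  nbr_cnt <- matrix(0L, nrow(L), ncol(L))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    L2 <- .shift_levels(L, dr, dc)
    has <- !is.na(L2)
    nbr_sum[has] <- nbr_sum[has] + L2[has]
    nbr_cnt <- nbr_cnt + has
  }
  ok <- !is.na(L)
  lv <- L[ok]
  cnt <- nbr_cnt[ok]
  avg <- ifelse(cnt > 0, nbr_sum[ok] / pmax(cnt, 1L), lv)  # zero deviation if isolated
  ng <- d$ng
  n <- tabulate(lv, nbins = ng)
  s <- vapply(seq_len(ng), function(g) sum(abs(g - avg[lv == g])), numeric(1))
  tab <- cbind(n = n, p = n / d$np, s = s)
  .texture_matrix("NGTDM", list(tab), ng, d$np)
}
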