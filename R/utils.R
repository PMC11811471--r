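#' @importFrom stats rnorm quantile sd var qf dnorm
#' @importFrom utils write.csv read.csv
NULL

# Largest prime below 2^31; all derived seeds live in [1, MOD-1] so they are
# valid 32-bit R integers.
.SEED_MOD <- 2147483647

#' Derive a reproducible child seed from a master seed and index path
#'
#' Counter-based scheme: the master seed is combined with an arbitrary path of
#' non-negative integer indices (subject, slice, run, ...) by a polynomial
#' hash modulo 2^31 - 1, so any single object of a cohort can be regenerated
#' in isolation without replaying the full stream.
#'
#' @param master integer master seed.
#' @param ... non-negative integer indices identifying the object.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.numeric(master) %% .SEED_MOD
  for (i in idx) {
    if (i < 0) stop("seed indices must be non-negative")
    s <- (s * 69069 + as.numeric(i) + 1) %% .SEED_MOD
  }
  as.integer(s %% (.SEED_MOD - 2) + 1)
}

# Row-stochastic 1D Gaussian smoothing operator of size n (sigma in pixels).
.gauss_operator <- function(n, sigma_px) {
  if (sigma_px <= 0) return(diag(n))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  w <- exp(-0.5 * (d / sigma_px)^2)
  w / rowSums(w)
}

# Standardized Gaussian random field: smoothed white noise with the stated
# correlation length (mm), rescaled to zero mean / unit sd over the grid.
# Caller is responsible for seeding.
.grf <- function(nrow, ncol, corr_length_mm, pixel_spacing) {
  z <- matrix(rnorm(nrow * ncol), nrow, ncol)
  sr <- .gauss_operator(nrow, corr_length_mm / pixel_spacing[1])
  sc <- .gauss_operator(ncol, corr_length_mm / pixel_spacing[2])
  f <- sr %*% z %*% t(sc)
  s <- stats::sd(f)
  if (s == 0) return(f * 0)
  (f - mean(f)) / s
}

# 8- (or 4-) connected component labels of a logical matrix.
# Returns an integer matrix, 0 outside the mask, labels 1..n_components.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  idx <- which(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(out)
  nr <- nrow(mask)
  nc <- ncol(mask)
  vid <- matrix(0L, nr, nc)
  vid[idx] <- seq_along(idx)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      from <- c(from, vid[cbind(rows[ok], cols[ok])])
      to <- c(to, vid[cbind(r2[ok], c2[ok])])
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

.assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lower, upper))
  invisible(x)
}
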