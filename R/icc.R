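#' Build a complete targets-by-raters measurement matrix
#'
#' @param data data.frame in long format.
#' @param target,rater,value column names.
#' @return numeric matrix, rows = targets, columns = raters/conditions.
#' @export
measurement_matrix <- function(data, target = "target", rater = "rater",
                               value = "value") {
  stopifnot(is.data.frame(data), all(c(target, rater, value) %in% names(data)))
  t_ <- factor(data[[target]])
  r_ <- factor(data[[rater]])
  m <- matrix(NA_real_, nlevels(t_), nlevels(r_),
              dimnames = list(levels(t_), levels(r_)))
  m[cbind(as.integer(t_), as.integer(r_))] <- data[[value]]
  if (anyNA(m)) stop("measurement table is incomplete (missing cells)")
  m
}

#' Two-way crossed ANOVA mean squares
#'
#' Row (target), column (rater/condition) and residual mean squares of the
#' two-way crossed layout without replication; the sums of squares satisfy
#' the reconstruction identity `SST = SSR + SSC + SSE`.
#'
#' @param m numeric matrix (targets x raters), `n >= 2` rows, `k >= 2`
#'   columns, no missing values.
#' @return list `msr`, `msc`, `mse`, `n`, `k`.
#' @export
two_way_mean_squares <- function(m) {
  if (is.data.frame(m)) m <- measurement_matrix(m)
  stopifnot(is.matrix(m), is.numeric(m))
  if (anyNA(m)) stop("measurement table is incomplete")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters")
  gm <- mean(m)
  ssr <- k * sum((rowMeans(m) - gm)^2)
  ssc <- n * sum((colMeans(m) - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  # snap components that are pure floating-point residue to exact zero
  tol <- 1e-12 * sst
  if (ssr < tol) ssr <- 0
  if (ssc < tol) ssc <- 0
  if (sse < tol) sse <- 0
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Four-tier reliability category of an ICC value
#'
#' Thresholds: excellent `ICC >= 0.95`, good `0.95 > ICC >= 0.75`, moderate
#' `0.75 > ICC >= 0.5`, poor `ICC < 0.5` (negative estimates are poor).
#'
#' @param value numeric vector of ICC point estimates (each <= 1).
#' @return character vector of category labels.
#' @export
icc_categorize <- function(value) {
  stopifnot(all(value <= 1 + 1e-12, na.rm = TRUE))
  out <- ifelse(value >= 0.95, "excellent",
         ifelse(value >= 0.75, "good",
         ifelse(value >= 0.5, "moderate", "poor")))
  out[is.na(value)] <- NA_character_
  out
}

#' Category labels in decreasing order of reliability
#' @return character vector of length 4.
#' @export
icc_categories <- function() c("excellent", "good", "moderate", "poor")

#' Intraclass correlation from a two-way layout
#'
#' Single-measurement and k-averaged ICCs of the two-way crossed design:
#' \itemize{
#'   \item `ICC(2,1)` two-way random effects, absolute agreement:
#'     `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#'   \item `ICC(3,1)` two-way mixed effects, consistency:
#'     `(MSR - MSE) / (MSR + (k-1) MSE)`
#'   \item `ICC(2,k)`: `(MSR - MSE) / (MSR + (MSC - MSE)/n)`
#'   \item `ICC(3,k)`: `(MSR - MSE) / MSR`
#' }
#' 95% confidence intervals use the standard F-distribution constructions of
#' McGraw & Wong for each model (upper bound truncated at 1; point estimates
#' are reported as computed, not clipped). A table with zero total variance
#' has no defined reliability and is flagged degenerate (`icc = NA`).
#'
#' @param m numeric targets-by-raters matrix (or long data.frame accepted by
#'   [measurement_matrix()]).
#' @param model one of `"icc2_1"`, `"icc3_1"`, `"icc2_k"`, `"icc3_k"`.
#' @param conf_level confidence level of the interval.
#' @return one-row data.frame: `model`, `icc`, `ci_lo`, `ci_hi`, `category`,
#'   `n`, `k`, `degenerate`.
#' @export
icc <- function(m, model = c("icc2_1", "icc3_1", "icc2_k", "icc3_k"),
                conf_level = 0.95) {
  model <- match.arg(model)
  if (is.data.frame(m)) m <- measurement_matrix(m)
  ms <- two_way_mean_squares(m)
  n <- ms$n; k <- ms$k
  label <- c(icc2_1 = "ICC(2,1)", icc3_1 = "ICC(3,1)",
             icc2_k = "ICC(2,k)", icc3_k = "ICC(3,k)")[[model]]
  if (stats::var(as.vector(m)) == 0) {
    return(data.frame(model = label, icc = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, category = NA_character_,
                      n = n, k = k, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  alpha <- 1 - conf_level
  # perfect-agreement limits: the F constructions degenerate when MSE = 0
  if (mse <= 0 && msc <= 0) {
    return(data.frame(model = label, icc = 1, ci_lo = 1, ci_hi = 1,
                      category = "excellent", n = n, k = k,
                      degenerate = FALSE, stringsAsFactors = FALSE))
  }
  if (mse <= 0 && model %in% c("icc3_1", "icc3_k")) {
    return(data.frame(model = label, icc = 1, ci_lo = 1, ci_hi = 1,
                      category = "excellent", n = n, k = k,
                      degenerate = FALSE, stringsAsFactors = FALSE))
  }
  if (model %in% c("icc2_1", "icc2_k")) {
    val1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    # Satterthwaite df for the absolute-agreement interval
    a <- (k * val1) / (n * (1 - val1))
    b <- 1 + (k * val1 * (n - 1)) / (n * (1 - val1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    # near-perfect agreement drives v astronomically large; the F quantile is
    # then at its infinite-df limit, which qf evaluates exactly
    if (!is.finite(v) || v > 1e7) v <- Inf
    f_u <- qf(1 - alpha / 2, n - 1, v)
    f_l <- qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi1 <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
    if (model == "icc2_1") {
      val <- val1; lo <- lo1; hi <- hi1
    } else {
      val <- (msr - mse) / (msr + (msc - mse) / n)
      lo <- k * lo1 / (1 + (k - 1) * lo1)
      hi <- k * hi1 / (1 + (k - 1) * hi1)
    }
  } else {
    fstat <- msr / mse
    df2 <- (n - 1) * (k - 1)
    f_u <- qf(1 - alpha / 2, n - 1, df2)
    f_l <- qf(1 - alpha / 2, df2, n - 1)
    if (model == "icc3_1") {
      val <- (msr - mse) / (msr + (k - 1) * mse)
      lo <- (fstat / f_u - 1) / (fstat / f_u + k - 1)
      hi <- (fstat * f_l - 1) / (fstat * f_l + k - 1)
    } else {
      val <- (msr - mse) / msr
      lo <- 1 - f_u / fstat
      hi <- 1 - 1 / (fstat * f_l)
    }
  }
  if (!is.finite(val)) {
    return(data.frame(model = label, icc = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, category = NA_character_,
                      n = n, k = k, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  hi <- min(hi, 1)
  data.frame(model = label, icc = val, ci_lo = lo, ci_hi = hi,
             category = icc_categorize(val), n = n, k = k,
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Screen degenerate features before reliability estimation
#'
#' A feature is excluded when it is constant across every observation (zero
#' variance, reliability undefined) or contains non-finite values. Screening
#' is applied globally, across all conditions, before any per-condition
#' analysis.
#'
#' @param data long-format data.frame with columns `feature` and `value`.
#' @return list with `kept` (character vector of feature names) and
#'   `excluded` (data.frame `feature`, `reason`).
#' @export
screen_degenerate <- function(data) {
  stopifnot(is.data.frame(data), all(c("feature", "value") %in% names(data)))
  feats <- split(data$value, data$feature)
  reason <- vapply(feats, function(v) {
    if (any(!is.finite(v))) "non-finite values"
    else if (max(v) - min(v) == 0) "zero variance"
    else ""
  }, character(1))
  excluded <- data.frame(feature = names(reason)[reason != ""],
                         reason = unname(reason[reason != ""]),
                         stringsAsFactors = FALSE)
  list(kept = names(reason)[reason == ""], excluded = excluded)
}

#' Per-feature ICC estimation from a long table
#'
#' @param data long-format data.frame with columns `target`, `rater`,
#'   `feature`, `value`; every feature must form a complete balanced grid.
#' @param model passed to [icc()].
#' @return data.frame with one row per feature (columns of [icc()] plus
#'   `feature`).
#' @export
icc_by_feature <- function(data, model = "icc2_1") {
  stopifnot(all(c("target", "rater", "feature", "value") %in% names(data)))
  out <- lapply(split(data, data$feature), function(df) {
    est <- icc(measurement_matrix(df), model = model)
    est$feature <- df$feature[1]
    est
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("feature", setdiff(names(res), "feature"))]
}

# Parse "(filter)_(class)_(feature)" names; filter labels contain no "_".
.parse_feature_name <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)
  data.frame(filter = vapply(parts, `[`, "", 1),
             class = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Robustness breakdown of ICC estimates by filter class or feature class
#'
#' Counts and proportions of features in each reliability category per group,
#' plus the highest-ICC feature of each group. Proportions per group sum to 1
#' over the four categories.
#'
#' @param estimates data.frame from [icc_by_feature()] (kept features only).
#' @param group_axis `"filter"`, `"class"`, or `"overall"`.
#' @return list with `proportions` (long data.frame: group, category, count,
#'   proportion) and `top_features` (best feature per group).
#' @export
reliability_breakdown <- function(estimates,
                                  group_axis = c("filter", "class", "overall")) {
  group_axis <- match.arg(group_axis)
  stopifnot(all(c("feature", "icc", "category") %in% names(estimates)))
  est <- estimates[!is.na(estimates$icc), , drop = FALSE]
  meta <- .parse_feature_name(est$feature)
  grp <- switch(group_axis, filter = meta$filter, class = meta$class,
                overall = rep("overall", nrow(est)))
  cat_f <- factor(est$category, levels = icc_categories())
  tab <- table(group = grp, category = cat_f)
  props <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(props) <- c("group", "category", "count")
  totals <- stats::ave(props$count, props$group, FUN = sum)
  props$proportion <- ifelse(totals > 0, props$count / totals, 0)
  top <- do.call(rbind, lapply(split(est, grp), function(df) {
    best <- df[which.max(df$icc), , drop = FALSE]
    data.frame(group = grp[match(best$feature, est$feature)][1],
               feature = best$feature, icc = best$icc,
               ci_lo = best$ci_lo, ci_hi = best$ci_hi,
               stringsAsFactors = FALSE)
  }))
  rownames(top) <- NULL
  list(proportions = props, top_features = top, group_axis = group_axis)
}
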