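#' Wilcoxon matched-pairs signed rank test
#'
#' Compares paired per-experiment medians (e.g. the CD32 thresholds of
#' non-allergic versus allergic donors within each experiment). Zero
#' differences are discarded (classic convention); ranks of the absolute
#' differences use midranks for ties. For `n <= 12` usable pairs the
#' two-sided p-value is computed by exact enumeration of all `2^n` sign
#' assignments; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used. The z statistic (signed
#' so that predominantly positive differences give positive z) is
#' reported in both regimes, together with the per-experiment
#' higher/lower/equal counts.
#'
#' @param a,b paired numeric vectors (`a - b` is tested), or `b = NULL`
#'   and `a` already the vector of differences.
#' @param exact_max largest n for the exact-enumeration path
#'   (default 12).
#' @return list: `z_statistic`, `two_tailed_p`, `method`
#'   (`"exact"`/`"asymptotic"`/`"degenerate"`), `n_used`, `n_higher`,
#'   `n_lower`, `n_equal`, `w_plus`.
#' @export
wilcoxon_matched_pairs <- function(a, b = NULL, exact_max = 12L) {
  d <- if (is.null(b)) as.numeric(a) else as.numeric(a) - as.numeric(b)
  if (any(!is.finite(d))) stop_binbat("binbat_config_error", "differences must be finite")
  n_higher <- sum(d > 0); n_lower <- sum(d < 0); n_equal <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warn_binbat("binbat_degenerate", "all differences are zero; test degenerate")
    return(list(z_statistic = 0, two_tailed_p = 1, method = "degenerate",
                n_used = 0L, n_higher = n_higher, n_lower = n_lower,
                n_equal = n_equal, w_plus = 0))
  }
  r <- rank(abs(d))  # midranks for ties
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) {
    cc <- 0.5 * sign(w_plus - mu)
    (w_plus - mu - cc) / sqrt(sigma2)
  } else 0
  if (n <= exact_max) {
    # enumerate all sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p_ge <- mean(w_all >= w_plus)
    p_le <- mean(w_all <= w_plus)
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "asymptotic"
  }
  list(z_statistic = z, two_tailed_p = p, method = method, n_used = n,
       n_higher = n_higher, n_lower = n_lower, n_equal = n_equal, w_plus = w_plus)
}

#' Pearson correlation with t-distribution p-value
#'
#' @param a,b numeric vectors of equal length >= 3, neither constant.
#' @return list `r`, `r_squared`, `p` (two-sided).
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop_binbat("binbat_config_error", "pearson_r needs two equal-length vectors, length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_binbat("binbat_degenerate", "correlation undefined for a constant vector")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2, p = ct$p.value)
}

#' Flag agreement outliers by the Q3 + 1.5 IQR rule
#'
#' An auto-vs-manual difference is an outlier when its magnitude exceeds
#' Q3 + 1.5 * IQR of the absolute differences, with nearest-rank
#' quartiles.
#'
#' @param diffs numeric vector of differences, length >= 4.
#' @return logical mask, `TRUE` where flagged; attribute `"threshold"`.
#' @export
flag_outliers <- function(diffs) {
  if (length(diffs) < 4) stop_binbat("binbat_config_error", "flag_outliers needs >= 4 values")
  ad <- abs(diffs)
  q <- nearest_rank_quantile(ad, c(0.25, 0.75))
  thr <- q[2] + 1.5 * (q[2] - q[1])
  mask <- ad > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Tally per-experiment cohort direction
#'
#' For each experiment, the sign of (non-allergic median - allergic
#' median) is tallied into higher / lower / equal counts (the
#' bar-summary view of a paired cohort).
#'
#' @param non_allergic,allergic paired numeric vectors of per-experiment
#'   medians.
#' @return list `n_higher`, `n_lower`, `n_equal`, `n`.
#' @export
classify_experiments <- function(non_allergic, allergic) {
  if (length(non_allergic) != length(allergic))
    stop_binbat("binbat_config_error", "paired vectors must have equal length")
  if (any(!is.finite(non_allergic)) || any(!is.finite(allergic)))
    stop_binbat("binbat_config_error", "medians must be complete (finite) for tested experiments")
  d <- non_allergic - allergic
  list(n_higher = sum(d > 0), n_lower = sum(d < 0), n_equal = sum(d == 0),
       n = length(d))
}

#' Build an auto-vs-manual agreement table
#'
#' @param auto,manual paired CD63+% vectors (one entry per sample).
#' @param sample_ids optional identifiers.
#' @return data.frame `sample_id`, `auto`, `manual`, `difference`,
#'   `outlier`; attributes `"pearson"` (list from [pearson_r()]) and
#'   `"outlier_threshold"`.
#' @export
agreement_table <- function(auto, manual, sample_ids = seq_along(auto)) {
  mask <- flag_outliers(auto - manual)
  pr <- pearson_r(auto, manual)
  out <- data.frame(sample_id = sample_ids, auto = auto, manual = manual,
                    difference = auto - manual, outlier = as.logical(mask))
  attr(out, "pearson") <- pr
  attr(out, "outlier_threshold") <- attr(mask, "threshold")
  out
}
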