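#' Nearest-rank quantile
#'
#' Quantile by the nearest-rank definition: for probability `p` in (0, 1]
#' the value at rank `ceiling(p * n)` of the sorted vector; `p = 0` returns
#' the minimum. This convention is used throughout the package (threshold
#' calibration, quartiles, violin trimming) because it always returns an
#' observed value, which makes positive-event counts under a
#' strictly-greater-than positivity rule exactly reproducible.
#'
#' @param x numeric vector, no NAs.
#' @param p probability in \[0, 1\] (may be a vector).
#' @return numeric vector of quantile values, same length as `p`.
#' @export
nearest_rank_quantile <- function(x, p) {
  if (length(x) == 0L) stop("nearest_rank_quantile: empty vector")
  if (any(!is.finite(x))) stop("nearest_rank_quantile: non-finite values")
  if (any(p < 0 | p > 1)) stop("nearest_rank_quantile: p outside [0, 1]")
  xs <- sort(x)
  n <- length(xs)
  idx <- pmax(1L, as.integer(ceiling(p * n)))
  xs[idx]
}

# Deterministic sub-seed derivation: keeps derived seeds positive and
# below 2^31 for any master seed and index.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_binbat <- function(class, msg) {
  stop(structure(
    class = c(class, "binbat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

warn_binbat <- function(class, msg) {
  warning(structure(
    class = c(class, "binbat_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
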