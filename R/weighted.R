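#' Survey-weighted mean
#'
#' Mean of `x` with expansion (frequency-type) weights `w`. For integer
#' weights this equals the unweighted mean of the expanded data set in which
#' each observation is replicated `w` times.
#'
#' @param x numeric vector.
#' @param w positive numeric weights, recycled to `length(x)`.
#' @return length-1 numeric.
#' @export
weighted_mean <- function(x, w = rep(1, length(x))) {
  w <- rep_len(w, length(x))
  stopifnot(all(is.finite(x)), all(is.finite(w)), all(w > 0))
  sum(w * x) / sum(w)
}

#' Survey-weighted standard deviation
#'
#' Expansion-weight analogue of the population standard deviation:
#' `sqrt(sum(w * (x - m)^2) / sum(w))`. Used for the mean (SD) cells of the
#' consumption and BMI summary tables.
#'
#' @inheritParams weighted_mean
#' @return length-1 numeric.
#' @export
weighted_sd <- function(x, w = rep(1, length(x))) {
  m <- weighted_mean(x, w)
  w <- rep_len(w, length(x))
  sqrt(sum(w * (x - m)^2) / sum(w))
}

#' Survey-weighted quantiles
#'
#' Weighted generalisation of the type-7 quantile. Observations are sorted
#' and each assigned the normalised plotting position
#' `u_i = C_{i-1} / (W - w_i)` where `C_{i-1}` is the cumulative weight of
#' all smaller observations and `W = sum(w)`; quantiles interpolate
#' linearly between adjacent positions. With equal weights this reduces
#' exactly to `stats::quantile(..., type = 7)`, and the positions depend on
#' weights only through their ratios, so rescaling all weights by a common
#' factor leaves every quantile unchanged. For integer expansion weights
#' the result agrees with type-7 quantiles of the replicated data set up to
#' terms of order `max(w)/W`.
#'
#' @inheritParams weighted_mean
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector the length of `probs`, named like
#'   `stats::quantile`.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs = c(0.25, 0.5, 0.75)) {
  w <- rep_len(w, length(x))
  stopifnot(length(x) > 0, all(is.finite(x)), all(w > 0),
            all(probs >= 0), all(probs <= 1))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  if (length(x) == 1) {
    out <- rep(x, length(probs))
    names(out) <- paste0(format(100 * probs, trim = TRUE), "%")
    return(out)
  }
  cw <- cumsum(w)
  W <- cw[length(cw)]
  u <- (cw - w) / (W - w)   # u_1 = 0, u_n = 1, non-decreasing
  out <- vapply(probs, function(p) stats::approx(u, x, xout = p, ties = "ordered")$y,
                numeric(1))
  names(out) <- paste0(format(100 * probs, trim = TRUE), "%")
  out
}
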