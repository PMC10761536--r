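#' Percent coefficient of variation of a replicate run
#'
#' Precision (intra-assay repeatability) of a meter from replicate readings
#' of the same sample: `CV% = SD / mean * 100`, with the sample (n - 1)
#' standard deviation. Scale-invariant and zero when all replicates agree.
#'
#' @param replicates Numeric vector of at least two replicate readings with
#'   positive mean.
#' @return CV as a percentage (unrounded; round only at report time).
#' @export
cv_percent <- function(replicates) {
  if (length(replicates) < 2) {
    stop("need at least 2 replicates to estimate CV", call. = FALSE)
  }
  m <- mean(replicates)
  if (!is.finite(m) || m <= 0) {
    stop("CV undefined: replicate mean must be positive", call. = FALSE)
  }
  sd(replicates) / m * 100
}

#' Percent bias of a POC meter against the reference method
#'
#' Signed mean-level inaccuracy,
#' `Bias% = (mean(reference) - mean(POC)) / mean(reference) * 100`
#' (reference minus POC in the numerator, so a meter that reads high gives
#' a negative bias under this convention).
#'
#' @param poc,ref Equal-length numeric vectors of paired readings;
#'   `mean(ref)` must be positive.
#' @return Signed percent bias.
#' @export
bias_percent <- function(poc, ref) {
  if (length(poc) != length(ref)) {
    stop("poc and ref must have equal length", call. = FALSE)
  }
  mr <- mean(ref)
  if (!is.finite(mr) || mr <= 0) {
    stop("bias undefined: mean reference must be positive", call. = FALSE)
  }
  (mr - mean(poc)) / mr * 100
}

#' Observed total error
#'
#' Westgard-style combined quality metric `TE_obs% = 2 * CV% + Bias%`. By
#' default the bias magnitude is used, since observed total error is a
#' magnitude-style metric; set `signed_bias = TRUE` to propagate the sign.
#'
#' @param cv_pct Replicate CV as a percentage.
#' @param bias_pct Percent bias (signed; see `signed_bias`).
#' @param signed_bias Use the signed bias rather than its magnitude.
#' @return Observed total error as a percentage.
#' @export
total_error_observed <- function(cv_pct, bias_pct, signed_bias = FALSE) {
  b <- if (signed_bias) bias_pct else abs(bias_pct)
  2 * cv_pct + b
}

#' Percent relative error of individual paired readings
#'
#' `RelativeError% = (POC - reference) / reference * 100`, per pair.
#'
#' @param poc,ref Numeric vectors (recycled as usual); all `ref` entries
#'   must be positive.
#' @return Signed percent relative error, vectorised.
#' @export
relative_error <- function(poc, ref) {
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    stop("relative error undefined: reference values must be positive",
         call. = FALSE)
  }
  (poc - ref) / ref * 100
}

#' Proportion of readings inside relative-error zones
#'
#' For each threshold `t`, the percentage of pairs whose absolute percent
#' relative error is strictly below `t`. The default thresholds 12/15/20%
#' are the FDA human-glucometer accuracy bands. Monotone non-decreasing in
#' the threshold by construction.
#'
#' @param poc,ref Equal-length numeric vectors of paired readings.
#' @param thresholds Numeric vector of zone thresholds (percent).
#' @return Named numeric vector of percentages in `[0, 100]`, one per
#'   threshold.
#' @export
zone_proportions <- function(poc, ref, thresholds = c(12, 15, 20)) {
  if (length(poc) != length(ref) || length(poc) < 1) {
    stop("need at least one POC/reference pair", call. = FALSE)
  }
  re <- abs(relative_error(poc, ref))
  out <- vapply(thresholds, function(t) 100 * mean(re < t), numeric(1))
  names(out) <- paste0("zone", thresholds)
  out
}

#' Summary statistics with censoring awareness
#'
#' Compiles n, mean, SD, median, min and max on (post-imputation) values,
#' recording whether the minimum is an imputed below-LLOQ reading so reports
#' can render it as `"< LLOQ"` rather than as a number.
#'
#' @param values Numeric vector (imputed values for censored readings).
#' @param censored Logical vector marking imputed entries.
#' @param lloq The LLOQ to use when rendering a censored minimum (optional).
#' @return One-row tibble: `n, mean, sd, median, min, max, n_censored,
#'   any_censored_min, min_label`. `sd` is reported as 0 with
#'   `sd_defined = FALSE` when `n = 1`.
#' @export
summary_stats <- function(values, censored = rep(FALSE, length(values)),
                          lloq = NA_real_) {
  n <- length(values)
  if (n < 1) stop("need at least one value", call. = FALSE)
  stopifnot(length(censored) == n)
  mn <- min(values)
  any_cen_min <- any(censored & values == mn)
  min_label <- if (any_cen_min && is.finite(lloq)) {
    paste0("< ", format(lloq, trim = TRUE))
  } else {
    format(mn, trim = TRUE)
  }
  tibble::tibble(
    n = n,
    mean = mean(values),
    sd = if (n > 1) sd(values) else 0,
    sd_defined = n > 1,
    median = median(values),
    min = mn,
    max = max(values),
    n_censored = sum(censored),
    any_censored_min = any_cen_min,
    min_label = min_label
  )
}
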