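#' Bland-Altman agreement analysis
#'
#' Computes the mean difference (bias) between a point-of-care meter and the
#' reference method, the 95% limits of agreement
#' `LoA = mean(d) +/- 1.96 * sd(d)` on the differences `d = poc - ref`, and
#' confidence intervals: the bias CI is the exact t interval
#' `mean(d) +/- t * sd(d)/sqrt(n)`, and each LoA CI uses the classical
#' large-sample approximation `Var(LoA) ~ 3 * sd(d)^2 / n` with the same t
#' quantile (df = n - 1). The 1.96 multiplier in the LoA itself is fixed (a
#' normal 95% band on individual differences), while the CIs use t; this is
#' the standard presentation. Bias is flagged statistically significant when
#' the bias CI excludes 0.
#'
#' @param poc,ref Equal-length numeric vectors (n >= 3) of paired readings.
#' @param alpha Two-sided CI level is `1 - alpha` (default 0.05).
#' @param loa_quantile Multiplier for the limits of agreement (default 1.96).
#' @param ci_quantile `"t"` (default) or `"z"` for the CI quantile.
#' @return An object of class `ba_result`: `n`, `mean_bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `ci_bias`, `ci_loa_lower`, `ci_loa_upper`
#'   (each a length-2 numeric), and `significant_bias`.
#' @export
bland_altman <- function(poc, ref, alpha = 0.05, loa_quantile = 1.96,
                         ci_quantile = c("t", "z")) {
  if (length(poc) != length(ref)) {
    stop("poc and ref must have equal length", call. = FALSE)
  }
  n <- length(poc)
  if (n < 3) stop("Bland-Altman requires n >= 3 pairs", call. = FALSE)
  ci_quantile <- match.arg(ci_quantile)
  d <- poc - ref
  m <- mean(d)
  s <- sd(d)
  q <- if (ci_quantile == "t") qt(1 - alpha / 2, df = n - 1)
       else qnorm(1 - alpha / 2)
  loa_lower <- m - loa_quantile * s
  loa_upper <- m + loa_quantile * s
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  ci_bias <- c(m - q * se_bias, m + q * se_bias)
  out <- list(
    n = n,
    mean_bias = m,
    sd_diff = s,
    loa_lower = loa_lower,
    loa_upper = loa_upper,
    ci_bias = ci_bias,
    ci_loa_lower = c(loa_lower - q * se_loa, loa_lower + q * se_loa),
    ci_loa_upper = c(loa_upper - q * se_loa, loa_upper + q * se_loa),
    significant_bias = !(ci_bias[1] <= 0 && 0 <= ci_bias[2]),
    alpha = alpha
  )
  class(out) <- "ba_result"
  out
}

#' @export
print.ba_result <- function(x, digits = 3, ...) {
  fmt <- function(v) format(round(v, digits), trim = TRUE)
  ci <- function(v) paste0("(", fmt(v[1]), ", ", fmt(v[2]), ")")
  cat("Bland-Altman agreement (n = ", x$n, ")\n", sep = "")
  cat("  Mean bias: ", fmt(x$mean_bias), " ", ci(x$ci_bias),
      if (x$significant_bias) " *" else "", "\n", sep = "")
  cat("  Lower LoA: ", fmt(x$loa_lower), " ", ci(x$ci_loa_lower), "\n",
      sep = "")
  cat("  Upper LoA: ", fmt(x$loa_upper), " ", ci(x$ci_loa_upper), "\n",
      sep = "")
  invisible(x)
}

#' Per-pair plot data for a Bland-Altman plot
#'
#' Returns one (pair mean, difference) point per animal plus the horizontal
#' reference lines (bias, both LoAs and their CI bounds), ready for any
#' plotting layer.
#'
#' @inheritParams bland_altman
#' @param exclude_ids Optional animal ids to drop from the plotted points
#'   (the agreement statistics in `lines` are still computed on all pairs).
#' @param animal_ids Optional ids aligned with `poc`/`ref`, required when
#'   `exclude_ids` is used.
#' @return A list with a tibble `points` (`animal_id, pair_mean, difference`)
#'   and a named numeric `lines`.
#' @export
ba_plot_data <- function(poc, ref, alpha = 0.05, exclude_ids = NULL,
                         animal_ids = NULL) {
  fit <- bland_altman(poc, ref, alpha = alpha)
  if (is.null(animal_ids)) animal_ids <- as.character(seq_along(poc))
  pts <- tibble::tibble(
    animal_id = animal_ids,
    pair_mean = (poc + ref) / 2,
    difference = poc - ref
  )
  if (!is.null(exclude_ids)) {
    dropped <- intersect(exclude_ids, pts$animal_id)
    if (length(dropped) > 0) {
      message("ba_plot_data: excluding ", length(dropped), " animal(s): ",
              paste(dropped, collapse = ", "))
    }
    pts <- pts[!pts$animal_id %in% exclude_ids, ]
  }
  list(
    points = pts,
    lines = c(
      mean_bias = fit$mean_bias,
      loa_lower = fit$loa_lower,
      loa_upper = fit$loa_upper,
      ci_bias_lo = fit$ci_bias[1], ci_bias_hi = fit$ci_bias[2],
      ci_loa_lower_lo = fit$ci_loa_lower[1],
      ci_loa_lower_hi = fit$ci_loa_lower[2],
      ci_loa_upper_lo = fit$ci_loa_upper[1],
      ci_loa_upper_hi = fit$ci_loa_upper[2]
    )
  )
}
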