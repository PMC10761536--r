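#' Pairwise slopes for Passing-Bablok regression
#'
#' Computes the multiset of slopes `S_ij = (y_j - y_i) / (x_j - x_i)` over
#' all point pairs `i < j`, with the method's degenerate-pair rules: pairs
#' identical in both coordinates are dropped; pairs with `x_i == x_j` but
#' differing `y` contribute a signed infinite slope; slopes exactly equal to
#' -1 are dropped. `K`, the count of remaining slopes below -1, is the
#' offset that makes the slope estimator median-unbiased under the method's
#' symmetry assumption.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A list: `slopes` (ascending), `K`, and `N = length(slopes)`.
#' @export
pairwise_slopes <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(2:n, function(k) k:n), use.names = FALSE)
  dx <- x[j] - x[i]
  dy <- y[j] - y[i]
  both_zero <- dx == 0 & dy == 0
  dx <- dx[!both_zero]
  dy <- dy[!both_zero]
  if (length(dx) == 0) {
    stop("all points identical: Passing-Bablok slopes undefined",
         call. = FALSE)
  }
  slopes <- ifelse(dx == 0, sign(dy) * Inf, dy / dx)
  slopes <- slopes[slopes != -1]
  if (length(slopes) == 0) {
    stop("no valid pairwise slopes remain after exclusions", call. = FALSE)
  }
  slopes <- sort(slopes)
  list(slopes = slopes, K = sum(slopes < -1), N = length(slopes))
}

# round-half-away-from-zero (base round() is round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Passing-Bablok rank regression
#'
#' Nonparametric structural regression for method comparison: the slope is
#' the shifted median of all pairwise slopes (offset `K` = number of slopes
#' below -1, after dropping slopes equal to -1), the intercept is
#' `median(y - slope * x)`, and confidence intervals come from the rank
#' statistic `C = z * sqrt(n (n-1) (2n+5) / 18)`: with `M1 =
#' round((N - C)/2)` (half away from zero) and `M2 = N - M1 + 1`, the slope
#' CI is `(S[M1+K], S[M2+K])` and the intercept CI re-fits the intercept at
#' the slope bounds (upper slope bound gives the lower intercept bound).
#' Constant bias is flagged when the intercept CI excludes 0, proportional
#' bias when the slope CI excludes 1. The method assumes a positive
#' association between the two measurement methods.
#'
#' @param x Reference method values.
#' @param y POC (test) method values.
#' @param alpha Two-sided CI level is `1 - alpha` (default 0.05).
#' @return An object of class `pb_fit`: `n`, `N_slopes`, `K`, `slope`,
#'   `ci_slope`, `intercept`, `ci_intercept`, `constant_bias`,
#'   `proportional_bias`.
#' @export
pb_fit <- function(x, y, alpha = 0.05) {
  n <- length(x)
  ps <- pairwise_slopes(x, y)
  if (n < 10) {
    warning("Passing-Bablok with n < 10 pairs; confidence intervals are ",
            "unreliable at this sample size", call. = FALSE)
  }
  S <- ps$slopes
  N <- ps$N
  K <- ps$K
  if (N %% 2 == 1) {
    b <- S[(N + 1) / 2 + K]
  } else {
    b <- mean(S[c(N / 2 + K, N / 2 + 1 + K)])
  }
  C <- qnorm(1 - alpha / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round_half_away((N - C) / 2)
  M2 <- N - M1 + 1
  if (M1 + K < 1 || M2 + K > N) {
    stop("Passing-Bablok CI undefined at this n/alpha (rank index outside ",
         "the slope multiset)", call. = FALSE)
  }
  ci_slope <- c(S[M1 + K], S[M2 + K])
  a <- median(y - b * x)
  ci_intercept <- c(median(y - ci_slope[2] * x), median(y - ci_slope[1] * x))
  out <- list(
    n = n,
    N_slopes = N,
    K = K,
    slope = b,
    ci_slope = ci_slope,
    intercept = a,
    ci_intercept = ci_intercept,
    constant_bias = !(ci_intercept[1] <= 0 && 0 <= ci_intercept[2]),
    proportional_bias = !(ci_slope[1] <= 1 && 1 <= ci_slope[2]),
    alpha = alpha
  )
  class(out) <- "pb_fit"
  out
}

#' @export
print.pb_fit <- function(x, digits = 3, ...) {
  fmt <- function(v) format(round(v, digits), trim = TRUE)
  cat("Passing-Bablok regression (n = ", x$n, ", ", x$N_slopes,
      " pairwise slopes, K = ", x$K, ")\n", sep = "")
  cat("  Intercept: ", fmt(x$intercept), " (", fmt(x$ci_intercept[1]), ", ",
      fmt(x$ci_intercept[2]), ")",
      if (x$constant_bias) " * constant bias" else "", "\n", sep = "")
  cat("  Slope:     ", fmt(x$slope), " (", fmt(x$ci_slope[1]), ", ",
      fmt(x$ci_slope[2]), ")",
      if (x$proportional_bias) " * proportional bias" else "", "\n", sep = "")
  invisible(x)
}

#' Brute-force Passing-Bablok oracle
#'
#' Independent re-derivation of the Passing-Bablok point estimates by
#' literal double-loop enumeration of all C(n,2) slopes with the same
#' exclusion rules, written as a separate code path for testing. Not for
#' production use (quadratic loops, n <= 200).
#'
#' @param x,y Equal-length numeric vectors, n <= 200.
#' @return A list with `slope` and `intercept`.
#' @export
pb_oracle <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3, n <= 200)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      run <- x[j] - x[i]
      rise <- y[j] - y[i]
      if (run == 0 && rise == 0) next
      s <- if (run == 0) {
        if (rise > 0) Inf else -Inf
      } else {
        rise / run
      }
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  if (length(slopes) == 0) stop("no valid slopes", call. = FALSE)
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- 0
  for (s in slopes) if (s < -1) K <- K + 1
  if (N %% 2 == 1) {
    b <- slopes[(N + 1) %/% 2 + K]
  } else {
    b <- (slopes[N %/% 2 + K] + slopes[N %/% 2 + 1 + K]) / 2
  }
  resid <- sort(y - b * x)
  m <- length(resid)
  a <- if (m %% 2 == 1) resid[(m + 1) %/% 2] else
    (resid[m %/% 2] + resid[m %/% 2 + 1]) / 2
  list(slope = b, intercept = a)
}

#' Regression-line plot data for a Passing-Bablok fit
#'
#' @param x,y As in [pb_fit()].
#' @param alpha CI level.
#' @param exclude_ids,animal_ids As in [ba_plot_data()]: excluded animals are
#'   removed from the plotted points only.
#' @return A list with tibble `points` (`animal_id, ref, poc`) and `fit`
#'   (the `pb_fit` on all pairs).
#' @export
pb_plot_data <- function(x, y, alpha = 0.05, exclude_ids = NULL,
                         animal_ids = NULL) {
  fit <- pb_fit(x, y, alpha = alpha)
  if (is.null(animal_ids)) animal_ids <- as.character(seq_along(x))
  pts <- tibble::tibble(animal_id = animal_ids, ref = x, poc = y)
  if (!is.null(exclude_ids)) pts <- pts[!pts$animal_id %in% exclude_ids, ]
  list(points = pts, fit = fit)
}
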