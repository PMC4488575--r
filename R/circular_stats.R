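#' Wrap an angle into (-180, 180]
#'
#' Reduces any finite angle (in degrees) modulo 360 into the half-open
#' interval (-180, 180]. By convention -180 maps to +180, so the antipode of
#' the reference direction has a single representation.
#'
#' @param x Numeric vector of angles in degrees (any real values).
#' @return Numeric vector of the same length, each element in (-180, 180].
#' @examples
#' wrap_degrees(c(190, -180, 361.5))
#' @export
wrap_degrees <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("wrap_degrees: input must be finite numeric", call. = FALSE)
  }
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w[w == -180] <- 180
  w
}

#' Circular summary: mean direction and mean resultant length
#'
#' Computes the first trigonometric moment of a sample of angles. The mean
#' direction is the atan2 of the mean sine and cosine; the mean resultant
#' length R is the norm of the mean unit vector, 0 for a perfectly balanced
#' sample and 1 for total concentration.
#'
#' @param angles_deg Numeric vector of angles in degrees.
#' @return A list of class `circ_summary` with elements `n`,
#'   `mean_direction_deg` (in (-180, 180], `NA` when undefined),
#'   `resultant_length`, and `direction_defined` (FALSE when R is numerically
#'   zero, in which case the mean direction is meaningless).
#' @examples
#' circ_summary(c(0, 90))          # direction 45, R = sqrt(2)/2
#' circ_summary(c(0, 90, 180, 270)) # R = 0, direction undefined
#' @export
circ_summary <- function(angles_deg) {
  if (length(angles_deg) < 1L) stop("circ_summary: empty angle set", call. = FALSE)
  a <- wrap_degrees(angles_deg) * pi / 180
  C <- mean(cos(a))
  S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  defined <- R > 1e-12
  out <- list(
    n = length(a),
    mean_direction_deg = if (defined) wrap_degrees(atan2(S, C) * 180 / pi) else NA_real_,
    resultant_length = R,
    direction_defined = defined
  )
  class(out) <- "circ_summary"
  out
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("Circular summary: n = %d, R = %.4f, mean direction = %s\n",
              x$n, x$resultant_length,
              if (x$direction_defined) sprintf("%.2f deg", x$mean_direction_deg)
              else "undefined"))
  invisible(x)
}

# Internal: clamp a p-value into (0, 1] so downstream log-reporting is safe.
clamp_p <- function(p) min(max(p, .Machine$double.xmin), 1)

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis of a uniform circular distribution against a
#' unimodal alternative. The statistic is Z = n * R^2 where R is the mean
#' resultant length; the p-value uses the standard small-sample-corrected
#' approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`, clamped into (0, 1].
#'
#' @param angles_deg Numeric vector of angles in degrees, length >= 2.
#' @param criterion Significance criterion for the `significant` flag
#'   (default 0.05; use [bonferroni_plan()] criteria for corrected families).
#' @return A list of class `circ_test` with `test = "rayleigh"`, `statistic`
#'   (Z), `p_value`, `summary` (a `circ_summary`), `criterion`, `significant`.
#' @examples
#' rayleigh_test(rep(90, 10))  # R = 1, Z = 10, p << 0.001
#' @export
rayleigh_test <- function(angles_deg, criterion = 0.05) {
  n <- length(angles_deg)
  if (n < 2L) stop("rayleigh_test: need at least 2 angles", call. = FALSE)
  s <- circ_summary(angles_deg)
  R <- s$resultant_length
  Z <- n * R^2
  p <- clamp_p(exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n)))
  structure(list(test = "rayleigh", statistic = Z, p_value = p, summary = s,
                 criterion = criterion, significant = p < criterion),
            class = "circ_test")
}

# Internal: Hodges-Ajne statistic m = minimum, over all half-circles, of the
# number of sample points the half-circle contains. Half-circles are closed on
# the leading boundary and open on the trailing one ([theta, theta + 180)), so
# a point antipodal to the boundary is counted exactly once. The minimum over
# continuously rotating half-circles is attained either at a boundary passing
# through a data point or one of its antipodes, evaluated from both sides; the
# scan below checks all 2n such candidates with O(n log n) binary searches.
ajne_statistic <- function(angles_deg) {
  u <- sort((angles_deg %% 360) * pi / 180)
  n <- length(u)
  v <- c(u, u + 2 * pi)
  cand <- sort(c(u, (u + pi) %% (2 * pi)))
  # count in [theta, theta + pi): strict counts of v below each endpoint
  closed_lead <- findInterval(cand + pi, v, left.open = TRUE) -
    findInterval(cand, v, left.open = TRUE)
  # count in (theta, theta + pi]: the limit just past each candidate boundary
  open_lead <- findInterval(cand + pi, v) - findInterval(cand, v)
  min(closed_lead, open_lead)
}

# Internal: p-value for the Hodges-Ajne statistic. For n <= n_exact and
# m < n/3 the exact null tail P(M <= m) = (n - 2m) C(n, m) 2^(1 - n),
# evaluated in log space. Otherwise the large-sample approximation
# p = sqrt(2 pi)/A * exp(-pi^2 / (8 A^2)), A = pi sqrt(n) / (2(n - 2m)).
# The approximation is a tail formula that turns back down once
# n - 2m < sqrt(n) (A > pi/2); beyond that point the sample carries no
# evidence against uniformity and p = 1 is reported, which also keeps p
# monotone non-decreasing in m.
ajne_p_value <- function(m, n, n_exact = 50L) {
  if (n <= n_exact && m < n / 3) {
    return(clamp_p((n - 2 * m) * exp(lchoose(n, m) - (n - 1) * log(2))))
  }
  if (n - 2 * m <= sqrt(n)) return(1)
  A <- pi * sqrt(n) / (2 * (n - 2 * m))
  clamp_p(sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2)))
}

#' Hodges-Ajne omnibus test of circular uniformity
#'
#' Nonparametric test of circular uniformity based on the minimal number of
#' sample points contained in any half-circle. Unlike the Rayleigh test it is
#' sensitive to multimodal as well as unimodal departures from uniformity,
#' which makes it the appropriate omnibus test when tap-phase distributions
#' may show several preferred phases.
#'
#' The statistic m is the minimum half-circle count (an integer in
#' \[0, floor(n/2)\]). For n <= `n_exact` and m < n/3 the exact null
#' probability (n - 2m) C(n, m) 2^(1-n) is used; otherwise the standard
#' large-sample approximation (see Details in the package vignette). p-values
#' are clamped into (0, 1].
#'
#' @param angles_deg Numeric vector of angles in degrees, length >= 4.
#' @param criterion Significance criterion for the `significant` flag.
#' @param n_exact Largest sample size at which the exact tail formula is used
#'   (default 50).
#' @return A list of class `circ_test` with `test = "hodges_ajne"`,
#'   `statistic` (m), `p_value`, `summary`, `criterion`, `significant`.
#' @examples
#' set.seed(1)
#' hodges_ajne_test(runif(10, 0, 170))  # all in one semicircle: m = 0
#' @export
hodges_ajne_test <- function(angles_deg, criterion = 0.05, n_exact = 50L) {
  n <- length(angles_deg)
  if (n < 4L) stop("hodges_ajne_test: need at least 4 angles", call. = FALSE)
  if (any(!is.finite(angles_deg))) stop("hodges_ajne_test: non-finite angles", call. = FALSE)
  m <- ajne_statistic(angles_deg)
  p <- ajne_p_value(m, n, n_exact = n_exact)
  structure(list(test = "hodges_ajne", statistic = m, p_value = p,
                 summary = circ_summary(angles_deg),
                 criterion = criterion, significant = p < criterion),
            class = "circ_test")
}

#' @export
print.circ_test <- function(x, ...) {
  lab <- c(hodges_ajne = "Hodges-Ajne omnibus test", rayleigh = "Rayleigh test")[x$test]
  stat <- c(hodges_ajne = "m", rayleigh = "Z")[x$test]
  cat(sprintf("%s: n = %d, %s = %.4g, p = %.4g%s\n", lab, x$summary$n, stat,
              x$statistic, x$p_value,
              if (x$significant) sprintf(" (significant at %.3g)", x$criterion) else ""))
  invisible(x)
}
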