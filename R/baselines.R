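#' Rival-account baseline predictions
#'
#' Two accounts the channel model is tested against, plus the Gaussian
#' order-statistic constants the decision stage uses: (i) Gaussian max
#' uncertainty theory, in which monitoring m channels instead of one raises
#' the signal intensity needed to keep d' constant and shrinks the SD of the
#' decision variable (the max); (ii) the weight-of-evidence /
#' signal-to-noise account, in which the evidence needed scales with the
#' number of candidate axis orientations and the TvD slope is 1.
#'
#' @name baselines
NULL

#' SD of the maximum of m i.i.d. standard Gaussians
#'
#' Ratio of the SD of the maximum of m independent standard normal samples
#' to the SD of a single sample (= 1). Quadrature integrates the
#' order-statistic density m * phi(x) * Phi(x)^(m-1); Monte Carlo draws
#' `n_samples` maxima. Closed form at m = 2: sqrt(1 - 1/pi); at m = 4 the
#' value is approximately 0.70.
#'
#' @param m number of samples (>= 1).
#' @param method `"quadrature"` (deterministic) or `"monte_carlo"`.
#' @param n_samples Monte Carlo draws.
#' @param seed RNG seed for Monte Carlo.
#' @return The sd ratio; Monte Carlo results carry an `"se"` attribute.
#' @export
max_gaussian_sd_ratio <- function(m, method = c("quadrature", "monte_carlo"),
                                  n_samples = 1e6, seed = NULL) {
  method <- match.arg(method)
  if (m < 1) stop("m must be >= 1")
  if (method == "quadrature") {
    dens <- function(x) m * stats::dnorm(x) * stats::pnorm(x)^(m - 1)
    e1 <- stats::integrate(function(x) x * dens(x), -Inf, Inf,
                           rel.tol = 1e-10)$value
    e2 <- stats::integrate(function(x) x^2 * dens(x), -Inf, Inf,
                           rel.tol = 1e-10)$value
    sqrt(e2 - e1^2)
  } else {
    if (!is.null(seed)) set.seed(seed)
    mx <- matrixStats_rowmax(matrix(stats::rnorm(n_samples * m),
                                    ncol = m))
    s <- stats::sd(mx)
    ## SE of the sample SD via the fourth central moment
    m2 <- mean((mx - mean(mx))^2); m4 <- mean((mx - mean(mx))^4)
    se <- sqrt((m4 - m2^2) / n_samples) / (2 * s)
    structure(s, se = se)
  }
}

## rowMaxs without a matrixStats dependency
matrixStats_rowmax <- function(x) do.call(pmax, as.data.frame(x))

#' Signal-intensity ratio required under max-of-m uncertainty
#'
#' The signal shift that a max-rule observer monitoring m channels (signal
#' added to one) needs in order to match the performance of a single-channel
#' observer at signal = `dprime_target`, expressed as shift / dprime_target.
#' Performance is equated on two-interval percent correct,
#' P = Pr(max of \{delta + Z0, Z1..Z_(m-1)\} > max of m independent Z),
#' with the single-channel reference P = Phi(dprime_target / sqrt(2)).
#' The switchable `"yes_no"` rule instead equates yes/no percent correct at
#' the accuracy-maximising criterion (reference P = Phi(dprime_target / 2)).
#'
#' Monte Carlo uses a common-random-numbers quantile construction: for each
#' simulated trial the minimal shift that makes it correct is
#' `max(noise interval) - Z0` (or -Inf if a non-signal channel already wins),
#' so the required shift is the target-percent-correct quantile of those
#' per-trial minima; this is exact for the drawn sample and monotone in the
#' target.
#'
#' @param m monitored channels (>= 1).
#' @param dprime_target single-channel reference d' (> 0).
#' @param method `"monte_carlo"` or `"quadrature"`.
#' @param rule `"two_interval"` (default) or `"yes_no"`.
#' @param n_samples Monte Carlo trials.
#' @param seed RNG seed for Monte Carlo.
#' @return The intensity ratio (>= 1, equal to 1 at m = 1).
#' @export
uncertainty_threshold_ratio <- function(m, dprime_target = 1,
                                        method = c("monte_carlo", "quadrature"),
                                        rule = c("two_interval", "yes_no"),
                                        n_samples = 1e6, seed = NULL) {
  method <- match.arg(method); rule <- match.arg(rule)
  if (m < 1) stop("m must be >= 1")
  if (dprime_target <= 0) stop("dprime_target must be positive")
  if (m == 1) return(1)  # identity: no uncertainty to resolve
  if (rule == "two_interval") {
    target_pc <- stats::pnorm(dprime_target / sqrt(2))
    if (method == "monte_carlo") {
      if (!is.null(seed)) set.seed(seed)
      z0 <- stats::rnorm(n_samples)
      other <- if (m > 1)
        matrixStats_rowmax(matrix(stats::rnorm(n_samples * (m - 1)),
                                  ncol = m - 1))
      else rep(-Inf, n_samples)
      noise_max <- matrixStats_rowmax(matrix(stats::rnorm(n_samples * m),
                                             ncol = m))
      crit_shift <- ifelse(other > noise_max, -Inf, noise_max - z0)
      delta <- stats::quantile(crit_shift, target_pc, names = FALSE,
                               type = 8)
      delta / dprime_target
    } else {
      pc <- function(delta) {
        f <- function(x)
          (stats::dnorm(x - delta) * stats::pnorm(x)^(m - 1) +
             (m - 1) * stats::pnorm(x - delta) * stats::pnorm(x)^(m - 2) *
               stats::dnorm(x)) * stats::pnorm(x)^m
        stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
      }
      if (m == 1) return(1)
      stats::uniroot(function(d) pc(d) - target_pc,
                     c(1e-3, 10 * dprime_target + 10),
                     tol = 1e-9)$root / dprime_target
    }
  } else {
    ## yes/no at the accuracy-maximising criterion; deterministic closed
    ## forms in the normal CDF, so both methods evaluate the same expression
    target_pc <- stats::pnorm(dprime_target / 2)
    pc <- function(delta) {
      acc <- function(c)
        0.5 * (1 - stats::pnorm(c - delta) * stats::pnorm(c)^(m - 1)) +
          0.5 * stats::pnorm(c)^m
      stats::optimize(acc, c(-8, delta + 8), maximum = TRUE)$objective
    }
    if (m == 1) return(1)
    stats::uniroot(function(d) pc(d) - target_pc,
                   c(1e-3, 10 * dprime_target + 10), tol = 1e-9)$root /
      dprime_target
  }
}

#' Weight-of-evidence threshold factor
#'
#' Under the signal-to-noise account the evidence required scales with the
#' number of axis orientations inspected, so knowing the axis gives an
#' n-fold threshold improvement.
#'
#' @param n_orientations candidate axis orientations (>= 1).
#' @return `n_orientations`.
#' @export
weight_of_evidence_ratio <- function(n_orientations) {
  if (any(n_orientations < 1)) stop("n_orientations must be >= 1")
  n_orientations
}

#' TvD slope predicted by the signal-to-noise account
#'
#' The weight-of-evidence null: target threshold proportional to masker
#' density, slope 1 in log-log coordinates.
#' @return 1.
#' @export
snr_predicted_slope <- function() 1

#' Compare two fixed-slope fits to a TvD dataset
#'
#' Fits log10 threshold = intercept + slope * log10 masker density with the
#' slope fixed at each candidate (free intercept, least squares), and
#' reports the sum of squared errors of each, their ratio, and which slope
#' is preferred.
#'
#' @param dataset a [tvd_dataset].
#' @param slope_a,slope_b candidate slopes (default: model-like 0.75 vs the
#'   signal-to-noise null of 1).
#' @param density_range masker-density range entering the fit.
#' @return List with `sse_a`, `sse_b`, `ratio` (= sse_a / sse_b) and
#'   `preferred`.
#' @export
compare_fixed_slopes <- function(dataset, slope_a = 0.75,
                                 slope_b = snr_predicted_slope(),
                                 density_range = c(0.001, 0.1)) {
  stopifnot(inherits(dataset, "tvd_dataset"))
  d <- dataset[dataset$masker_density >= density_range[1] &
               dataset$masker_density <= density_range[2] &
               dataset$masker_density > 0, , drop = FALSE]
  if (nrow(d) < 2) stop("need at least 2 points in the density range")
  x <- log10(d$masker_density); y <- log10(d$threshold_density)
  sse <- function(s) { r <- y - s * x; sum((r - mean(r))^2) }
  a <- sse(slope_a); b <- sse(slope_b)
  list(sse_a = a, sse_b = b, ratio = a / b,
       preferred = if (a <= b) slope_a else slope_b)
}

#' Table of max-uncertainty baseline constants
#'
#' @param m_values channel counts.
#' @param dprime_target reference d'.
#' @param seed RNG seed for the Monte Carlo intensity ratios.
#' @return data.frame of (m, sd_ratio, intensity_ratio).
#' @export
baseline_table <- function(m_values = c(1, 2, 4, 8), dprime_target = 1,
                           seed = 1) {
  data.frame(
    m = m_values,
    sd_ratio = vapply(m_values, max_gaussian_sd_ratio, numeric(1),
                      method = "quadrature"),
    intensity_ratio = vapply(m_values, function(m)
      uncertainty_threshold_ratio(m, dprime_target, method = "quadrature"),
      numeric(1)))
}
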