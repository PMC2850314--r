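#' Channel model of symmetry detection under noise masking
#'
#' The perception stage: each orientation-selective symmetry channel responds
#' to the symmetric and non-symmetric dot-density components of the display
#' through linear excitation, an expansive nonlinearity, and divisive
#' inhibition. With the inhibitory exponent fixed at q = 2 the external-noise
#' variance (quadratic in masker density) and the noise-related inhibition
#' collapse into a single squared term, and the internal-noise variance into
#' the additive constant, so the simplified channel response is
#'
#'   R = (S_et*Dt + S_eb*Db)^p / ((S_it*Dt)^2 + (S_ib*Db)^2 + z')
#'
#' with the response-scale noise SD normalised to 1. The decision stage takes
#' the maximum of the monitored channels; its mean is approximated by a
#' fourth-power sum over m monitored channels (n of them responding to the
#' symmetry component) and its SD by gamma times the single-channel SD
#' (gamma = 1 cued, 0.71 non-cued). Threshold is the target density at which
#' d' reaches 1.
#'
#' @name model
NULL

#' Channel model parameters
#'
#' @param S_et named numeric of excitatory target sensitivities, one entry
#'   per cue x salience combination: `cued_high`, `cued_low`,
#'   `noncued_high`, `noncued_low`.
#' @param S_eb excitatory sensitivity to the non-symmetric (noise) component.
#' @param S_it named numeric of target divisive-inhibition weights by
#'   salience: `high`, `low`.
#' @param S_ib noise divisive-inhibition weight (absorbs the external-noise
#'   variance, which is quadratic in masker density).
#' @param z_prime additive denominator constant (absorbs the internal-noise
#'   variance).
#' @param p excitatory exponent (> 0).
#' @param q inhibitory exponent, fixed at 2 in the simplified response.
#' @param grouping `"quadrature"` for the canonical denominator
#'   `(S_it*Dt)^2 + (S_ib*Db)^2 + z'`; `"linear"` for the alternative
#'   `(S_it*Dt + S_ib*Db)^2 + z'` kept for sensitivity analysis.
#' @return A `channel_params` object.
#' @export
channel_params <- function(S_et, S_eb, S_it, S_ib, z_prime, p, q = 2,
                           grouping = c("quadrature", "linear")) {
  grouping <- match.arg(grouping)
  need_et <- c("cued_high", "cued_low", "noncued_high", "noncued_low")
  if (!all(need_et %in% names(S_et)))
    stop("S_et must be named: ", paste(need_et, collapse = ", "))
  if (!all(c("high", "low") %in% names(S_it)))
    stop("S_it must be named: high, low")
  vals <- c(S_et, S_eb, S_it, S_ib, z_prime)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("sensitivities and z_prime must be finite and non-negative")
  if (p <= 0) stop("p must be positive")
  if (q != 2) stop("the simplified response requires q = 2")
  structure(list(S_et = S_et[need_et], S_eb = S_eb,
                 S_it = S_it[c("high", "low")], S_ib = S_ib,
                 z_prime = z_prime, p = p, q = q, grouping = grouping),
            class = "channel_params")
}

#' @export
print.channel_params <- function(x, ...) {
  cat("<channel_params>\n")
  cat(sprintf("  S_et: %s\n", paste(sprintf("%s=%.4g", names(x$S_et), x$S_et),
                                    collapse = " ")))
  cat(sprintf("  S_eb=%.4g  S_it: high=%.4g low=%.4g  S_ib=%.4g\n",
              x$S_eb, x$S_it[["high"]], x$S_it[["low"]], x$S_ib))
  cat(sprintf("  z'=%.4g  p=%.4g  q=%g  grouping=%s\n",
              x$z_prime, x$p, x$q, x$grouping))
  invisible(x)
}

#' Experimental condition
#'
#' @param cue `"cued"` or `"noncued"`.
#' @param salience `"high"` or `"low"`.
#' @export
condition <- function(cue = c("cued", "noncued"),
                      salience = c("high", "low")) {
  structure(list(cue = match.arg(cue), salience = match.arg(salience)),
            class = "condition")
}

#' All four cue x salience conditions
#' @return List of the 2 x 2 [condition()] combinations.
#' @export
all_conditions <- function() {
  out <- list()
  for (cue in c("cued", "noncued"))
    for (sal in c("high", "low"))
      out[[paste(cue, sal, sep = "_")]] <- condition(cue, sal)
  out
}

#' Decision-stage configuration
#'
#' Cued: a single monitored channel (m = n = 1, gamma = 1). Non-cued: four
#' monitored channels, one responding (m = 4, n = 1), with the max-of-4 SD
#' factor gamma = 0.71.
#'
#' @param cue `"cued"` or `"noncued"`; sets the conventional (m, n, gamma).
#' @param m,n,gamma,dprime_criterion optional overrides.
#' @export
decision_config <- function(cue = c("cued", "noncued"), m = NULL, n = NULL,
                            gamma = NULL, dprime_criterion = 1) {
  cue <- match.arg(cue)
  if (is.null(m)) m <- if (cue == "cued") 1 else 4
  if (is.null(n)) n <- 1
  if (is.null(gamma)) gamma <- if (cue == "cued") 1 else 0.71
  if (n < 1 || m < n) stop("need 1 <= n <= m")
  if (dprime_criterion <= 0) stop("dprime_criterion must be positive")
  structure(list(cue = cue, m = m, n = n, gamma = gamma,
                 dprime_criterion = dprime_criterion),
            class = "decision_config")
}

#' Bundled fitted parameter sets for four observers
#'
#' Reference channel-model parameter sets for observers CC, LY, TR and HP
#' (nine free parameters each; the cued/high-salience target sensitivity is
#' anchored at 1000 and q = 2, m, n, gamma are fixed).
#'
#' @param observer one of `"CC"`, `"LY"`, `"TR"`, `"HP"`.
#' @return A [channel_params] object.
#' @export
observer_params <- function(observer = c("CC", "LY", "TR", "HP")) {
  observer <- match.arg(observer)
  tab <- list(
    CC = list(S_et = c(cued_high = 1000, cued_low = 401,
                       noncued_high = 540, noncued_low = 201),
              S_eb = 1.68, S_it = c(high = 890, low = 60),
              S_ib = 1196, z_prime = 0.15, p = 2.17),
    LY = list(S_et = c(cued_high = 1000, cued_low = 443,
                       noncued_high = 466, noncued_low = 268),
              S_eb = 270, S_it = c(high = 850, low = 750),
              S_ib = 2007, z_prime = 0.03, p = 2.23),
    TR = list(S_et = c(cued_high = 1000, cued_low = 867,
                       noncued_high = 528, noncued_low = 416),
              S_eb = 0.10, S_it = c(high = 400, low = 260),
              S_ib = 7132, z_prime = 3.54, p = 2.60),
    HP = list(S_et = c(cued_high = 1000, cued_low = 477,
                       noncued_high = 549, noncued_low = 362),
              S_eb = 247, S_it = c(high = 1060, low = 780),
              S_ib = 15219, z_prime = 2145, p = 2.91))
  do.call(channel_params, tab[[observer]])
}

#' Illustration parameter set with a double-corner TvD function
#'
#' A cued-channel parameter set chosen so the TvD function shows two
#' distinct slope increases: a first corner where the external-noise term
#' overtakes the additive constant z', and a second, self-inhibition-driven
#' steepening (p < 2 lets the target's own inhibition outgrow its
#' excitation at high masker density).
#'
#' @return List with `params` ([channel_params]) and the recommended
#'   `D_b_grid` (the threshold diverges just beyond its upper end).
#' @export
double_corner_params <- function() {
  list(params = channel_params(
         S_et = c(cued_high = 1000, cued_low = 1000,
                  noncued_high = 1000, noncued_low = 1000),
         S_eb = 5, S_it = c(high = 550, low = 550),
         S_ib = 2000, z_prime = 0.04, p = 1.8),
       D_b_grid = 10^seq(-5, -1.7, by = 0.1))
}

et_key <- function(condition) paste(condition$cue, condition$salience, sep = "_")

#' Linear channel excitation
#'
#' @param Se sensitivity (gain) of the channel to an image component.
#' @param D dot density of the component.
#' @return `Se * D`.
#' @export
excitation <- function(Se, D) {
  if (any(Se < 0) || any(D < 0)) stop("Se and D must be non-negative")
  Se * D
}

## Core response, vectorised over densities with per-element sensitivities.
.response <- function(D_sym, D_rand, Set, Seb, Sit, Sib, z, p,
                      grouping = "quadrature") {
  num <- (Set * D_sym + Seb * D_rand)^p
  den <- if (grouping == "linear")
    (Sit * D_sym + Sib * D_rand)^2 + z
  else
    (Sit * D_sym)^2 + (Sib * D_rand)^2 + z
  bad <- den == 0 & num == 0
  if (any(bad))
    stop("undefined response: zero denominator with zero excitation ",
         "(z_prime = 0 and both densities 0)")
  num / den
}

#' Nonlinear channel response with divisive inhibition
#'
#' Response of the channel tuned to the presented axis, given the densities
#' of the symmetric and non-symmetric image components.
#'
#' @param D_sym density of the symmetric (target) component.
#' @param D_rand density of the non-symmetric (control + masker) component.
#' @param params a [channel_params].
#' @param condition a [condition()]; selects the S_et and S_it entries.
#' @return Numeric response (vectorised over densities).
#' @export
channel_response <- function(D_sym, D_rand, params, condition) {
  stopifnot(inherits(params, "channel_params"), inherits(condition, "condition"))
  if (any(D_sym < 0) || any(D_rand < 0)) stop("densities must be non-negative")
  .response(D_sym, D_rand,
            params$S_et[[et_key(condition)]], params$S_eb,
            params$S_it[[condition$salience]], params$S_ib,
            params$z_prime, params$p, params$grouping)
}

#' Channel response to the density-matched control stimulus
#'
#' The control interval contains no symmetric component but the same total
#' dot count, so the channel sees a non-symmetric density `D_b + D_t`.
#'
#' @inheritParams channel_response
#' @param D_t target density matched by the control.
#' @param D_b masker density.
#' @export
control_response <- function(D_t, D_b, params, condition) {
  channel_response(0, D_b + D_t, params, condition)
}

#' Fourth-power pooling over monitored channels
#'
#' Approximates the mean of the maximum of m monitored channels, n of which
#' respond to the symmetry component.
#'
#' @param R_responding response of the n responding channels.
#' @param R_nonresponding response of the m - n non-responding channels.
#' @param m,n channel counts, `1 <= n <= m`.
#' @return `(n * R_responding^4 + (m - n) * R_nonresponding^4)^(1/4)`.
#' @export
pooled_response <- function(R_responding, R_nonresponding, m, n) {
  if (n < 1 || m < n) stop("need 1 <= n <= m")
  (n * R_responding^4 + (m - n) * R_nonresponding^4)^0.25
}

#' Decision-stage discriminability
#'
#' d' between the target-plus-masker and density-matched control intervals:
#' pooled target response minus pooled control response, divided by gamma
#' (the response-scale SD is normalised to 1; gamma carries the max-of-m SD
#' reduction). Non-responding channels in the target interval see the same
#' physical image but no symmetry signal, so they take the control-style
#' response at the same total density.
#'
#' @inheritParams control_response
#' @param decision a [decision_config].
#' @return d' (vectorised over densities).
#' @export
dprime <- function(D_t, D_b, params, condition, decision) {
  stopifnot(inherits(decision, "decision_config"))
  R_t <- channel_response(D_t, D_b, params, condition)
  R_c <- control_response(D_t, D_b, params, condition)
  pooled_t <- pooled_response(R_t, R_c, decision$m, decision$n)
  pooled_c <- pooled_response(R_c, R_c, decision$m, decision$m)
  (pooled_t - pooled_c) / decision$gamma
}

## Vectorised first-crossing bisection for d' = criterion on log10(D_t).
## f_dprime(log10_Dt_vector) must return d' per element for the row-wise
## condition data already bound into it.
.solve_threshold <- function(f_dprime, n_rows, criterion, log_lo, log_hi,
                             n_scan = 49, rel_tol = 1e-6) {
  grid <- seq(log_lo, log_hi, length.out = n_scan)
  lo <- rep(NA_real_, n_rows); hi <- rep(NA_real_, n_rows)
  prev <- rep(log_lo, n_rows)
  below <- f_dprime(rep(log_lo, n_rows)) < criterion
  at_lower <- !below  # criterion already met at the lower bracket edge
  for (g in grid[-1]) {
    v <- f_dprime(rep(g, n_rows))
    cross <- below & v >= criterion & is.na(lo)
    lo[cross] <- prev[cross]; hi[cross] <- g
    below <- below & v < criterion
    prev[] <- g
  }
  out <- rep(NA_real_, n_rows)
  act <- which(!is.na(lo))
  if (length(act)) {
    l <- lo[act]; h <- hi[act]
    n_iter <- ceiling(log2((grid[2] - grid[1]) / (rel_tol * 0.4342))) + 2
    n_iter <- min(max(n_iter, 20), 60)
    for (it in seq_len(n_iter)) {
      mid <- (l + h) / 2
      full <- rep(NA_real_, n_rows); full[act] <- mid
      v <- f_dprime(full)[act]
      up <- v >= criterion  # keep the lower crossing: shrink toward it
      h[up] <- mid[up]; l[!up] <- mid[!up]
    }
    out[act] <- 10^((l + h) / 2)
  }
  out[at_lower] <- 10^log_lo  # clamp: true threshold at or below the bracket
  out
}

#' Target-density threshold at the d' criterion
#'
#' Smallest target density in `[lower, upper]` at which d' reaches the
#' criterion (default 1), by coarse bracketing plus bisection on log10
#' density.
#'
#' @inheritParams dprime
#' @param D_b masker density (vectorised).
#' @param lower,upper search bracket on target density.
#' @param rel_tol relative tolerance of the solution.
#' @param on_fail `"error"` to stop when the criterion is unreachable,
#'   `"na"` to return NA for those masker densities.
#' @return Threshold density (same length as `D_b`).
#' @export
threshold <- function(D_b, params, condition, decision = NULL,
                      lower = 1e-6, upper = 1, rel_tol = 1e-6,
                      on_fail = c("error", "na")) {
  on_fail <- match.arg(on_fail)
  if (is.null(decision)) decision <- decision_config(condition$cue)
  f <- function(lDt) {
    ok <- !is.na(lDt)
    out <- rep(NA_real_, length(lDt))
    out[ok] <- dprime(10^lDt[ok], D_b[ok], params, condition, decision)
    out
  }
  th <- .solve_threshold(f, length(D_b), decision$dprime_criterion,
                         log10(lower), log10(upper), rel_tol = rel_tol)
  if (on_fail == "error" && any(is.na(th)))
    stop("d' criterion unreachable for some masker densities ",
         "(no threshold in the search bracket)")
  as.numeric(th)
}

#' TvD dataset container
#'
#' @param df data.frame with columns `cue`, `salience`, `masker_density`,
#'   `threshold_density` and optionally `se`.
#' @return The data.frame with class `tvd_dataset`.
#' @export
tvd_dataset <- function(df) {
  need <- c("cue", "salience", "masker_density", "threshold_density")
  if (!all(need %in% names(df)))
    stop("tvd_dataset needs columns: ", paste(need, collapse = ", "))
  if (!"se" %in% names(df)) df$se <- NA_real_
  if (any(df$masker_density < 0) ||
      any(df$threshold_density <= 0, na.rm = TRUE))
    stop("masker densities must be >= 0 and thresholds positive")
  class(df) <- c("tvd_dataset", "data.frame")
  df
}

#' Predict a TvD curve from the channel model
#'
#' Thresholds over a masker-density grid for one condition, optionally
#' ablating a denominator component: `"z_prime"` removes the internal-noise
#' constant (lowers the low-density limb), `"S_it"` removes the target
#' self-inhibition (alters the high-density limb).
#'
#' @inheritParams threshold
#' @param D_b_grid masker densities.
#' @param ablate `"none"`, `"z_prime"` or `"S_it"`.
#' @return A [tvd_dataset]; unreachable grid points get NA thresholds and
#'   are flagged in the `reachable` column.
#' @export
tvd_curve <- function(params, condition, decision = NULL,
                      D_b_grid = 10^seq(-3.5, -1, by = 0.25),
                      ablate = c("none", "z_prime", "S_it")) {
  ablate <- match.arg(ablate)
  if (is.null(decision)) decision <- decision_config(condition$cue)
  if (ablate == "z_prime") params$z_prime <- 0
  if (ablate == "S_it") params$S_it[] <- 0
  th <- threshold(D_b_grid, params, condition, decision, on_fail = "na")
  df <- data.frame(cue = condition$cue, salience = condition$salience,
                   masker_density = D_b_grid, threshold_density = th,
                   se = NA_real_)
  keep <- !is.na(df$threshold_density)
  ds <- tvd_dataset(df[keep, , drop = FALSE])
  attr(ds, "flagged") <- df$masker_density[!keep]
  ds
}

#' Log-log slope of a TvD dataset
#'
#' Least-squares slope of log10 threshold against log10 masker density over
#' a density range (rows with zero masker density are excluded).
#'
#' @param dataset a [tvd_dataset].
#' @param density_range length-2 numeric; rows with `masker_density` inside
#'   the closed range enter the fit.
#' @return The fitted slope.
#' @export
tvd_slope <- function(dataset, density_range = c(0.01, 0.1)) {
  stopifnot(inherits(dataset, "tvd_dataset"))
  d <- dataset[dataset$masker_density >= density_range[1] &
               dataset$masker_density <= density_range[2] &
               dataset$masker_density > 0 &
               !is.na(dataset$threshold_density), , drop = FALSE]
  if (nrow(d) < 2) stop("need at least 2 points in the density range")
  unname(stats::coef(stats::lm(log10(threshold_density) ~
                                 log10(masker_density), data = d))[2])
}

#' Locate slope-increase corners of a TvD curve
#'
#' Detects "corners" (locations where the log-log slope increases) as
#' disjoint runs where the discrete slope increment per grid step exceeds
#' `min_rise`, separated by a run below `dip`. A curve with a double corner
#' returns two locations.
#'
#' @param dataset a [tvd_dataset] on a log-spaced masker grid (one condition).
#' @param min_rise minimum slope increment per step inside a corner.
#' @param dip maximum slope increment per step between corners.
#' @return Numeric vector of corner locations (log10 masker density).
#' @export
find_tvd_corners <- function(dataset, min_rise = 0.1, dip = 0.03) {
  stopifnot(inherits(dataset, "tvd_dataset"))
  d <- dataset[!is.na(dataset$threshold_density) &
               dataset$masker_density > 0, , drop = FALSE]
  x <- log10(d$masker_density); y <- log10(d$threshold_density)
  o <- order(x); x <- x[o]; y <- y[o]
  s <- diff(y) / diff(x)
  ds <- diff(s)                         # slope increment per step
  step <- stats::median(diff(x))
  hot <- ds >= min_rise * step / 0.1    # scale thresholds to a 0.1 step
  cold <- ds <= dip * step / 0.1
  corners <- numeric(0)
  in_run <- FALSE; seen_cold <- TRUE; best <- -Inf; best_x <- NA
  for (k in seq_along(ds)) {
    if (hot[k] && seen_cold) {
      if (!in_run) { in_run <- TRUE; best <- -Inf }
      if (ds[k] > best) { best <- ds[k]; best_x <- x[k + 1] }
    } else if (in_run && !hot[k]) {
      corners <- c(corners, best_x); in_run <- FALSE; seen_cold <- FALSE
    }
    if (cold[k]) seen_cold <- TRUE
  }
  if (in_run) corners <- c(corners, best_x)
  corners
}
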