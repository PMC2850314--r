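#' Psychometric and model fitting
#'
#' Threshold estimation from constant-stimulus trial tables (ML Weibull on
#' log10 target density with parametric-bootstrap SEs), the nine-parameter
#' channel-model fit to TvD datasets (multi-start local optimisation in
#' log-parameter space, objective in log10 threshold units), and the nested
#' F comparison against the uncertainty-only reduction.
#'
#' @name fitting
NULL

## percent-correct level corresponding to the d' criterion
pc_at_criterion <- function(dprime_criterion, mapping = c("yesno", "2afc")) {
  mapping <- match.arg(mapping)
  if (mapping == "yesno") stats::pnorm(dprime_criterion / 2)
  else stats::pnorm(dprime_criterion / sqrt(2))
}

weibull_pc <- function(log_d, alpha_log, beta, lapse) {
  0.5 + (0.5 - lapse) * (1 - exp(-10^(beta * (log_d - alpha_log))))
}

weibull_nll <- function(par, log_d, n_correct, n_trials, lapse) {
  p <- weibull_pc(log_d, par[1], exp(par[2]), lapse)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(n_correct * log(p) + (n_trials - n_correct) * log(1 - p))
}

#' Maximum-likelihood psychometric threshold
#'
#' Fits a Weibull psychometric function of log10 target density to yes/no
#' trial data (guess rate 0.5, fixed small lapse), and reads off the
#' threshold at the percent-correct level corresponding to the d' criterion
#' (default: unbiased yes/no mapping P = Phi(d'/2); `mapping = "2afc"` uses
#' Phi(d'/sqrt(2))). Standard error by parametric bootstrap.
#'
#' @param trials data.frame with columns `target_density` and `correct`
#'   (logical), one block (one condition x masker density).
#' @param dprime_criterion threshold criterion, default 1.
#' @param mapping d'-to-percent-correct convention.
#' @param lapse fixed lapse rate, at most 0.03.
#' @param n_boot parametric bootstrap replicates for the SE (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @return List with `threshold` (density), `se` (log10 units), `alpha`,
#'   `beta`, `pc_criterion`, `converged`, `n_trials`.
#' @export
fit_psychometric <- function(trials, dprime_criterion = 1,
                             mapping = c("yesno", "2afc"), lapse = 0.01,
                             n_boot = 200, seed = NULL) {
  mapping <- match.arg(mapping)
  if (lapse < 0 || lapse > 0.03) stop("lapse must be in [0, 0.03]")
  if (!all(c("target_density", "correct") %in% names(trials)))
    stop("trials needs columns target_density, correct")
  agg <- stats::aggregate(cbind(n_correct = correct,
                                n_trials = rep(1, nrow(trials))) ~
                            target_density, data = trials, FUN = sum)
  if (nrow(agg) < 4) stop("need at least 4 target-density levels")
  if (any(agg$n_trials < 10)) stop("need at least 10 trials per level")
  log_d <- log10(agg$target_density)
  pc_star <- pc_at_criterion(dprime_criterion, mapping)

  fit_once <- function(n_correct) {
    ## start near the level whose observed PC brackets the criterion
    pobs <- n_correct / agg$n_trials
    a0 <- log_d[which.min(abs(pobs - 0.75))]
    best <- NULL
    for (b0 in c(0.5, 1, 2)) {
      o <- stats::optim(c(a0, log(b0)), weibull_nll, log_d = log_d,
                        n_correct = n_correct, n_trials = agg$n_trials,
                        lapse = lapse, method = "Nelder-Mead",
                        control = list(maxit = 500))
      if (is.null(best) || o$value < best$value) best <- o
    }
    best
  }
  pc_all <- mean(trials$correct)
  if (pc_all >= 1 - 1e-12) stop("degenerate data: all trials correct")
  if (pc_all <= 1e-12) stop("degenerate data: no trials correct")
  fit <- fit_once(agg$n_correct)
  alpha_log <- fit$par[1]; beta <- exp(fit$par[2])
  thr_from <- function(alpha_log, beta) {
    frac <- (pc_star - 0.5) / (0.5 - lapse)
    if (frac >= 1) return(NA_real_)
    alpha_log + log10(-log(1 - frac)) / beta
  }
  log_thr <- thr_from(alpha_log, beta)
  se <- NA_real_
  if (n_boot > 0 && is.finite(log_thr)) {
    if (!is.null(seed)) set.seed(seed)
    p_hat <- weibull_pc(log_d, alpha_log, beta, lapse)
    boot <- vapply(seq_len(n_boot), function(b) {
      nc <- stats::rbinom(length(p_hat), agg$n_trials, p_hat)
      f <- fit_once(nc)
      thr_from(f$par[1], exp(f$par[2]))
    }, numeric(1))
    se <- stats::sd(boot, na.rm = TRUE)
  }
  list(threshold = 10^log_thr, se = se, alpha = 10^alpha_log, beta = beta,
       pc_criterion = pc_star, converged = fit$convergence == 0,
       n_trials = sum(agg$n_trials))
}

#' Estimate a TvD dataset from a trial table
#'
#' Groups trials by condition and masker density and fits each block with
#' [fit_psychometric()].
#'
#' @param trials trial table with columns `cue`, `salience`,
#'   `masker_density`, `target_density`, `correct`.
#' @param ... passed to [fit_psychometric()].
#' @return A [tvd_dataset] (blocks whose fit fails are dropped with a
#'   warning).
#' @export
estimate_thresholds <- function(trials, ...) {
  key <- interaction(trials$cue, trials$salience, trials$masker_density,
                     drop = TRUE)
  rows <- lapply(split(trials, key), function(blk) {
    f <- tryCatch(fit_psychometric(blk, ...), error = function(e) NULL)
    if (is.null(f) || !is.finite(f$threshold)) return(NULL)
    data.frame(cue = blk$cue[1], salience = blk$salience[1],
               masker_density = blk$masker_density[1],
               threshold_density = f$threshold, se = f$se)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " block(s) dropped (psychometric fit failed)")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  tvd_dataset(out[order(out$cue, out$salience, out$masker_density), ])
}

## -- nine-parameter model fit ------------------------------------------------

FREE_PARAM_NAMES <- c("S_et_cued_low", "S_et_noncued_high",
                      "S_et_noncued_low", "S_eb", "S_it_high", "S_it_low",
                      "S_ib", "z_prime", "p")

params_from_vector <- function(theta, anchor = 1000, reduced = FALSE,
                               grouping = "quadrature") {
  ## theta in log10 space except p (linear); reduced drops the two
  ## non-cued S_et entries (cue collapse within salience)
  if (reduced) {
    S_et <- c(cued_high = anchor, cued_low = 10^theta[1],
              noncued_high = anchor, noncued_low = 10^theta[1])
    rest <- theta[-1]
  } else {
    S_et <- c(cued_high = anchor, cued_low = 10^theta[1],
              noncued_high = 10^theta[2], noncued_low = 10^theta[3])
    rest <- theta[-(1:3)]
  }
  channel_params(S_et = S_et, S_eb = 10^rest[1],
                 S_it = c(high = 10^rest[2], low = 10^rest[3]),
                 S_ib = 10^rest[4], z_prime = 10^rest[5], p = rest[6],
                 grouping = grouping)
}

## predicted log10 thresholds for every row of a tvd_dataset, solved in one
## vectorised bisection across rows (row-wise sensitivities and decision
## constants bound in advance)
predict_log_thresholds <- function(params, data, dprime_criterion = 1) {
  et <- params$S_et[paste(data$cue, data$salience, sep = "_")]
  it <- params$S_it[data$salience]
  m <- ifelse(data$cue == "cued", 1, 4)
  gam <- ifelse(data$cue == "cued", 1, 0.71)
  Db <- data$masker_density
  f <- function(lDt) {
    ok <- !is.na(lDt)
    out <- rep(NA_real_, length(lDt))
    Dt <- 10^lDt[ok]
    Rt <- .response(Dt, Db[ok], et[ok], params$S_eb, it[ok], params$S_ib,
                    params$z_prime, params$p, params$grouping)
    Rc <- .response(0, Db[ok] + Dt, et[ok], params$S_eb, it[ok],
                    params$S_ib, params$z_prime, params$p, params$grouping)
    pt <- (Rt^4 + (m[ok] - 1) * Rc^4)^0.25
    pc <- m[ok]^0.25 * Rc
    out[ok] <- (pt - pc) / gam[ok]
    out
  }
  th <- .solve_threshold(f, nrow(data), dprime_criterion, -6, 0)
  log10(as.numeric(th))
}

#' Fit the nine-parameter channel model to a TvD dataset
#'
#' Minimises the sum of squared log10-threshold errors over the nine free
#' parameters (three unanchored target sensitivities, S_eb, two S_it, S_ib,
#' z' and p) with the cued/high-salience target sensitivity anchored at
#' `anchor` and q = 2 fixed. Sensitivities, S_ib and z' are searched in
#' log10 space under box constraints; multi-start Nelder-Mead with a fixed
#' seed. Data points whose predicted threshold is unreachable are penalised,
#' not fatal. `reduced = TRUE` fits the uncertainty-only model in which
#' S_et is forced equal across cue conditions within salience (two fewer
#' free parameters).
#'
#' @param tvd a [tvd_dataset] with at least 10 points over >= 2 conditions.
#' @param n_starts number of optimisation starts (default 20).
#' @param seed RNG seed for the starts.
#' @param anchor fixed value of S_et(cued, high).
#' @param reduced fit the cue-collapsed reduction.
#' @param dprime_criterion threshold criterion used in prediction.
#' @param grouping denominator grouping passed to [channel_params()].
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A `fit_result`: `params`, `sse_log`, `rmse_log`,
#'   `variance_explained`, `n_points`, `n_free_params`, `residuals`,
#'   `identifiability_warning`, `converged`.
#' @export
fit_model <- function(tvd, n_starts = 20, seed = 1, anchor = 1000,
                      reduced = FALSE, dprime_criterion = 1,
                      grouping = "quadrature", maxit = 800) {
  stopifnot(inherits(tvd, "tvd_dataset"))
  n_free <- if (reduced) 7L else 9L
  conds <- unique(paste(tvd$cue, tvd$salience))
  if (nrow(tvd) < 10 || length(conds) < 2)
    stop("need >= 10 data points spanning >= 2 conditions")
  if (nrow(tvd) <= n_free) stop("fewer data points than free parameters")
  y <- log10(tvd$threshold_density)

  ## layout: [S_et terms...] S_eb S_it_high S_it_low S_ib z p
  n_et <- if (reduced) 1 else 3
  lb <- c(rep(0, n_et), -2, -1, -1, 0, -4, 1)
  ub <- c(rep(4, n_et), 4, 4.5, 4.5, 5, log10(1e4), 5)

  objective <- function(theta) {
    theta <- pmin(pmax(theta, lb), ub)
    pars <- params_from_vector(theta, anchor, reduced, grouping)
    pred <- predict_log_thresholds(pars, tvd, dprime_criterion)
    miss <- is.na(pred)
    sse <- sum((pred[!miss] - y[!miss])^2)
    sse + 25 * sum(miss)
  }
  set.seed(seed)
  base_start <- c(rep(log10(300), n_et), 0.5, 2.8, 2.8, 3.2, -0.5, 2.3)
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) base_start else
      pmin(pmax(base_start + stats::rnorm(n_free, 0, 0.8), lb), ub)
    o <- stats::optim(st, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ## polish the best start (restarted simplex escapes collapsed simplices)
  for (polish in 1:2) {
    o <- stats::optim(best$par, objective, method = "Nelder-Mead",
                      control = list(maxit = 2 * maxit, reltol = 1e-12))
    if (o$value < best$value) best <- o else break
  }
  theta <- pmin(pmax(best$par, lb), ub)
  params <- params_from_vector(theta, anchor, reduced, grouping)
  pred <- predict_log_thresholds(params, tvd, dprime_criterion)
  resid <- y - pred
  sse <- sum(resid^2, na.rm = TRUE) + 25 * sum(is.na(pred))
  sst <- sum((y - mean(y))^2)
  ## crude identifiability probe: objective curvature along each axis
  curv <- vapply(seq_len(n_free), function(k) {
    h <- 0.05; e <- rep(0, n_free); e[k] <- h
    (objective(theta + e) - 2 * best$value + objective(theta - e)) / h^2
  }, numeric(1))
  structure(list(params = params, theta = theta, sse_log = sse,
                 rmse_log = sqrt(mean(resid^2, na.rm = TRUE)),
                 variance_explained = 1 - sse / sst,
                 n_points = nrow(tvd), n_free_params = n_free,
                 reduced = reduced, anchor = anchor,
                 residuals = data.frame(tvd[c("cue", "salience",
                                              "masker_density")],
                                        observed_log10 = y,
                                        predicted_log10 = pred,
                                        residual_log10 = resid),
                 identifiability_warning = any(curv < 1e-4),
                 converged = best$convergence == 0,
                 dprime_criterion = dprime_criterion, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s model, %d free params, %d points>\n",
              if (x$reduced) "uncertainty-only" else "full",
              x$n_free_params, x$n_points))
  cat(sprintf("  sse_log = %.5g  rmse_log = %.4g  var explained = %.4g\n",
              x$sse_log, x$rmse_log, x$variance_explained))
  if (x$identifiability_warning)
    cat("  note: near-flat objective along >=1 parameter axis",
        "(S_eb is typically poorly constrained)\n")
  invisible(x)
}

#' Goodness-of-fit report
#'
#' @param fit a `fit_result`.
#' @return List with `rmse_log`, `variance_explained` and per-condition
#'   residual summaries.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  r <- fit$residuals
  per <- stats::aggregate(residual_log10 ~ cue + salience, data = r,
                          FUN = function(v) sqrt(mean(v^2)))
  names(per)[3] <- "rmse_log"
  list(rmse_log = fit$rmse_log,
       variance_explained = fit$variance_explained,
       per_condition = per, residuals = r)
}

#' Nested F comparison of the full and uncertainty-only models
#'
#' F = ((SSE_r - SSE_f) / delta_df) / (SSE_f / (N - p_f)) with
#' delta_df = p_f - p_r (2 for the cue-collapse reduction).
#'
#' @param full,reduced `fit_result`s of the full and reduced models fitted
#'   to the same data.
#' @return List with `F`, `df` (length 2), `p_value`.
#' @export
compare_nested <- function(full, reduced) {
  stopifnot(inherits(full, "fit_result"), inherits(reduced, "fit_result"))
  if (full$n_points != reduced$n_points)
    stop("fits must be to the same data")
  if (full$sse_log <= 0) stop("degenerate full fit: SSE = 0")
  ddf <- full$n_free_params - reduced$n_free_params
  if (ddf <= 0) stop("'full' must have more free parameters than 'reduced'")
  df2 <- full$n_points - full$n_free_params
  Fstat <- ((reduced$sse_log - full$sse_log) / ddf) /
    (full$sse_log / df2)
  list(F = Fstat, df = c(ddf, df2),
       p_value = stats::pf(Fstat, ddf, df2, lower.tail = FALSE))
}

#' Per-condition TvD slope report
#'
#' Log-log slopes per condition over a masker-density range, plus means by
#' salience and overall.
#'
#' @param tvd a [tvd_dataset].
#' @param density_range masker-density range entering each slope fit.
#' @return List with `per_condition` (data.frame), `by_salience`, `overall`.
#' @export
slope_report <- function(tvd, density_range = c(0.01, 0.1)) {
  stopifnot(inherits(tvd, "tvd_dataset"))
  key <- unique(tvd[c("cue", "salience")])
  sl <- vapply(seq_len(nrow(key)), function(k) {
    d <- tvd[tvd$cue == key$cue[k] & tvd$salience == key$salience[k], ,
             drop = FALSE]
    d <- d[d$masker_density >= density_range[1] &
           d$masker_density <= density_range[2] & d$masker_density > 0, ,
           drop = FALSE]
    if (nrow(d) < 3) stop("need >= 3 points per condition in range")
    unname(stats::coef(stats::lm(log10(threshold_density) ~
                                   log10(masker_density), data = d))[2])
  }, numeric(1))
  per <- data.frame(key, slope = sl)
  list(per_condition = per,
       by_salience = tapply(per$slope, per$salience, mean),
       overall = mean(per$slope))
}
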