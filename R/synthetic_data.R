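#' Synthetic-observer experiment generator
#'
#' Generates trial-level and threshold-level datasets with the experiment's
#' structure (2 cueing x 2 axial-salience conditions, masker densities from
#' 0 to 10%, constant-stimulus blocks of 7-9 target densities in 0.15-log
#' steps straddling the model threshold), driven by the channel model, so
#' the whole downstream pipeline is testable without any external data.
#'
#' Trial simulation uses the true max rule (Gaussian channel draws with
#' unit SD around their model mean responses), not the fourth-power
#' approximation, so the approximation error of the pooling stage is itself
#' measurable.
#'
#' @name synthetic_data
NULL

DEFAULT_MASKER_GRID <- c(0, 10^seq(-3.5, -1, by = 0.5))

#' Generate a constant-stimulus experiment design
#'
#' For every condition and masker density, solves the generating model's
#' threshold and lays a grid of `n_levels` target densities in 0.15-log
#' steps centred on it. Cells whose threshold is unreachable are flagged
#' and skipped.
#'
#' @param params generating [channel_params].
#' @param trials_per_level trials per target-density level.
#' @param seed integer seed recorded in the design.
#' @param masker_densities masker-density grid (default 0 and
#'   10^-3.5 ... 10^-1 in half-log steps).
#' @param n_levels target densities per block, 7-9.
#' @param dprime_criterion threshold criterion of the generating model.
#' @return An `experiment_design`: `cells` (condition x masker table with
#'   generating thresholds), `levels` (per-cell target grids), settings.
#' @export
generate_design <- function(params, trials_per_level = 50, seed = 1,
                            masker_densities = DEFAULT_MASKER_GRID,
                            n_levels = 8, dprime_criterion = 1) {
  if (n_levels < 7 || n_levels > 9) stop("n_levels must be 7-9")
  cells <- NULL; levels <- NULL; flagged <- NULL
  for (cond in all_conditions()) {
    dec <- decision_config(cond$cue, dprime_criterion = dprime_criterion)
    th <- threshold(masker_densities, params, cond, dec, on_fail = "na")
    for (k in seq_along(masker_densities)) {
      if (is.na(th[k])) {
        flagged <- rbind(flagged, data.frame(
          cue = cond$cue, salience = cond$salience,
          masker_density = masker_densities[k]))
        next
      }
      cell_id <- sprintf("%s_%s_%g", cond$cue, cond$salience,
                         masker_densities[k])
      cells <- rbind(cells, data.frame(
        cell_id = cell_id, cue = cond$cue, salience = cond$salience,
        masker_density = masker_densities[k], threshold_model = th[k]))
      steps <- seq_len(n_levels) - (n_levels + 1) / 2
      grid <- pmin(th[k] * 10^(0.15 * steps), 1)
      levels <- rbind(levels, data.frame(
        cell_id = cell_id, target_density = grid))
    }
  }
  structure(list(cells = cells, levels = levels, flagged = flagged,
                 trials_per_level = trials_per_level, n_levels = n_levels,
                 dprime_criterion = dprime_criterion, seed = seed),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design: %d cells x %d levels x %d trials (seed %d)>\n",
              nrow(x$cells), x$n_levels, x$trials_per_level, x$seed))
  if (!is.null(x$flagged))
    cat(sprintf("  %d cell(s) flagged unreachable and skipped\n",
                nrow(x$flagged)))
  invisible(x)
}

#' Simulate a model observer over a design
#'
#' Per trial, one stimulus interval (target + masker, or density-matched
#' control) is presented and the observer responds "target" when its
#' decision statistic exceeds a per-block criterion placed midway between
#' the two classes' expected statistics. Two decision rules are available:
#'
#' * `"gaussian"` (default): the decision statistic is Gaussian with mean
#'   equal to the fourth-power pooled response for the presented class and
#'   SD gamma — exactly the distributional assumption under which the
#'   model's d' and threshold are defined, so at the model threshold the
#'   percent correct matches the Phi(d'/2) mapping and the
#'   simulate-fit-recover loop closes.
#' * `"max"`: the true max rule — the m monitored channels are drawn as
#'   unit-SD Gaussians around their mean responses (n responding channels
#'   at the target response in target intervals, the rest control-style)
#'   and the statistic is their maximum, with the criterion midway between
#'   the two classes' true expected maxima (estimated by seeded Monte
#'   Carlo). This exposes the fourth-power pooling approximation error,
#'   which is substantial in the non-cued condition at low control
#'   response; see [pooling_approximation_report()].
#'
#' Stimulus classes are balanced within each level; axis orientation is
#' assigned uniformly at random (it does not enter the density-domain
#' model and is carried for schema fidelity).
#'
#' @param design an [generate_design()] result.
#' @param params generating [channel_params].
#' @param seed RNG seed.
#' @param lapse probability of a uniformly random response, default 0.
#' @param decision_rule `"gaussian"` or `"max"`.
#' @return Trial table: `cue`, `salience`, `masker_density`,
#'   `target_density`, `axis`, `stimulus_class`, `response`, `correct`.
#' @export
simulate_observer <- function(design, params, seed = 1, lapse = 0,
                              decision_rule = c("gaussian", "max")) {
  stopifnot(inherits(design, "experiment_design"))
  decision_rule <- match.arg(decision_rule)
  set.seed(seed)
  npl <- design$trials_per_level
  out <- vector("list", nrow(design$cells))
  for (ci in seq_len(nrow(design$cells))) {
    cell <- design$cells[ci, ]
    cond <- condition(cell$cue, cell$salience)
    dec <- decision_config(cell$cue,
                           dprime_criterion = design$dprime_criterion)
    grid <- design$levels$target_density[design$levels$cell_id ==
                                           cell$cell_id]
    cell_rows <- vector("list", length(grid))
    for (li in seq_along(grid)) {
      Dt <- grid[li]; Db <- cell$masker_density
      R_t <- channel_response(Dt, Db, params, cond)
      R_c <- control_response(Dt, Db, params, cond)
      cls <- sample(rep(c("target", "control"), length.out = npl))
      is_t <- cls == "target"
      if (decision_rule == "gaussian") {
        mu_t <- pooled_response(R_t, R_c, dec$m, dec$n)
        mu_c <- pooled_response(R_c, R_c, dec$m, dec$m)
        crit <- (mu_t + mu_c) / 2
        mx <- stats::rnorm(npl, mean = ifelse(is_t, mu_t, mu_c),
                           sd = dec$gamma)
      } else {
        mu_target <- c(rep(R_t, dec$n), rep(R_c, dec$m - dec$n))
        mu_control <- rep(R_c, dec$m)
        emax <- function(mu) {
          z <- matrix(stats::rnorm(2000 * dec$m), ncol = dec$m)
          mean(do.call(pmax, as.data.frame(sweep(z, 2, mu, "+"))))
        }
        crit <- (emax(mu_target) + emax(mu_control)) / 2
        draw_max <- function(flag) {
          mu <- if (flag) mu_target else mu_control
          max(stats::rnorm(dec$m, mean = mu, sd = 1))
        }
        mx <- vapply(is_t, draw_max, numeric(1))
      }
      resp <- ifelse(mx > crit, "target", "control")
      if (lapse > 0) {
        lp <- stats::runif(npl) < lapse
        resp[lp] <- sample(c("target", "control"), sum(lp), replace = TRUE)
      }
      cell_rows[[li]] <- data.frame(
        cue = cell$cue, salience = cell$salience,
        masker_density = Db, target_density = Dt,
        axis = sample(AXIS_ORIENTATIONS, npl, replace = TRUE),
        stimulus_class = cls, response = resp,
        correct = resp == cls, row.names = NULL)
    }
    out[[ci]] <- do.call(rbind, cell_rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  res
}

#' Pooling-approximation report
#'
#' Compares the fourth-power approximation to the empirical mean of the max
#' of the monitored channels at given densities.
#'
#' @inheritParams simulate_observer
#' @param D_t,D_b target and masker density.
#' @param condition,decision model condition and decision config.
#' @param n_samples Monte Carlo draws.
#' @return List with `predicted_mean` (fourth-power), `empirical_mean`,
#'   `abs_error`.
#' @export
pooling_approximation_report <- function(params, condition, decision,
                                         D_t, D_b, n_samples = 1e5,
                                         seed = 1) {
  set.seed(seed)
  R_t <- channel_response(D_t, D_b, params, condition)
  R_c <- control_response(D_t, D_b, params, condition)
  mu <- c(rep(R_t, decision$n), rep(R_c, decision$m - decision$n))
  draws <- matrix(stats::rnorm(n_samples * decision$m, mean = rep(mu,
                    each = n_samples)), ncol = decision$m)
  emp <- mean(do.call(pmax, as.data.frame(draws)))
  pred <- pooled_response(R_t, R_c, decision$m, decision$n)
  list(predicted_mean = pred, empirical_mean = emp,
       abs_error = abs(pred - emp))
}

#' Threshold-noise recovery suite
#'
#' Generates replicate TvD datasets as the generating model's thresholds
#' perturbed by Gaussian log10-threshold noise, fits each with
#' [fit_model()], and reports the distribution of fit quality and
#' threshold-surface recovery error.
#'
#' @param true_params generating [channel_params].
#' @param noise_sd_log SD of the log10-threshold perturbation (>= 0).
#' @param n_replicates number of replicate datasets.
#' @param seed RNG seed.
#' @param masker_densities masker grid (zero rows are excluded from the
#'   fitting surface).
#' @param n_starts optimisation starts per fit (scaled down from the
#'   fitting default for suite runtime; pass 20 for the full setting).
#' @return List with `replicates` (data.frame of rmse_log,
#'   variance_explained, recovery_rmse_log per replicate) and `datasets`.
#' @export
make_recovery_suite <- function(true_params, noise_sd_log = 0.08,
                                n_replicates = 3, seed = 1,
                                masker_densities = 10^seq(-3.5, -1, by = 0.5),
                                n_starts = 8) {
  if (noise_sd_log < 0) stop("noise_sd_log must be >= 0")
  set.seed(seed)
  true_rows <- NULL
  for (cond in all_conditions()) {
    th <- threshold(masker_densities, true_params, cond,
                    decision_config(cond$cue), on_fail = "na")
    keep <- !is.na(th)
    true_rows <- rbind(true_rows, data.frame(
      cue = cond$cue, salience = cond$salience,
      masker_density = masker_densities[keep], threshold_density = th[keep]))
  }
  reps <- vector("list", n_replicates); sets <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    d <- true_rows
    d$threshold_density <- 10^(log10(d$threshold_density) +
                                 stats::rnorm(nrow(d), 0, noise_sd_log))
    ds <- tvd_dataset(d)
    fit <- fit_model(ds, n_starts = n_starts, seed = seed + r)
    pred <- predict_log_thresholds(fit$params, true_rows,
                                   fit$dprime_criterion)
    rec <- sqrt(mean((pred - log10(true_rows$threshold_density))^2,
                     na.rm = TRUE))
    reps[[r]] <- data.frame(replicate = r, rmse_log = fit$rmse_log,
                            variance_explained = fit$variance_explained,
                            recovery_rmse_log = rec)
    sets[[r]] <- ds
  }
  list(replicates = do.call(rbind, reps), datasets = sets,
       true_thresholds = tvd_dataset(true_rows), seed = seed,
       noise_sd_log = noise_sd_log)
}
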