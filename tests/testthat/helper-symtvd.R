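# shared fixtures, all built in code

# model-generated TvD dataset over the default masker grid
model_tvd <- function(params, D_b_grid = 10^seq(-3.5, -1, by = 0.5),
                      conditions = all_conditions()) {
  rows <- lapply(conditions, function(cond) {
    th <- threshold(D_b_grid, params, cond, decision_config(cond$cue),
                    on_fail = "na")
    data.frame(cue = cond$cue, salience = cond$salience,
               masker_density = D_b_grid, threshold_density = th)
  })
  out <- do.call(rbind, rows)
  tvd_dataset(out[!is.na(out$threshold_density), ])
}

# exact power-law TvD rows for one condition
power_law_tvd <- function(slope, intercept = -1, cue = "cued",
                          salience = "high",
                          D_b = 10^seq(-3, -1, by = 0.25)) {
  tvd_dataset(data.frame(cue = cue, salience = salience, masker_density = D_b,
                         threshold_density = 10^(intercept +
                                                   slope * log10(D_b))))
}

# perpendicular distance (arcmin) from each on-cell to the axis line at
# `theta` degrees from vertical, for geometry checks
dot_axis_distances <- function(pattern, theta) {
  idx <- which(pattern$grid == 1L)
  nr <- pattern$height_px; nc <- pattern$width_px
  i <- ((idx - 1) %% nr) + 1; j <- ((idx - 1) %/% nr) + 1
  u <- (j - 1 - (nc - 1) / 2) * pattern$pixel_arcmin
  v <- ((nr - 1) / 2 - (i - 1)) * pattern$pixel_arcmin
  a <- theta * pi / 180
  # the axis is the fixed line of the reflection: u*cos(theta) + v*sin(theta) = 0
  abs(u * cos(a) + v * sin(a))
}
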