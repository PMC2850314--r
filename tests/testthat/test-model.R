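cc <- observer_params("CC")
cued_high <- condition("cued", "high")

test_that("excitation is linear and validated", {
  expect_equal(excitation(1000, 0), 0)
  expect_equal(excitation(0, 0.5), 0)
  expect_equal(excitation(3, 0.2), 2 * excitation(3, 0.1))
  expect_error(excitation(-1, 0.1))
})

test_that("channel response matches an independent hand computation", {
  # CC parameters, cued high salience: S_et = 1000, S_eb = 1.68,
  # S_it = 890, S_ib = 1196, z' = 0.15, p = 2.17, q = 2
  Dt <- 0.005; Db <- 0.01
  by_hand <- (1000 * Dt + 1.68 * Db)^2.17 /
    ((890 * Dt)^2 + (1196 * Db)^2 + 0.15)
  expect_equal(channel_response(Dt, Db, cc, cued_high), by_hand,
               tolerance = 1e-12)
  # trivial zeros
  expect_equal(channel_response(0, 0, cc, cued_high), 0)
  zero_noise <- channel_params(S_et = cc$S_et, S_eb = 0, S_it = cc$S_it,
                               S_ib = cc$S_ib, z_prime = cc$z_prime,
                               p = cc$p)
  expect_equal(channel_response(0, 0.05, zero_noise, cued_high), 0)
  # 0/0 domain error when z' = 0 and both densities vanish
  z0 <- channel_params(S_et = cc$S_et, S_eb = cc$S_eb, S_it = cc$S_it,
                       S_ib = cc$S_ib, z_prime = 0, p = cc$p)
  expect_error(channel_response(0, 0, z0, cued_high), "undefined")
  expect_error(channel_response(-0.1, 0, cc, cued_high), "non-negative")
})

test_that("control response is the density-matched non-symmetric response", {
  expect_equal(control_response(0, 0.02, cc, cued_high),
               channel_response(0, 0.02, cc, cued_high))
  expect_equal(control_response(0, 0, cc, cued_high), 0)
  # count matching: monotone in D_t over the sparse regime
  Dt <- seq(0.001, 0.05, length.out = 30)
  r <- control_response(Dt, 0.01, cc, cued_high)
  expect_true(all(diff(r) > 0))
})

test_that("fourth-power pooling closed forms", {
  expect_equal(pooled_response(2.5, 0, 1, 1), 2.5)
  expect_equal(pooled_response(1.3, 1.3, 4, 1), 4^0.25 * 1.3)
  expect_equal(pooled_response(0.8, 0, 4, 1), 0.8)
  expect_error(pooled_response(1, 1, 1, 2))
})

test_that("d' is zero at zero target density in every condition", {
  for (obs in c("CC", "LY", "TR", "HP")) {
    pars <- observer_params(obs)
    for (cond in all_conditions()) {
      dec <- decision_config(cond$cue)
      for (Db in c(0.001, 0.03, 0.1))
        expect_identical(dprime(0, Db, pars, cond, dec), 0)
    }
  }
})

test_that("non-cued d' follows the pooling and gamma algebra", {
  dec <- decision_config("noncued")
  cond <- condition("noncued", "high")
  Dt <- 0.02; Db <- 0.03
  Rt <- channel_response(Dt, Db, cc, cond)
  Rc <- control_response(Dt, Db, cc, cond)
  expect_equal(dprime(Dt, Db, cc, cond, dec),
               ((Rt^4 + 3 * Rc^4)^0.25 - (4 * Rc^4)^0.25) / 0.71,
               tolerance = 1e-12)
  # cued path is degenerate pooling: identical to the raw channel difference
  dec1 <- decision_config("cued")
  expect_equal(dprime(Dt, Db, cc, cued_high, dec1),
               channel_response(Dt, Db, cc, cued_high) -
                 control_response(Dt, Db, cc, cued_high))
})

test_that("d' is increasing in target density over the sparse regime", {
  Dt <- 10^seq(-3.5, -1, length.out = 40)
  for (cond in list(cued_high, condition("noncued", "low"))) {
    d <- dprime(Dt, 0.01, cc, cond, decision_config(cond$cue))
    expect_true(all(diff(d) > 0))
  }
})

test_that("threshold solver agrees with a brute-force grid oracle", {
  grid <- 10^seq(-6, 0, length.out = 1e4)
  spacing <- 6 / (1e4 - 1)  # log10 units
  cases <- expand.grid(obs = c("CC", "TR"), cue = c("cued", "noncued"),
                       Db = c(0.003, 0.03), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    pars <- observer_params(cases$obs[k])
    cond <- condition(cases$cue[k], "high")
    dec <- decision_config(cases$cue[k])
    dvals <- dprime(grid, cases$Db[k], pars, cond, dec)
    oracle <- grid[which(dvals >= 1)[1]]
    th <- threshold(cases$Db[k], pars, cond, dec)
    expect_lt(abs(log10(th) - log10(oracle)), 1.5 * spacing)
  }
})

test_that("threshold errors and edge cases", {
  dead <- channel_params(S_et = c(cued_high = 0, cued_low = 0,
                                  noncued_high = 0, noncued_low = 0),
                         S_eb = 1, S_it = c(high = 1, low = 1), S_ib = 1,
                         z_prime = 0.1, p = 2)
  expect_error(threshold(0.01, dead, cued_high, decision_config("cued")),
               "unreachable")
  expect_true(is.na(threshold(0.01, dead, cued_high,
                              decision_config("cued"), on_fail = "na")))
  # criterion already met at the lower bracket edge: clamps to the bracket
  hot <- channel_params(S_et = c(cued_high = 1e9, cued_low = 1e9,
                                 noncued_high = 1e9, noncued_low = 1e9),
                        S_eb = 0, S_it = c(high = 0, low = 0), S_ib = 1,
                        z_prime = 1, p = 1.5)
  expect_equal(threshold(0.001, hot, cued_high, decision_config("cued")),
               1e-6)
})

test_that("TvD curves are monotone and sub-unit sloped where defined", {
  # Oracle-verified behaviour of the bundled parameter sets: CC, TR and HP
  # are monotone non-decreasing in masker density in every condition; LY
  # (whose noise sensitivity S_eb = 270 nearly equals its non-cued low
  # target sensitivity 268) shows a bounded facilitation dip in two
  # conditions and cannot reach d' = 1 at all in the non-cued low
  # condition. High-density limb slopes stay below 1 wherever defined.
  for (obs in c("CC", "TR", "HP")) {
    pars <- observer_params(obs)
    for (cond in all_conditions()) {
      cv <- tvd_curve(pars, cond)
      expect_true(all(diff(cv$threshold_density) > -1e-12))
      s <- tvd_slope(cv, c(0.01, 0.1))
      expect_lt(s, 1)
      expect_gte(s, 0)
    }
  }
  ly <- observer_params("LY")
  expect_true(all(diff(tvd_curve(ly, condition("cued", "high"))
                       $threshold_density) > -1e-12))
  for (cond in list(condition("cued", "low"), condition("noncued", "high"))) {
    cv <- tvd_curve(ly, cond)
    lt <- log10(cv$threshold_density)
    expect_lt(max(lt[1] - lt), 0.2)          # dip bounded
    expect_gt(lt[length(lt)], lt[1])         # recovers and rises
    expect_lt(tvd_slope(cv, c(0.01, 0.1)), 1)
  }
  cv_nl <- tvd_curve(ly, condition("noncued", "low"))
  expect_identical(nrow(cv_nl), 0L)          # criterion unreachable
  expect_length(attr(cv_nl, "flagged"), 11)
})

test_that("tvd_slope recovers exact power laws", {
  expect_equal(tvd_slope(power_law_tvd(0.75), c(0.001, 0.1)), 0.75,
               tolerance = 1e-10)
  expect_equal(tvd_slope(power_law_tvd(0), c(0.001, 0.1)), 0,
               tolerance = 1e-10)
  expect_error(tvd_slope(power_law_tvd(0.5)[1, ], c(0.001, 0.1)), "2 points")
})

test_that("component ablations act on the expected TvD limbs", {
  dc <- double_corner_params()
  cond <- condition("cued", "high")
  grid <- dc$D_b_grid
  full <- tvd_curve(dc$params, cond, D_b_grid = grid)
  no_z <- tvd_curve(dc$params, cond, D_b_grid = grid, ablate = "z_prime")
  no_self <- tvd_curve(dc$params, cond, D_b_grid = grid, ablate = "S_it")
  lo <- 1; hi <- nrow(full)
  dz <- log10(full$threshold_density) - log10(no_z$threshold_density)
  ds <- log10(full$threshold_density) - log10(no_self$threshold_density)
  # internal-noise removal: large drop at low density, none at high
  expect_gt(dz[lo], 0.3)
  expect_lt(abs(dz[hi]), 0.02)
  # self-inhibition removal: little change at low density, large at high
  expect_lt(abs(ds[lo]), 0.06)
  expect_gt(ds[hi], 0.3)
  # the weaker claims also hold for a fitted observer set (CC)
  fullc <- tvd_curve(cc, cond)
  nozc <- tvd_curve(cc, cond, ablate = "z_prime")
  dzc <- log10(fullc$threshold_density) - log10(nozc$threshold_density)
  expect_gt(dzc[1], 0)                       # lowers the low-density limb
  expect_lt(abs(dzc[nrow(fullc)]), 0.005)    # leaves the high limb unchanged
  nositc <- tvd_curve(cc, cond, ablate = "S_it")
  dsc <- abs(log10(fullc$threshold_density) -
               log10(nositc$threshold_density))
  expect_gt(dsc[nrow(fullc)], 0.05)          # alters the high-density limb
})

test_that("the illustration set shows a double-corner TvD function", {
  dc <- double_corner_params()
  cv <- tvd_curve(dc$params, condition("cued", "high"),
                  D_b_grid = dc$D_b_grid)
  corners <- find_tvd_corners(cv)
  expect_length(corners, 2)
  expect_lt(corners[1], corners[2] - 1)  # well separated in log density
  # a single-corner observer curve yields fewer corners
  expect_lte(length(find_tvd_corners(tvd_curve(cc, cued_high,
    D_b_grid = 10^seq(-4, -1, by = 0.1)))), 1)
})

test_that("pure fourth-power pooling (gamma = 1) penalizes uncertainty", {
  eq <- channel_params(S_et = c(cued_high = 1000, cued_low = 1000,
                                noncued_high = 1000, noncued_low = 1000),
                       S_eb = cc$S_eb, S_it = cc$S_it, S_ib = cc$S_ib,
                       z_prime = cc$z_prime, p = cc$p)
  Dbs <- 10^seq(-3, -1, by = 0.5)
  th1 <- threshold(Dbs, eq, condition("cued", "high"),
                   decision_config("cued"))
  th4 <- threshold(Dbs, eq, condition("noncued", "high"),
                   decision_config("noncued", gamma = 1))
  expect_true(all(th4 >= th1 - 1e-12))
  # with the conventional gamma = 0.71 the SD reduction outweighs pooling
  # when the control response is negligible, reversing the ordering
  th4g <- threshold(Dbs, eq, condition("noncued", "high"),
                    decision_config("noncued"))
  expect_true(all(th4g < th1))
})

test_that("parameter containers validate their invariants", {
  expect_error(channel_params(S_et = c(cued_high = 1), S_eb = 1,
                              S_it = c(high = 1, low = 1), S_ib = 1,
                              z_prime = 1, p = 2), "S_et")
  expect_error(channel_params(S_et = cc$S_et, S_eb = 1, S_it = cc$S_it,
                              S_ib = 1, z_prime = 1, p = 2, q = 3), "q = 2")
  expect_error(decision_config("cued", m = 1, n = 2))
  expect_error(tvd_dataset(data.frame(cue = "cued", salience = "high",
                                      masker_density = 0.01,
                                      threshold_density = -1)))
  d <- decision_config("noncued")
  expect_equal(c(d$m, d$n, d$gamma), c(4, 1, 0.71))
  d <- decision_config("cued")
  expect_equal(c(d$m, d$n, d$gamma), c(1, 1, 1))
})

test_that("the alternative denominator grouping is switchable", {
  alt <- channel_params(S_et = cc$S_et, S_eb = cc$S_eb, S_it = cc$S_it,
                        S_ib = cc$S_ib, z_prime = cc$z_prime, p = cc$p,
                        grouping = "linear")
  Dt <- 0.01; Db <- 0.02
  by_hand <- (1000 * Dt + 1.68 * Db)^2.17 /
    ((890 * Dt + 1196 * Db)^2 + 0.15)
  expect_equal(channel_response(Dt, Db, alt, cued_high), by_hand,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(channel_response(Dt, Db, alt, cued_high),
                                channel_response(Dt, Db, cc, cued_high))))
})
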