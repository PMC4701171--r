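test_that("the oxic butyrate run conserves N and recovers it as N2", {
  sim <- sim_butyrate7()
  tr <- sim$trajectory
  n0 <- sim$summary$initialN
  totN <- tr$no3 + tr$no2 + tr$noAq + tr$noGas + tr$n2oAq + tr$n2oGas +
    tr$n2Aq + tr$n2Gas + tr$sampledN
  expect_lt(max(abs(totN - n0)) / n0, 1e-6)

  last <- tr[nrow(tr), ]
  expect_lt(last$no3, 1e-3 * n0)
  expect_lt(last$no2, 1e-3 * n0)
  expect_lt(last$noAq + last$noGas, 1e-3 * n0)
  expect_lt(last$n2oAq + last$n2oGas, 1e-3 * n0)
  expect_gt((last$n2Aq + last$n2Gas + last$sampledN) / n0, 0.99)
})

test_that("intermediates appear in the canonical order", {
  sim <- sim_butyrate7()
  tr <- sim$trajectory
  tNO2peak <- sim$summary$no2PeakTime
  ## N2O onset: first time headspace N2O reaches 5% of its maximum
  tN2Oonset <- min(tr$time[tr$n2oGas >= 0.05 * max(tr$n2oGas)])
  tN2done <- min(tr$time[(tr$n2Aq + tr$n2Gas + tr$sampledN) >=
                           0.99 * sim$summary$initialN])
  expect_lt(tNO2peak, tN2Oonset)
  expect_lt(tN2Oonset, tN2done)
  ## practically all nitrate is converted to nitrite before gas production
  expect_gt(sim$summary$no2Peak / (sim$config$initialNO3 *
                                     sim$config$volLiquid), 0.97)
})

test_that("headspace N2O rises throughout active denitrification", {
  sim <- sim_butyrate7()
  tr <- sim$trajectory
  ## observed (pre-sampling) N2O series between onset and NO2- exhaustion
  st <- sim$config$samplingSchedule
  idx <- match(st[st <= max(tr$time)], tr$time)
  obs <- tr[idx, ]
  onset <- min(obs$time[obs$n2oGas >= 0.05 * max(obs$n2oGas)])
  ## up to the last sampling at which NO2- is still clearly present
  no2last <- max(obs$time[obs$no2 >= 0.05 * max(obs$no2)])
  act <- obs[obs$time >= onset & obs$time <= no2last, ]
  expect_gt(nrow(act), 3)
  expect_true(all(diff(act$n2oGas) > 0))
})

test_that("with zero yields recruitment only shuffles cells", {
  p <- kinetic_params("butyrate", yieldO2 = 0, yieldNOx = 0)
  cfg <- treatment_config("butyrate", 7, tEnd = 60, rtol = 1e-8)
  sim <- run_simulation(cfg, p, dtOut = 1)
  tr <- sim$trajectory
  tot <- tr$zMinus + tr$zNa + tr$zNaNi + tr$zNi
  expect_lt(max(abs(tot - cfg$inoculum)) / cfg$inoculum, 1e-7)
})

test_that("an uninoculated vial only equilibrates its gases", {
  cfg <- treatment_config("succinate", 7, inoculum = 0, tEnd = 30)
  sim <- run_simulation(cfg, kinetic_params("succinate"), dtOut = 1)
  tr <- sim$trajectory
  expect_true(all(tr$zMinus + tr$zNa + tr$zNaNi + tr$zNi == 0))
  expect_equal(tr$no3[nrow(tr)], cfg$initialNO3 * cfg$volLiquid)
  expect_equal(max(tr$no2), 0)
  expect_equal(sim$summary$fNaFunctional, 0)
})

test_that("aerobic specific growth at saturating O2 matches the yield relation", {
  for (cs in c("succinate", "butyrate")) {
    p <- kinetic_params(cs)
    cfg <- treatment_config(cs, 7)
    y <- initial_state(cfg, p)
    dy <- derivatives(0, y, p, cfg)
    mu <- sum(dy[c("zMinus", "zNa", "zNaNi", "zNi")]) / cfg$inoculum
    ## yield relation mu = yieldO2 * veMaxO2, with a sub-percent Km
    ## correction at the initial Henry-equilibrium O2 concentration
    target <- if (cs == "succinate") 0.22 else 0.12
    expect_equal(mu, target, tolerance = 0.05)
  }
})

test_that("derivatives conserve N and reduce to transport without cells", {
  p <- kinetic_params("butyrate")
  cfg <- treatment_config("butyrate", 7)
  y <- initial_state(cfg, p)
  y["zMinus"] <- 0
  y["n2oGas"] <- 1e-7
  dy <- derivatives(10, y, p, cfg)
  expect_equal(unname(dy["no3"]), 0)
  expect_equal(unname(dy["no2"]), 0)
  ## pure transport: headspace loss equals aqueous gain per species
  expect_equal(unname(dy["n2oGas"]), -unname(dy["n2oAq"]))
  expect_equal(unname(dy["o2Gas"]), -unname(dy["o2Aq"]))

  ## with cells, the eight N pools still sum to zero derivative
  y2 <- initial_state(cfg, p)
  y2["zNa"] <- 1e9; y2["zNaNi"] <- 1e8; y2["o2Aq"] <- 1e-9
  y2["no2"] <- 2e-5; y2["noAq"] <- 1e-12; y2["n2oAq"] <- 1e-8
  dy2 <- derivatives(20, y2, p, cfg)
  npools <- c("no3", "no2", "noAq", "noGas", "n2oAq", "n2oGas", "n2Aq",
              "n2Gas", "sampledN")
  expect_lt(abs(sum(dy2[npools])), 1e-12 * max(abs(dy2[npools])))
})

test_that("simulation refuses unresolved trace O2 and reports summaries", {
  cfg0 <- canonical_treatments()$butyrate_0$config
  expect_error(run_simulation(cfg0, kinetic_params("butyrate")),
               "trace O2")
  s <- sim_butyrate7()$summary
  expect_true(s$no2Peak <= s$initialN)
  expect_true(s$finalN2 <= s$initialN * (1 + 1e-6))
  expect_true(s$fNaFunctional <= s$fNaTheoretical)
})

test_that("forced nar transcription recruits essentially all cells", {
  cfg <- treatment_config("butyrate", 7, tEnd = 60)
  sim <- run_counterfactual(cfg, kinetic_params("butyrate"),
                            mode = "narAlwaysOn")
  ## with rNa = 4 h-1, one hour of open window recruits 98%
  expect_gte(sim$summary$tNaFunctional, 1)
  expect_gte(sim$summary$fNaFunctional, 0.98)
  ## and the Nar-positive pools dominate the population early
  tr <- sim$trajectory
  tEnd_o2 <- min(tr$time[tr$o2Aq_conc < 1e-7])
  at <- tr[which.min(abs(tr$time - (tEnd_o2 + 1))), ]
  fracNar <- (at$zNa + at$zNaNi) / (at$zMinus + at$zNa + at$zNaNi + at$zNi)
  expect_gt(fracNar, 0.95)
})

test_that("denitrification completes without a minimum ATP flow", {
  cfg <- treatment_config("butyrate", 7)
  p <- kinetic_params("butyrate", rNa = 0.033, rNi = 0.0033)
  sim <- run_counterfactual(cfg, p, mode = "veMinZero")
  tr <- sim$trajectory
  last <- tr[nrow(tr), ]
  expect_gt((last$n2Aq + last$n2Gas + last$sampledN) /
              sim$summary$initialN, 0.99)
  expect_identical(sim$mode, "veMinZero")
  ## scaled mode wires through the factor
  sim5 <- run_counterfactual(treatment_config("butyrate", 7, tEnd = 1),
                             kinetic_params("butyrate"),
                             mode = "veMinScaled", f = 5)
  expect_equal(sim5$params$veMin, 5 * 1.87e-17)
  expect_error(run_counterfactual(cfg, p, mode = "unheard-of"))
})

test_that("full denitrifiers outgrow Nar-only cells throughout anoxia", {
  ## the driver of the rising N2O trace: NirS+cNor-positive cells grow much
  ## faster than N2O-only respirers (extra NO2- and NO electron flows), and
  ## the advantage shrinks as the denitrifier fraction -- and with it the
  ## quasi-steady N2O concentration -- rises
  sim <- sim_butyrate7()
  tr <- sim$trajectory[!duplicated(sim$trajectory$time), ]
  dn2 <- c(0, diff(tr$n2Aq + tr$n2Gas) / diff(tr$time))
  tPeak <- tr$time[which.max(dn2)]
  muRatio <- function(at) {
    fl <- electron_flows(at$o2Aq_conc, at$no3_conc, at$no2_conc,
                         at$noAq_conc, at$n2oAq_conc, sim$params)
    g <- growth_rates(list(zMinus = at$zMinus, zNa = at$zNa,
                           zNaNi = at$zNaNi, zNi = at$zNi), fl, sim$params)
    (g[["zNaNi"]] / at$zNaNi) / (g[["zNa"]] / at$zNa)
  }
  rPeak <- muRatio(tr[which.max(dn2), ])
  expect_gt(rPeak, 2)
  ## advantage declines as denitrifiers take over the N2O sink
  rEarly <- muRatio(tr[which.min(abs(tr$time - (tPeak - 12))), ])
  expect_gt(rEarly, rPeak)
})

test_that("restricting NosZ to the denitrifying minority flattens the N2O trace", {
  cfg <- treatment_config("butyrate", 7)
  p <- kinetic_params("butyrate")
  full <- sim_butyrate7()
  cut <- run_counterfactual(cfg, p, mode = "nosZOnlyDenitrifiers")

  midphase <- function(sim) {
    tr <- sim$trajectory
    st <- sim$config$samplingSchedule
    obs <- tr[match(st[st <= max(tr$time)], tr$time), ]
    onset <- min(obs$time[obs$n2oGas >= 0.05 * max(obs$n2oGas)])
    done <- min(obs$time[obs$time > onset &
                           obs$no2 < 0.01 * max(obs$no2)])
    lo <- onset + 0.25 * (done - onset)
    hi <- onset + 0.75 * (done - onset)
    obs$n2oGas[obs$time >= lo & obs$time <= hi]
  }
  mid <- midphase(cut)
  drift <- (max(mid) - min(mid)) / mean(mid)
  expect_lt(drift, 0.2)
  ## whereas the full model rises severalfold over the same window
  midFull <- midphase(full)
  expect_gt((max(midFull) - min(midFull)) / mean(midFull), 0.5)
})
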