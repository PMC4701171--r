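## Hybrid ODE / discrete-event simulator for the four-subpopulation
## denitrification model. Continuous dynamics are integrated with a
## stiff-capable variable-step method (deSolve::lsoda) between consecutive
## headspace samplings; each sampling is applied as an instantaneous state
## reset. Recruitment-window durations are accumulated as indicator states
## alongside the ODEs so they are independent of the output grid.

.state_names <- c(
  "zMinus", "zNa", "zNaNi", "zNi",
  "o2Gas", "o2Aq", "no3", "no2",
  "noAq", "noGas", "n2oAq", "n2oGas", "n2Aq", "n2Gas", "sampledN",
  "wNaFunc", "wNaTheo", "wNaNi", "wNi"
)

.no_floor <- 1e-25  # mol; aqueous NO is never exactly zero

#' Initial state vector for a treatment
#'
#' Builds the full model state at inoculation: the whole inoculum in the
#' naive pool; headspace O2 from the configured vol% by the ideal gas law
#' (1 atm total pressure); aqueous O2 at Henry equilibrium with the
#' headspace; NO3- from the configured concentration; NO2-, N2O and N2 at
#' zero; aqueous NO at the 1e-25 mol floor that keeps the cooperative NO
#' kinetics defined.
#'
#' @param config a [treatment_config()] object.
#' @param params a [kinetic_params()] object.
#' @return named numeric vector of all model states (amounts in mol or mol N
#'   per vial; cell pools in cells; `w*` recruitment-window accumulators in
#'   h, starting at 0).
#' @export
initial_state <- function(config, params) {
  if (is.na(config$initialO2VolPct)) {
    stop("initialO2VolPct is NA: the trace O2 of a nominally anoxic ",
         "treatment must be set explicitly before simulating")
  }
  RT <- params$gasConstant * params$temperature
  pO2 <- config$initialO2VolPct / 100          # atm, at 1 atm total pressure
  o2Gas <- pO2 * config$volHeadspace / RT
  o2Aq <- pO2 * params$kHO2 * config$volLiquid # Henry equilibrium
  y <- stats::setNames(numeric(length(.state_names)), .state_names)
  y["zMinus"] <- config$inoculum
  y["o2Gas"] <- o2Gas
  y["o2Aq"] <- o2Aq
  y["no3"] <- config$initialNO3 * config$volLiquid
  y["noAq"] <- .no_floor
  y
}

## Builds the deSolve right-hand side as a closure over unpacked scalar
## parameters (the RHS is the hot path; list access per call would dominate
## the runtime). State is accessed positionally in .state_names order.
## Concentrations are clipped at zero so small negative integrator
## excursions cannot feed back into the kinetics.
.make_rhs <- function(params, volLiquid, volHeadspace, nosZOnly = FALSE) {
  vl <- volLiquid
  vg <- volHeadspace
  veMaxTCA <- params$veMaxTCA; veMaxO2 <- params$veMaxO2
  veMaxNO3 <- params$veMaxNO3; veMaxNO2 <- params$veMaxNO2
  veMaxNO <- params$veMaxNO; veMaxN2O <- params$veMaxN2O
  veMin <- params$veMin
  yO2 <- params$yieldO2; yNOx <- params$yieldNOx
  thrNar <- params$o2ThresholdNar; thrNir <- params$o2ThresholdNir
  rNa <- params$rNa; rNi <- params$rNi
  kmO2 <- params$kmO2; kmNO3 <- params$kmNO3; kmNO2 <- params$kmNO2
  kmN2O <- params$kmN2O; k1NO <- params$k1NO; k2NO <- params$k2NO
  kHO2 <- params$kHO2; kHNO <- params$kHNO
  kHN2O <- params$kHN2O; kHN2 <- params$kHN2
  kt <- params$kt
  RT <- params$gasConstant * params$temperature
  noFloor <- .no_floor

  function(t, y, parms) {
    zMinus <- max(y[1], 0); zNa <- max(y[2], 0)
    zNaNi <- max(y[3], 0); zNi <- max(y[4], 0)
    o2C <- max(y[6], 0) / vl
    no3C <- max(y[7], 0) / vl
    no2C <- max(y[8], 0) / vl
    noC <- max(y[9], noFloor) / vl
    n2oC <- max(y[11], 0) / vl

    veO2 <- veMaxO2 * o2C / (kmO2 + o2C)
    veNO3 <- veMaxNO3 * no3C / (kmNO3 + no3C)
    veNO2 <- veMaxNO2 * no2C / (kmNO2 + no2C)
    veN2O <- veMaxN2O * n2oC / (kmN2O + n2oC)
    veNO <- veMaxNO / (1 + k2NO * (1 / noC + k1NO / noC^2))
    veNO3Res <- max(0, min(veNO3, veMaxTCA - veO2))
    veNO2Res <- max(0, min(veNO2, veMaxTCA - veO2 - veNO3Res))

    ## pools without NosZ (counterfactual) draw nothing from N2O
    veN2O_naive <- if (nosZOnly) 0 else veN2O
    totCells <- zMinus + zNa + zNaNi + zNi

    RrO2 <- totCells * veO2 / 4                    # mol O2 h-1
    RrNO3 <- (zNa + zNaNi) * veNO3Res / 2          # mol NO3- h-1
    RrNO2 <- (zNaNi + zNi) * veNO2Res              # mol NO2- h-1
    RrNO <- (zNaNi + zNi) * veNO                   # mol N h-1
    RrN2O <- (if (nosZOnly) zNaNi + zNi else totCells) * veN2O

    TrO2 <- kt * (kHO2 * (max(y[5], 0) / vg) * RT - o2C)
    TrNO <- kt * (kHNO * (max(y[10], 0) / vg) * RT - noC)
    TrN2O <- kt * (kHN2O * (max(y[12], 0) / vg) * RT - n2oC)
    TrN2 <- kt * (kHN2 * (max(y[14], 0) / vg) * RT - max(y[13], 0) / vl)

    narOpen <- o2C < thrNar
    nirOpen <- o2C < thrNir
    eNar <- veO2 + 0.5 * veN2O_naive
    eNirNa <- veO2 + 0.5 * veNO3Res + 0.5 * veN2O
    RNa <- if (narOpen && eNar > veMin) zMinus * rNa else 0
    RNaNi <- if (nirOpen && eNirNa > veMin) zNa * rNi else 0
    RNi <- if (nirOpen && eNar > veMin) zMinus * rNi else 0

    gMinus <- zMinus * (yO2 * veO2 + yNOx * veN2O_naive)
    gNa <- zNa * (yO2 * veO2 + yNOx * (veNO3Res + veN2O_naive))
    gNaNi <- zNaNi * (yO2 * veO2 +
                        yNOx * (veNO3Res + veNO2Res + veNO + veN2O))
    gNi <- zNi * (yO2 * veO2 + yNOx * (veNO2Res + veNO + veN2O))

    list(c(
      gMinus - RNa - RNi,
      gNa + RNa - RNaNi,
      gNaNi + RNaNi,
      gNi + RNi,
      -TrO2,
      TrO2 - RrO2,
      -RrNO3,
      RrNO3 - RrNO2,
      RrNO2 - RrNO + TrNO,
      -TrNO,
      RrNO - RrN2O + TrN2O,
      -TrN2O,
      RrN2O + TrN2,
      -TrN2,
      0,
      as.numeric(narOpen && veO2 > veMin),
      as.numeric(narOpen && eNar > veMin),
      as.numeric(nirOpen && eNirNa > veMin),
      as.numeric(nirOpen && eNar > veMin)
    ))
  }
}

#' Time-derivatives of the full model state
#'
#' Evaluates the model right-hand side at one state: electron flows and
#' their TCA restriction, respiration of all five acceptors with their
#' electron stoichiometries (4 e- per O2, 2 per NO3-, 1 per NO2-, NO-N and
#' N2O-N), Henry's-law gas transport, recruitment transfers between the four
#' pools, and growth. Exposed mainly for inspection and testing; the
#' integrator uses the same kernel.
#'
#' @param t time, h (the model is autonomous; present for the deSolve
#'   calling convention).
#' @param state named state vector as produced by [initial_state()].
#' @param params a [kinetic_params()] object.
#' @param config a [treatment_config()] object (vial geometry).
#' @param nosZOnly if `TRUE`, only NirS+cNor-positive pools carry N2O
#'   reductase (counterfactual); naive and Nar-only pools then neither
#'   consume N2O nor draw energy or growth from it.
#' @return named numeric vector of d(state)/dt.
#' @export
derivatives <- function(t, state, params, config, nosZOnly = FALSE) {
  if (any(is.na(state))) stop("state contains NA")
  rhs <- .make_rhs(params, config$volLiquid, config$volHeadspace, nosZOnly)
  out <- rhs(t, as.numeric(state[.state_names]), NULL)[[1]]
  stats::setNames(as.numeric(out), .state_names)
}

#' Run a batch-incubation simulation
#'
#' Integrates the coupled population/chemistry ODEs from inoculation to
#' `config$tEnd`, applying the headspace-sampling perturbation at every
#' scheduled sampling time, and derives the summary quantities: recruitment
#' windows, recruited fractions (functional and theoretical Nar fraction,
#' NirS fraction), the NO2- peak, the headspace N2O maximum, and final N2.
#'
#' @param config a [treatment_config()] object.
#' @param params a [kinetic_params()] object.
#' @param dtOut output grid spacing, h (sampling times are always included;
#'   an output row is recorded immediately before and after each sampling).
#' @param nosZOnly passed to the model kernel; see [derivatives()].
#' @return An object of class `simulation_result`: a list with
#'   * `trajectory`: data.frame of time and all state variables plus aqueous
#'     concentrations (`*_conc`, mol or mol N per L),
#'   * `summary`: list with `tNaFunctional`, `tNaTheoretical`, `tNaNi`,
#'     `tNi` (h), `fNaFunctional`, `fNaTheoretical`, `fNi`,
#'     `no2Peak` (mol vial-1), `no2PeakTime` (h), `n2oGasMax` (mol N
#'     vial-1), `finalN2` (mol N vial-1), `initialN` (mol N vial-1),
#'   * `config`, `params`, and the counterfactual `mode` (if any).
#' @examples
#' \donttest{
#' sim <- run_simulation(treatment_config("butyrate", 7),
#'                       kinetic_params("butyrate"))
#' sim$summary$no2Peak * 1e6  # peak nitrite, umol per vial
#' }
#' @export
run_simulation <- function(config, params, dtOut = 0.25, nosZOnly = FALSE) {
  y <- initial_state(config, params)
  rhs <- .make_rhs(params, config$volLiquid, config$volHeadspace, nosZOnly)

  events <- config$samplingSchedule[config$samplingSchedule <= config$tEnd]
  bounds <- sort(unique(c(0, events, config$tEnd)))
  atol <- stats::setNames(rep(config$atol, length(.state_names)),
                          .state_names)
  atol[c("zMinus", "zNa", "zNaNi", "zNi")] <- 1e-2   # cells, O(1e8-1e10)
  atol[c("wNaFunc", "wNaTheo", "wNaNi", "wNi")] <- 1e-10

  rows <- list()
  t0 <- 0
  if (length(events) && events[1] == 0) {
    rows[[1]] <- c(time = 0, y)                       # pre-sampling state
    y <- .apply_event_vec(y, params)
  }
  for (i in seq_along(bounds)[-1]) {
    t1 <- bounds[i]
    if (t1 <= t0) next
    times <- sort(unique(c(t0, seq(t0, t1, by = dtOut), t1)))
    sol <- deSolve::lsoda(y, times, rhs, NULL,
                          rtol = config$rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0 || any(is.na(sol))) {
      stop(sprintf("integration failed in interval [%.3g, %.3g] h", t0, t1))
    }
    rows[[length(rows) + 1]] <- sol[-1, , drop = FALSE]
    y <- sol[nrow(sol), -1]
    if (t1 %in% events && t1 < config$tEnd) {
      y <- .apply_event_vec(y, params)
      rows[[length(rows) + 1]] <- c(time = t1, y)     # post-sampling state
    }
    t0 <- t1
  }
  traj <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
    if (is.null(dim(r))) matrix(r, nrow = 1, dimnames = list(NULL, names(r)))
    else r
  })))
  names(traj)[1] <- "time"
  if (any(is.na(traj))) stop("NaN in trajectory: integration diverged")

  traj$o2Aq_conc <- pmax(traj$o2Aq, 0) / config$volLiquid
  traj$no3_conc <- pmax(traj$no3, 0) / config$volLiquid
  traj$no2_conc <- pmax(traj$no2, 0) / config$volLiquid
  traj$noAq_conc <- pmax(traj$noAq, .no_floor) / config$volLiquid
  traj$n2oAq_conc <- pmax(traj$n2oAq, 0) / config$volLiquid

  last <- traj[nrow(traj), ]
  fNaTheo <- fraction_nar(params$rNa, last$wNaTheo)
  summary <- list(
    tNaFunctional = last$wNaFunc,
    tNaTheoretical = last$wNaTheo,
    tNaNi = last$wNaNi,
    tNi = last$wNi,
    fNaFunctional = fraction_nar(params$rNa, last$wNaFunc),
    fNaTheoretical = fNaTheo,
    fNi = fraction_nir(params$rNi, last$wNaNi, last$wNi, fNaTheo),
    no2Peak = max(traj$no2),
    no2PeakTime = traj$time[which.max(traj$no2)],
    n2oGasMax = max(traj$n2oGas),
    finalN2 = last$n2Aq + last$n2Gas,
    initialN = config$initialNO3 * config$volLiquid + .no_floor
  )
  structure(list(trajectory = traj, summary = summary, config = config,
                 params = params, mode = if (nosZOnly) "nosZOnlyDenitrifiers"
                 else NULL),
            class = "simulation_result")
}

.apply_event_vec <- function(y, params) {
  chem <- apply_sampling_event(as.list(y), params)
  y[names(chem)] <- unlist(chem)
  y
}

#' @export
print.simulation_result <- function(x, ...) {
  s <- x$summary
  cat("Batch denitrification simulation (", x$config$cSource, ", ",
      x$config$initialO2VolPct, " vol% O2",
      if (!is.null(x$mode)) paste0(", mode = ", x$mode), ")\n", sep = "")
  cat(sprintf("  NO2- peak: %.3g umol vial-1 at %.1f h\n",
              s$no2Peak * 1e6, s$no2PeakTime))
  cat(sprintf("  F_Na functional %.3f (window %.1f h), theoretical %.3f\n",
              s$fNaFunctional, s$tNaFunctional, s$fNaTheoretical))
  cat(sprintf("  F_Ni %.3f (windows %.1f / %.1f h)\n",
              s$fNi, s$tNaNi, s$tNi))
  cat(sprintf("  N2O headspace max: %.3g nmol N; final N2: %.3g umol N\n",
              s$n2oGasMax * 1e9, s$finalN2 * 1e6))
  invisible(x)
}

#' Run a counterfactual scenario
#'
#' Re-runs the model under one of the structural what-ifs used to probe the
#' cell-diversification hypothesis:
#' * `narAlwaysOn` — near-deterministic nar initiation (`rNa = 4` h-1, i.e.
#'   98\% of cells Nar-positive within an hour of the gate opening), the
#'   homogeneous-population assumption.
#' * `nosZOnlyDenitrifiers` — N2O reductase restricted to the
#'   NirS+cNor-positive pools, removing the population-wide N2O sink.
#' * `veMinZero` / `veMinScaled` — remove or rescale the minimum
#'   electron-flow (ATP) requirement for recruitment.
#'
#' @param config a [treatment_config()] object.
#' @param params a [kinetic_params()] object.
#' @param mode one of `"narAlwaysOn"`, `"nosZOnlyDenitrifiers"`,
#'   `"veMinZero"`, `"veMinScaled"`.
#' @param f scale factor for `veMinScaled`.
#' @param dtOut output grid spacing, h.
#' @return a `simulation_result` with `$mode` set.
#' @export
run_counterfactual <- function(config, params,
                               mode = c("narAlwaysOn", "nosZOnlyDenitrifiers",
                                        "veMinZero", "veMinScaled"),
                               f = 1, dtOut = 0.25) {
  mode <- match.arg(mode)
  nosZOnly <- FALSE
  if (mode == "narAlwaysOn") {
    params$rNa <- 4
  } else if (mode == "nosZOnlyDenitrifiers") {
    nosZOnly <- TRUE
  } else if (mode == "veMinZero") {
    params$veMin <- 0
  } else if (mode == "veMinScaled") {
    if (f < 0) stop("veMin scale factor must be >= 0")
    params$veMin <- params$veMin * f
  }
  res <- run_simulation(config, params, dtOut = dtOut, nosZOnly = nosZOnly)
  res$mode <- mode
  res
}
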