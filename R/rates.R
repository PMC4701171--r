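#' Michaelis-Menten electron-flow velocity
#'
#' Per-cell velocity of electron flow to a dissolved acceptor (O2, NO3-,
#' NO2-, or N2O) as a hyperbolic function of its aqueous concentration.
#'
#' @param veMax maximum per-cell velocity, mol e- cell-1 h-1.
#' @param conc acceptor concentration, mol L-1 (mol N2O-N L-1 for N2O).
#' @param km half-saturation constant, same units as `conc`.
#' @return velocity in mol e- cell-1 h-1, bounded above by `veMax`.
#' @examples
#' mm_velocity(4.42e-15, 1e-9, 2.25e-7)  # the succinate veMin derivation
#' @export
mm_velocity <- function(veMax, conc, km) {
  if (any(veMax <= 0) || any(km <= 0)) stop("veMax and km must be > 0")
  if (any(conc < 0)) stop("concentration must be >= 0")
  veMax * conc / (km + conc)
}

#' NO reduction velocity with cooperative substrate binding
#'
#' Per-cell electron flow to NO, assuming two NO molecules bind cNor
#' cooperatively to form N2O. Unlike the hyperbolic law this is sigmoidal in
#' NO concentration, which keeps the flux negligible at the 1e-25 mol
#' initialisation floor of the aqueous NO pool.
#'
#' @param veMaxNO maximum per-cell velocity, mol e- cell-1 h-1.
#' @param noAqConc aqueous NO concentration, mol L-1; must be > 0 (the
#'   simulator guarantees this via the initialisation floor).
#' @param k1NO,k2NO equilibrium dissociation constants of the cNor/NO and
#'   cNor/(NO)2 complexes, mol L-1.
#' @return velocity in mol e- cell-1 h-1, with supremum `veMaxNO`.
#' @export
no_reduction_velocity <- function(veMaxNO, noAqConc, k1NO, k2NO) {
  if (any(veMaxNO <= 0) || any(k1NO <= 0) || any(k2NO <= 0)) {
    stop("veMaxNO, k1NO and k2NO must be > 0")
  }
  if (any(noAqConc <= 0)) {
    stop("noAqConc must be > 0 (use the 1e-25 mol initialisation floor)")
  }
  veMaxNO / (1 + k2NO * (1 / noAqConc + k1NO / noAqConc^2))
}

#' Restrict NO3-/NO2- electron flows to the TCA-cycle supply
#'
#' When electrons flow to O2, NO3- and NO2- simultaneously, the summed
#' per-cell flow cannot exceed the maximum delivery from the TCA cycle.
#' O2 is prioritised, then NO3-, then NO2-; NO and N2O reduction are exempt
#' because their onset never coincides with electron-supply saturation.
#'
#' @param veO2 realised electron flow to O2, mol e- cell-1 h-1.
#' @param veNO3Pot,veNO2Pot potential (enzyme-kinetic) flows to NO3-/NO2-.
#' @param veMaxTCA maximum TCA-cycle electron delivery per cell.
#' @return list with `veNO3Res` and `veNO2Res`, the realised flows (clipped
#'   at zero, so a transient `veO2 > veMaxTCA` cannot produce negative flows).
#' @examples
#' restrict_electron_flows(4.22e-15, 1e-14, 2.65e-15, 1e-14)
#' @export
restrict_electron_flows <- function(veO2, veNO3Pot, veNO2Pot, veMaxTCA) {
  if (any(c(veO2, veNO3Pot, veNO2Pot, veMaxTCA) < 0)) {
    stop("electron flows must be >= 0")
  }
  veNO3Res <- pmax(0, pmin(veNO3Pot, veMaxTCA - veO2))
  veNO2Res <- pmax(0, pmin(veNO2Pot, veMaxTCA - veO2 - veNO3Res))
  list(veNO3Res = veNO3Res, veNO2Res = veNO2Res)
}

#' Per-cell electron flows at a given chemical state
#'
#' Evaluates all acceptor-specific velocities (potential and TCA-restricted)
#' from aqueous concentrations. This is the shared kinetic kernel of the
#' simulator right-hand side.
#'
#' @param o2AqConc,no3Conc,no2Conc,noAqConc,n2oAqConc aqueous concentrations,
#'   mol L-1 (mol N L-1 for NO and N2O).
#' @param params a [kinetic_params()] object.
#' @return list with `veO2`, `veNO3Pot`, `veNO3Res`, `veNO2Pot`, `veNO2Res`,
#'   `veNO`, `veN2O`, all in mol e- cell-1 h-1.
#' @export
electron_flows <- function(o2AqConc, no3Conc, no2Conc, noAqConc, n2oAqConc,
                           params) {
  veO2  <- mm_velocity(params$veMaxO2,  o2AqConc, params$kmO2)
  veNO3 <- mm_velocity(params$veMaxNO3, no3Conc,  params$kmNO3)
  veNO2 <- mm_velocity(params$veMaxNO2, no2Conc,  params$kmNO2)
  veN2O <- mm_velocity(params$veMaxN2O, n2oAqConc, params$kmN2O)
  veNO  <- no_reduction_velocity(params$veMaxNO, noAqConc,
                                 params$k1NO, params$k2NO)
  res <- restrict_electron_flows(veO2, veNO3, veNO2, params$veMaxTCA)
  list(veO2 = veO2,
       veNO3Pot = veNO3, veNO3Res = res$veNO3Res,
       veNO2Pot = veNO2, veNO2Res = res$veNO2Res,
       veNO = veNO, veN2O = veN2O)
}

#' Recruitment flux from the naive pool to the Nar-positive pool
#'
#' Expected-value flux of cells initiating \emph{nar} transcription. The
#' flux is `zMinus * rNa` while two gates hold: aqueous O2 below the
#' Nar-induction threshold, and the energy flow `veO2 + 0.5 * veN2O`
#' above the minimum required for protein synthesis (electrons to N oxides
#' yield roughly half the ATP of aerobic respiration, hence the 0.5 weight).
#'
#' @param zMinus cells in the naive pool.
#' @param o2AqConc aqueous O2 concentration, mol L-1.
#' @param flows an [electron_flows()] list.
#' @param params a [kinetic_params()] object.
#' @return recruitment flux, cells h-1.
#' @export
recruitment_rate_nar <- function(zMinus, o2AqConc, flows, params) {
  if (zMinus < 0) stop("zMinus must be >= 0")
  gate <- o2AqConc < params$o2ThresholdNar &&
    (flows$veO2 + 0.5 * flows$veN2O) > params$veMin
  if (gate) zMinus * params$rNa else 0
}

#' Recruitment flux into a NirS+cNor-positive pool
#'
#' Expected-value flux of cells initiating \emph{nirS} transcription, either
#' from the Nar-positive pool (`hasNar = TRUE`) or directly from the naive
#' pool (`hasNar = FALSE`). The energy gate for Nar-positive source cells
#' includes the TCA-restricted NO3- flow, since those cells can fuel enzyme
#' synthesis by nitrate respiration; naive cells cannot.
#'
#' @param sourcePool cells in the source pool.
#' @param o2AqConc aqueous O2 concentration, mol L-1.
#' @param flows an [electron_flows()] list.
#' @param hasNar logical; whether the source pool carries Nar.
#' @param params a [kinetic_params()] object.
#' @return recruitment flux, cells h-1.
#' @export
recruitment_rate_nir <- function(sourcePool, o2AqConc, flows, hasNar, params) {
  if (sourcePool < 0) stop("sourcePool must be >= 0")
  energy <- flows$veO2 + 0.5 * flows$veN2O +
    if (hasNar) 0.5 * flows$veNO3Res else 0
  gate <- o2AqConc < params$o2ThresholdNir && energy > params$veMin
  if (gate) sourcePool * params$rNi else 0
}

#' Growth rates of the four subpopulations
#'
#' Each pool grows in proportion to its usable electron flows: all pools
#' respire O2 and (carrying NosZ) N2O; Nar-positive pools add the restricted
#' NO3- flow; NirS+cNor-positive pools add the restricted NO2- flow and the
#' NO flow.
#'
#' @param pop named list or vector with `zMinus`, `zNa`, `zNaNi`, `zNi`
#'   (cells per vial).
#' @param flows an [electron_flows()] list of realised per-cell flows.
#' @param params a [kinetic_params()] object (yields are taken from here).
#' @return named numeric vector of growth rates (cells h-1) for the four
#'   pools.
#' @export
growth_rates <- function(pop, flows, params) {
  yO2 <- params$yieldO2
  yNOx <- params$yieldNOx
  c(
    zMinus = pop$zMinus * (yO2 * flows$veO2 + yNOx * flows$veN2O),
    zNa    = pop$zNa    * (yO2 * flows$veO2 +
                           yNOx * (flows$veNO3Res + flows$veN2O)),
    zNaNi  = pop$zNaNi  * (yO2 * flows$veO2 +
                           yNOx * (flows$veNO3Res + flows$veNO2Res +
                                   flows$veNO + flows$veN2O)),
    zNi    = pop$zNi    * (yO2 * flows$veO2 +
                           yNOx * (flows$veNO2Res + flows$veNO +
                                   flows$veN2O))
  )
}

#' Closed-form fraction of cells recruited to the Nar-positive pool
#'
#' With a constant specific transcription-initiation probability `rNa`
#' acting over a recruitment window of length `tNa`, the recruited fraction
#' is `1 - exp(-rNa * tNa)`.
#'
#' @param rNa specific probability of initiating nar transcription, h-1.
#' @param tNa length of the open recruitment window, h.
#' @return fraction in `[0, 1)`.
#' @examples
#' fraction_nar(4, 1)      # near-total recruitment within an hour
#' fraction_nar(0.035, 20)
#' @export
fraction_nar <- function(rNa, tNa) {
  if (any(rNa < 0) || any(tNa < 0)) stop("rNa and tNa must be >= 0")
  1 - exp(-rNa * tNa)
}

#' Closed-form fraction of cells recruited to NirS+cNor expression
#'
#' Two recruitment branches contribute: Nar-positive cells (fraction `fNa`
#' of the lineage) recruit over a window `tNaNi`, naive cells over `tNi`.
#'
#' @param rNi specific probability of initiating nirS transcription, h-1.
#' @param tNaNi window length for the Nar-positive branch, h.
#' @param tNi window length for the naive branch, h.
#' @param fNa fraction of cells in the Nar-positive branch.
#' @return fraction in `[0, 1)`.
#' @export
fraction_nir <- function(rNi, tNaNi, tNi, fNa) {
  if (any(rNi < 0) || any(tNaNi < 0) || any(tNi < 0) || any(fNa < 0)) {
    stop("all arguments must be >= 0")
  }
  if (any(fNa > 1)) stop("fNa must be <= 1")
  (1 - exp(-rNi * tNaNi)) * fNa + (1 - exp(-rNi * tNi)) * (1 - fNa)
}
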