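#' Gas species table
#'
#' The four gases tracked by the model with their Henry solubilities at
#' 20 degrees C and their behaviour under headspace sampling: O2, NO and N2O
#' are diluted by each sampling (He replacement) and O2 additionally leaks
#' into the vial through the injection system; produced N2 is compared
#' against sampling-corrected data, so its sampling loss is not modelled.
#'
#' @param params a [kinetic_params()] object supplying solubilities and the
#'   per-sampling O2 leak.
#' @return data.frame with columns `name`, `kH` (mol or molN L-1 atm-1),
#'   `sampledDilution` (logical) and `leakPerSampling` (mol).
#' @export
gas_species <- function(params = kinetic_params()) {
  data.frame(
    name = c("O2", "NO", "N2O", "N2"),
    kH = c(params$kHO2, params$kHNO, params$kHN2O, params$kHN2),
    sampledDilution = c(TRUE, TRUE, TRUE, FALSE),
    leakPerSampling = c(params$o2Leak, 0, 0, 0)
  )
}

#' Partial pressure of a headspace gas
#'
#' Ideal-gas partial pressure from the amount in the headspace. For NO, N2O
#' and N2 the model books amounts in mol N, making the result an
#' N-equivalent pressure that pairs with the mol N solubilities.
#'
#' @param amountGas mol (or mol N) of the gas in the headspace.
#' @param volHeadspace headspace volume, L.
#' @param R gas constant, L atm K-1 mol-1.
#' @param T temperature, K.
#' @return partial pressure, atm.
#' @export
partial_pressure <- function(amountGas, volHeadspace, R = 0.083, T = 293.15) {
  if (any(volHeadspace <= 0)) stop("volHeadspace must be > 0")
  (amountGas / volHeadspace) * R * T
}

#' Headspace-liquid gas transport rate
#'
#' First-order relaxation towards Henry equilibrium: the flux into the
#' liquid is proportional to the difference between the equilibrium aqueous
#' concentration (`kH * pGas`) and the actual one.
#'
#' @param kt transport coefficient, L vial-1 h-1.
#' @param kH solubility, mol (or mol N) L-1 atm-1.
#' @param pGas headspace partial pressure, atm.
#' @param concAq aqueous concentration, mol (or mol N) L-1.
#' @return transport rate in mol h-1 (positive into the liquid, zero exactly
#'   at Henry equilibrium).
#' @export
transport_rate <- function(kt, kH, pGas, concAq) {
  if (any(kt <= 0) || any(kH <= 0)) stop("kt and kH must be > 0")
  kt * (kH * pGas - concAq)
}

#' Apply one headspace sampling perturbation
#'
#' The robotised incubation system draws a headspace sample and replaces it
#' with He, removing a fraction `dilutionD` of every monitored gas, while a
#' small amount of O2 leaks in through tubing and membranes. Applied as an
#' instantaneous state update at each scheduled sampling time (equivalent to
#' the removal rate acting over the sampling duration). N2 headspace amounts
#' are left untouched because the production data the model is compared with
#' are already sampling-corrected. Aqueous pools are unaffected; the N
#' removed from the NO and N2O headspace pools is added to the `sampledN`
#' bookkeeping pool so that total N remains traceable.
#'
#' @param chem named list or vector with at least `o2Gas`, `noGas`,
#'   `n2oGas`, `n2Gas` and `sampledN` (mol / mol N per vial).
#' @param params a [kinetic_params()] object (`dilutionD`, `o2Leak`).
#' @return `chem` with the headspace pools and `sampledN` updated.
#' @examples
#' chem <- list(o2Gas = 2e-4, noGas = 0, n2oGas = 1e-8, n2Gas = 0, sampledN = 0)
#' apply_sampling_event(chem, kinetic_params())
#' @export
apply_sampling_event <- function(chem, params) {
  D <- params$dilutionD
  removedN <- D * (chem$noGas + chem$n2oGas)
  chem$o2Gas <- chem$o2Gas * (1 - D) + params$o2Leak
  chem$noGas <- chem$noGas * (1 - D)
  chem$n2oGas <- chem$n2oGas * (1 - D)
  chem$sampledN <- chem$sampledN + removedN
  chem
}
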