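#' Kinetic parameter set for a batch denitrification culture
#'
#' Assembles the full rate-constant ledger for the four-subpopulation
#' denitrification model: maximum per-cell electron-flow velocities to each
#' terminal acceptor, growth yields, the oxygen thresholds gating \emph{nar}
#' and \emph{nirS} transcription, the specific transcription-initiation
#' probabilities, half-saturation and NO-binding constants, gas solubilities,
#' and the incubation-system constants (transport coefficient, sampling
#' dilution, O2 leak, gas constant, temperature).
#'
#' Defaults are carbon-source specific: butyrate- and succinate-grown cultures
#' differ in their TCA-cycle electron-supply cap, maximum O2/NO3-/NO2-
#' velocities, minimum electron flow for protein synthesis, and growth yields.
#' Any default can be overridden by name.
#'
#' Units follow the model convention throughout: electron-flow velocities in
#' mol e- cell-1 h-1, yields in cells (mol e-)-1, concentrations and
#' half-saturation constants in mol L-1 (mol N2O-N L-1 for N2O), solubilities
#' in mol (or mol N) L-1 atm-1, `kt` in L vial-1 h-1, time in h.
#'
#' @param cSource `"butyrate"` or `"succinate"`; selects the matching default
#'   velocity/yield block.
#' @param ... named overrides for any parameter field.
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params("butyrate")
#' p$veMaxO2
#' kinetic_params("succinate", rNa = 0.030)$rNa
#' @export
kinetic_params <- function(cSource = c("butyrate", "succinate"), ...) {
  cSource <- match.arg(cSource)
  base <- if (cSource == "butyrate") {
    list(
      veMaxTCA = 1e-14,     # sign-corrected from the source table's 1e14
      veMaxO2  = 4.22e-15,
      veMaxNO3 = 1e-14,
      veMaxNO2 = 2.65e-15,
      veMin    = 1.87e-17,
      yieldO2  = 2.74e13,
      yieldNOx = 1.12e13
    )
  } else {
    list(
      veMaxTCA = 9.34e-15,
      veMaxO2  = 4.42e-15,
      veMaxNO3 = 9.34e-15,
      veMaxNO2 = 2.01e-15,
      veMin    = 1.95e-17,
      yieldO2  = 4.97e13,
      yieldNOx = 1.52e13
    )
  }
  common <- list(
    veMaxNO  = 3.56e-15,
    veMaxN2O = 5.5e-15,
    o2ThresholdNar = 5.95e-5,
    o2ThresholdNir = 9.75e-6,
    rNa = 0.035,
    rNi = 0.004,
    kmO2  = 2.25e-7,
    kmNO3 = 5e-6,
    kmNO2 = 4.13e-6,
    kmN2O = 5.93e-7,       # mol N2O-N L-1
    k1NO  = 8e-14,
    k2NO  = 34e-9,
    kHO2  = 0.0014,
    kHNO  = 0.0021,
    kHN2O = 0.056,         # mol N2O-N L-1 atm-1
    kHN2  = 0.00035,
    kt = 3.6,
    dilutionD = 0.015,     # table prints the range 0.013-0.016
    o2Leak = 2.92e-9,
    samplingDuration = 0.017,
    gasConstant = 0.083,
    temperature = 293.15
  )
  p <- c(base, common, list(cSource = cSource))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  class(p) <- "kinetic_params"
  validate_kinetic_params(p)
  p
}

validate_kinetic_params <- function(p) {
  num <- setdiff(names(p), "cSource")
  vals <- unlist(p[num])
  if (any(!is.finite(vals))) {
    stop("non-finite kinetic parameter(s): ",
         paste(num[!is.finite(vals)], collapse = ", "))
  }
  pos <- c("veMaxTCA", "veMaxO2", "veMaxNO3", "veMaxNO2", "veMaxNO",
           "veMaxN2O", "o2ThresholdNar",
           "o2ThresholdNir", "rNa", "rNi", "kmO2", "kmNO3", "kmNO2", "kmN2O",
           "k1NO", "k2NO", "kHO2", "kHNO", "kHN2O", "kHN2", "kt",
           "samplingDuration", "gasConstant", "temperature")
  neg <- pos[unlist(p[pos]) <= 0]
  if (length(neg)) stop("parameter(s) must be > 0: ", paste(neg, collapse = ", "))
  ## yields of zero are admissible (useful for pure-bookkeeping runs where
  ## recruitment transfers cells but nothing grows)
  nn <- c("veMin", "o2Leak", "yieldO2", "yieldNOx")
  bad <- nn[unlist(p[nn]) < 0]
  if (length(bad)) stop("parameter(s) must be >= 0: ", paste(bad, collapse = ", "))
  if (p$dilutionD <= 0 || p$dilutionD >= 1) stop("dilutionD must be in (0, 1)")
  if (p$veMin >= p$veMaxO2) stop("veMin must be below veMaxO2")
  if (!p$cSource %in% c("butyrate", "succinate")) {
    stop("cSource must be 'butyrate' or 'succinate'")
  }
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameter set (", x$cSource, ")\n", sep = "")
  num <- setdiff(names(x), "cSource")
  cat(paste0("  ", format(num, width = 16), " ",
             signif(unlist(x[num]), 4), collapse = "\n"), "\n")
  invisible(x)
}

#' Treatment configuration for a batch incubation
#'
#' Describes one vial: carbon source, initial headspace O2 (vol%), initial
#' NO3- concentration, inoculum size, vial geometry, the headspace sampling
#' schedule of the robotised incubation system, and integration settings.
#'
#' Initial aqueous O2 is derived at simulation time by assuming Henry
#' equilibrium with the headspace at inoculation; NO2-, N2O and N2 start at
#' zero and aqueous NO at a negligible 1e-25 mol floor.
#'
#' @param cSource `"butyrate"` or `"succinate"`.
#' @param initialO2VolPct initial headspace O2 in vol% (7 for the oxic
#'   treatments). The nominally anoxic treatments contain an unmeasured trace
#'   of O2; pass the trace explicitly (`NA` marks it as unresolved and
#'   `run_simulation()` refuses to guess).
#' @param initialNO3 initial NO3- concentration in the liquid, mol L-1.
#' @param inoculum initial cell number per vial.
#' @param volHeadspace,volLiquid vial compartment volumes, L.
#' @param samplingSchedule vector of sampling times (h), or `NULL` for the
#'   default of one sampling every 3 h from t = 0.
#' @param tEnd end of simulation, h.
#' @param rtol,atol relative tolerance and chemical-pool absolute tolerance
#'   for the integrator (cell pools use a rescaled absolute tolerance).
#' @return An object of class `treatment_config`.
#' @examples
#' treatment_config("butyrate", initialO2VolPct = 7)
#' @export
treatment_config <- function(cSource = c("butyrate", "succinate"),
                             initialO2VolPct = 7,
                             initialNO3 = 2e-3,
                             inoculum = 2.2e8,
                             volHeadspace = 0.07,
                             volLiquid = 0.05,
                             samplingSchedule = NULL,
                             tEnd = 150,
                             rtol = 1e-8,
                             atol = 1e-16) {
  cSource <- match.arg(cSource)
  if (is.null(samplingSchedule)) samplingSchedule <- seq(0, tEnd, by = 3)
  samplingSchedule <- sort(unique(as.numeric(samplingSchedule)))
  if (length(samplingSchedule) && any(samplingSchedule < 0)) {
    stop("sampling times must be >= 0")
  }
  if (!is.na(initialO2VolPct) &&
      (initialO2VolPct < 0 || initialO2VolPct > 100)) {
    stop("initialO2VolPct must be in [0, 100]")
  }
  stopifnot(initialNO3 >= 0, inoculum >= 0, volHeadspace > 0, volLiquid > 0,
            tEnd > 0, rtol > 0, atol > 0)
  structure(list(
    cSource = cSource,
    initialO2VolPct = initialO2VolPct,
    initialNO3 = initialNO3,
    inoculum = inoculum,
    volHeadspace = volHeadspace,
    volLiquid = volLiquid,
    samplingSchedule = samplingSchedule,
    tEnd = tEnd,
    rtol = rtol,
    atol = atol
  ), class = "treatment_config")
}

#' @export
print.treatment_config <- function(x, ...) {
  cat("Batch treatment: ", x$cSource, ", ",
      if (is.na(x$initialO2VolPct)) "trace (unset)" else x$initialO2VolPct,
      " vol% O2, ", x$initialNO3 * 1e3, " mM NO3-\n", sep = "")
  cat("  inoculum ", format(x$inoculum, scientific = TRUE),
      " cells; headspace ", x$volHeadspace * 1e3, " mL; liquid ",
      x$volLiquid * 1e3, " mL\n", sep = "")
  cat("  ", length(x$samplingSchedule), " samplings to t = ", x$tEnd,
      " h\n", sep = "")
  invisible(x)
}

#' The four canonical batch treatments
#'
#' Returns the experiment's treatment grid: butyrate and succinate cultures
#' at nominally 0 and 7 vol% initial headspace O2, each with 2 mM NO3-,
#' 50 mL medium under 70 mL headspace, and a 2.2e8-cell aerobically grown
#' inoculum, paired with the carbon-source-matched default parameter set.
#'
#' The "~0" treatments carry `initialO2VolPct = NA`: the actual trace O2 left
#' after helium washing was not quantified, so callers must set it explicitly
#' before simulating.
#'
#' @return A list of four `list(label=, config=, params=)` entries.
#' @examples
#' names(canonical_treatments())
#' @export
canonical_treatments <- function() {
  grid <- list(
    list(label = "butyrate_0",  cSource = "butyrate",  o2 = NA_real_),
    list(label = "butyrate_7",  cSource = "butyrate",  o2 = 7),
    list(label = "succinate_0", cSource = "succinate", o2 = NA_real_),
    list(label = "succinate_7", cSource = "succinate", o2 = 7)
  )
  out <- lapply(grid, function(g) {
    list(label = g$label,
         config = treatment_config(g$cSource, initialO2VolPct = g$o2),
         params = kinetic_params(g$cSource))
  })
  names(out) <- vapply(out, `[[`, "", "label")
  out
}
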