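## Config, observation and result I/O. Configs are JSON or YAML (chosen by
## file extension) with two sections, `treatment` and `params`, whose keys
## are exactly the romanised model symbols used by treatment_config() and
## kinetic_params(). Unknown keys are rejected by name, guarding against
## symbol typos. All tables are RFC-4180 CSV, UTF-8, dot decimal; amount
## columns are mol (mol N for N species) per vial and time is in hours.

.read_structured <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    stop("config must be .json, .yaml or .yml, got: ", path)
  }
}

#' Read a treatment + parameter configuration file
#'
#' @param path JSON or YAML file with optional sections `treatment`
#'   (fields of [treatment_config()]) and `params` (fields of
#'   [kinetic_params()]). `cSource` may be given in either section (they
#'   must agree); all other fields default as in the constructors.
#' @return list with elements `config` ([treatment_config()]) and `params`
#'   ([kinetic_params()]).
#' @export
read_config <- function(path) {
  raw <- .read_structured(path)
  bad <- setdiff(names(raw), c("treatment", "params"))
  if (length(bad)) {
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "))
  }
  tr <- raw$treatment
  pr <- raw$params
  if (is.null(tr)) tr <- list()
  if (is.null(pr)) pr <- list()

  trKnown <- names(formals(treatment_config))
  badTr <- setdiff(names(tr), trKnown)
  if (length(badTr)) {
    stop("unknown treatment key(s): ", paste(badTr, collapse = ", "))
  }
  cSource <- tr$cSource %||% pr$cSource %||% "butyrate"
  if (!is.null(tr$cSource) && !is.null(pr$cSource) &&
      tr$cSource != pr$cSource) {
    stop("cSource differs between treatment and params sections")
  }
  tr$cSource <- cSource
  config <- do.call(treatment_config, tr)

  pr$cSource <- NULL
  params <- do.call(kinetic_params, c(list(cSource = cSource), pr))
  list(config = config, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a treatment + parameter configuration file
#'
#' @param config a [treatment_config()] object.
#' @param params a [kinetic_params()] object.
#' @param path output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, params, path) {
  tr <- unclass(config)
  pr <- unclass(params)
  pr$cSource <- NULL
  ext <- tolower(tools::file_ext(path))
  obj <- list(treatment = tr, params = pr)
  if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(obj, path)
  } else {
    stop("config must be .json, .yaml or .yml, got: ", path)
  }
  invisible(path)
}

#' Read / write observation sets
#'
#' Tidy CSV with columns `time_h`, `species`, `amount_mol`, `replicate`
#' (and optionally `treatment`).
#'
#' @param path CSV path.
#' @return [read_observations()]: an `observation_set`.
#' @export
read_observations <- function(path) {
  as_observation_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_observations
#' @param obs an `observation_set`.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as_observation_set(obs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a simulated trajectory as CSV
#'
#' Columns: `time_h`, the four cell pools, every chemical pool (mol or mol N
#' per vial), aqueous concentrations (mol L-1), and the instantaneous
#' recruitment-gate indicators (0/1) for the nar and nirS windows.
#'
#' @param sim a `simulation_result`.
#' @param path output CSV path.
#' @export
write_trajectory <- function(sim, path) {
  tr <- sim$trajectory
  p <- sim$params
  fl <- electron_flows(tr$o2Aq_conc, tr$no3_conc, tr$no2_conc,
                       tr$noAq_conc, tr$n2oAq_conc, p)
  out <- data.frame(
    time_h = tr$time,
    zMinus_cells = tr$zMinus, zNa_cells = tr$zNa,
    zNaNi_cells = tr$zNaNi, zNi_cells = tr$zNi,
    o2Gas_mol = tr$o2Gas, o2Aq_mol = tr$o2Aq,
    no3_mol = tr$no3, no2_mol = tr$no2,
    noAq_molN = tr$noAq, noGas_molN = tr$noGas,
    n2oAq_molN = tr$n2oAq, n2oGas_molN = tr$n2oGas,
    n2Aq_molN = tr$n2Aq, n2Gas_molN = tr$n2Gas,
    sampledN_molN = tr$sampledN,
    o2Aq_molPerL = tr$o2Aq_conc, no3_molPerL = tr$no3_conc,
    no2_molPerL = tr$no2_conc, noAq_molPerL = tr$noAq_conc,
    n2oAq_molPerL = tr$n2oAq_conc,
    gateNarFunctional = as.integer(tr$o2Aq_conc < p$o2ThresholdNar &
                                     fl$veO2 > p$veMin),
    gateNarTheoretical = as.integer(tr$o2Aq_conc < p$o2ThresholdNar &
                                      fl$veO2 + 0.5 * fl$veN2O > p$veMin),
    gateNirFromNa = as.integer(tr$o2Aq_conc < p$o2ThresholdNir &
                                 fl$veO2 + 0.5 * fl$veNO3Res +
                                 0.5 * fl$veN2O > p$veMin),
    gateNirFromNaive = as.integer(tr$o2Aq_conc < p$o2ThresholdNir &
                                    fl$veO2 + 0.5 * fl$veN2O > p$veMin)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the run summary as a one-row CSV
#'
#' @param sim a `simulation_result`.
#' @param path output CSV path.
#' @export
write_summary <- function(sim, path) {
  s <- sim$summary
  out <- data.frame(
    cSource = sim$config$cSource,
    initialO2VolPct = sim$config$initialO2VolPct,
    mode = sim$mode %||% "default",
    tNaFunctional_h = s$tNaFunctional,
    tNaTheoretical_h = s$tNaTheoretical,
    tNaNi_h = s$tNaNi,
    tNi_h = s$tNi,
    fNaFunctional = s$fNaFunctional,
    fNaTheoretical = s$fNaTheoretical,
    fNi = s$fNi,
    no2Peak_mol = s$no2Peak,
    no2PeakTime_h = s$no2PeakTime,
    n2oGasMax_molN = s$n2oGasMax,
    finalN2_molN = s$finalN2
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records alongside every command output what produced it: the command,
#' the fully resolved configuration, parameter provenance, package version,
#' seed and timestamp, so a run can be reproduced from the manifest alone.
#'
#' @param path output JSON path.
#' @param command command name.
#' @param config a [treatment_config()] object.
#' @param params a [kinetic_params()] object.
#' @param provenance `"default"`, `"config"` or `"fitted"` per parameter,
#'   or a single value for all.
#' @param seed integer seed used, or `NULL`.
#' @export
write_manifest <- function(path, command, config, params,
                           provenance = "config", seed = NULL) {
  obj <- list(
    command = command,
    package = "denitpop",
    version = as.character(utils::packageVersion("denitpop")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    provenance = provenance,
    treatment = unclass(config),
    params = { p <- unclass(params); p }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
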