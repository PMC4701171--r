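#' Measurement-noise model for synthetic observations
#'
#' Describes the error structure used to emulate the robotised incubation
#' measurements: additive Gaussian noise, truncated at zero, with a standard
#' deviation set per species as a fraction of that species' observed range,
#' plus an optional detection-limit floor below which readings are censored
#' to zero.
#'
#' @param relativeSd noise standard deviation as a fraction of the species
#'   range (default 0.02, matching the replicate spread of a well-behaved
#'   incubation run).
#' @param absoluteFloor detection limit, mol (or mol N) per vial; observed
#'   values below it are reported as zero.
#' @param seed integer seed making generation reproducible.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(relativeSd = 0.02, absoluteFloor = 0, seed = 1L) {
  stopifnot(relativeSd >= 0, absoluteFloor >= 0, is.finite(seed))
  structure(list(relativeSd = relativeSd, absoluteFloor = absoluteFloor,
                 seed = as.integer(seed)), class = "noise_model")
}

.obs_species <- c("O2", "NO2-", "NO", "N2O", "N2")

## Map a trajectory to what the instruments see at the sampling times:
## headspace amounts for the gases, liquid amount for NO2-. Rows recorded
## immediately before a sampling event are used (the analyser measures the
## headspace it draws, not the diluted aftermath).
.sample_trajectory <- function(sim) {
  traj <- sim$trajectory
  times <- sim$config$samplingSchedule
  times <- times[times <= max(traj$time)]
  idx <- match(times, traj$time)  # first row at each time = pre-event state
  if (any(is.na(idx))) stop("sampling times missing from trajectory grid")
  data.frame(
    time_h = rep(times, 5),
    species = rep(.obs_species, each = length(idx)),
    ## clip the integrator's harmless sub-tolerance negative excursions
    amount_mol = pmax(0, c(traj$o2Gas[idx], traj$no2[idx], traj$noGas[idx],
                           traj$n2oGas[idx], traj$n2Gas[idx]))
  )
}

#' Generate synthetic observations for one treatment
#'
#' Runs the forward model and samples it with the measurement structure of
#' the incubation experiment: per-vial headspace amounts of O2, NO, N2O and
#' N2 plus the liquid NO2- amount at each scheduled sampling time, with
#' additive truncated-at-zero Gaussian noise scaled to each species' range.
#'
#' @param config a [treatment_config()] object.
#' @param params a [kinetic_params()] object.
#' @param noise a [noise_model()] object.
#' @param replicates number of noisy replicate series to draw.
#' @param sim optionally, a precomputed `simulation_result` for
#'   (`config`, `params`) to avoid re-running the model.
#' @return An `observation_set`: data.frame with columns `time_h`,
#'   `species` (`"O2"`, `"NO2-"`, `"NO"`, `"N2O"`, `"N2"`), `amount_mol`
#'   (mol or mol N per vial) and `replicate`.
#' @export
generate_observations <- function(config, params, noise = noise_model(),
                                  replicates = 1, sim = NULL) {
  stopifnot(inherits(noise, "noise_model"), replicates >= 1)
  if (is.null(sim)) sim <- run_simulation(config, params, dtOut = 1)
  base <- .sample_trajectory(sim)

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(noise$seed)

  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    d <- base
    d$replicate <- r
    if (noise$relativeSd > 0) {
      for (sp in unique(d$species)) {
        i <- d$species == sp
        sd_sp <- noise$relativeSd * diff(range(d$amount_mol[i]))
        if (sd_sp > 0) {
          d$amount_mol[i] <- pmax(0, d$amount_mol[i] +
                                    stats::rnorm(sum(i), 0, sd_sp))
        }
      }
    }
    if (noise$absoluteFloor > 0) {
      d$amount_mol[d$amount_mol < noise$absoluteFloor] <- 0
    }
    d
  }))
  out$treatment <- paste0(config$cSource, "_", config$initialO2VolPct)
  as_observation_set(out)
}

#' Construct / validate an observation set
#'
#' @param x data.frame with columns `time_h`, `species`, `amount_mol` and
#'   optionally `replicate` (defaults to 1) and `treatment`.
#' @return `x` with class `observation_set`, rows ordered by replicate,
#'   species and time.
#' @export
as_observation_set <- function(x) {
  need <- c("time_h", "species", "amount_mol")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  if (any(x$time_h < 0)) stop("observation times must be >= 0")
  if (any(x$amount_mol < 0)) stop("observed amounts must be >= 0")
  bad <- !x$species %in% .obs_species
  if (any(bad)) {
    stop("unknown species: ", paste(unique(x$species[bad]), collapse = ", "))
  }
  x <- x[order(x$replicate, x$species, x$time_h), , drop = FALSE]
  key <- interaction(x$replicate, x$species, drop = TRUE)
  if (any(tapply(x$time_h, key, function(t) any(diff(t) <= 0)))) {
    stop("times must be strictly increasing within each species/replicate")
  }
  rownames(x) <- NULL
  class(x) <- c("observation_set", "data.frame")
  x
}
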