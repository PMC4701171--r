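#' Specification of a calibration problem
#'
#' Names the free kinetic parameters with their (finite) bounds, the
#' observed species entering the objective, per-species weights, and the
#' optimiser budget. Two named presets reproduce the estimation recipes of
#' the original workflow: `"rNa-from-NO2"` frees only the nar initiation
#' probability against the NO2- series, `"rNi-from-N2"` frees only the nirS
#' initiation probability against NO2- depletion plus N2 accumulation.
#'
#' @param freeParams named list; each element a length-2 numeric
#'   `c(lower, upper)` bound for one [kinetic_params()] field.
#' @param targetSpecies character vector of species in the objective
#'   (`NULL` = every species present in the observations).
#' @param weights named numeric vector of per-species weights (default 1).
#' @param nStarts number of optimiser starts (first start at the base
#'   parameter values, the rest drawn from the bounds).
#' @param maxit maximum objective evaluations per start.
#' @param seed integer seed controlling the extra start points.
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(freeParams, targetSpecies = NULL, weights = NULL,
                     nStarts = 2, maxit = 150, seed = 1L) {
  if (!length(freeParams) || is.null(names(freeParams)) ||
      any(!nzchar(names(freeParams)))) {
    stop("freeParams must be a non-empty named list of c(lower, upper)")
  }
  known <- names(kinetic_params("butyrate"))
  bad <- setdiff(names(freeParams), known)
  if (length(bad)) stop("not kinetic parameter field(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(freeParams)) {
    b <- freeParams[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] <= 0 || b[1] >= b[2]) {
      stop("bounds for ", nm, " must be finite with 0 < lower < upper")
    }
  }
  if (!is.null(targetSpecies)) {
    stopifnot(all(targetSpecies %in% .obs_species))
  }
  structure(list(freeParams = freeParams, targetSpecies = targetSpecies,
                 weights = weights, nStarts = as.integer(nStarts),
                 maxit = as.integer(maxit), seed = as.integer(seed)),
            class = "fit_spec")
}

#' @rdname fit_spec
#' @param preset preset name, `"rNa-from-NO2"` or `"rNi-from-N2"`.
#' @param ... overrides passed on to [fit_spec()].
#' @export
preset_fit_spec <- function(preset = c("rNa-from-NO2", "rNi-from-N2"), ...) {
  preset <- match.arg(preset)
  args <- if (preset == "rNa-from-NO2") {
    list(freeParams = list(rNa = c(0.005, 0.2)), targetSpecies = "NO2-")
  } else {
    list(freeParams = list(rNi = c(5e-4, 0.02)),
         targetSpecies = c("NO2-", "N2"))
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(fit_spec, args)
}

#' Range-scaled sum-of-squares calibration objective
#'
#' Simulates the treatment under `params`, interpolates the simulated
#' observable of each species to the observation times, and sums the squared
#' residuals, each species scaled by the square of its observed range so
#' that species of very different magnitudes are commensurable.
#'
#' A failed simulation (non-physical parameter combination) returns a large
#' penalty (1e6) rather than propagating the error, so an optimiser can
#' step around it.
#'
#' @param params a [kinetic_params()] object.
#' @param obs an `observation_set` (see [as_observation_set()]).
#' @param config a [treatment_config()] object.
#' @param weights named per-species weights (default 1 each).
#' @param targetSpecies species to include (`NULL` = all present).
#' @return non-negative scalar.
#' @export
sse_objective <- function(params, obs, config, weights = NULL,
                          targetSpecies = NULL) {
  species <- if (is.null(targetSpecies)) unique(obs$species) else targetSpecies
  sim <- tryCatch(run_simulation(config, params, dtOut = 1),
                  error = function(e) NULL)
  if (is.null(sim)) {
    warning("simulation failed in objective; returning penalty")
    return(1e6)
  }
  simTab <- .sample_trajectory(sim)
  total <- 0
  for (sp in species) {
    o <- obs[obs$species == sp, ]
    if (!nrow(o)) next
    s <- simTab[simTab$species == sp, ]
    simAt <- stats::approx(s$time_h, s$amount_mol, xout = o$time_h,
                           rule = 2)$y
    scale <- diff(range(o$amount_mol))
    if (scale <= 0) scale <- max(o$amount_mol, 1)
    w <- if (!is.null(weights) && sp %in% names(weights)) weights[[sp]] else 1
    total <- total + w * sum((simAt - o$amount_mol)^2) / scale^2
  }
  total
}

#' Fit uncertain kinetic parameters to observed time series
#'
#' Bounded multi-start derivative-free optimisation of [sse_objective()].
#' Each free parameter is optimised on a log scale inside its bounds via a
#' logistic transform, so the Nelder-Mead search is unconstrained while the
#' model only ever sees admissible values. The first start is the base
#' parameter set (clamped into the bounds); further starts are drawn
#' uniformly in the transformed space under the spec's seed, making the
#' whole fit deterministic.
#'
#' @param spec a [fit_spec()].
#' @param obs an `observation_set`.
#' @param config a [treatment_config()] object; coarser integrator
#'   tolerances than the defaults are usually adequate here.
#' @param baseParams a [kinetic_params()] object supplying every non-free
#'   parameter and the first start.
#' @return list with `params` (fitted [kinetic_params()]), `estimates`
#'   (named vector of fitted values), `objective` (best value), `trace`
#'   (data.frame: one row per start with its optimum and evaluation count),
#'   and `spec`.
#' @export
fit_parameters <- function(spec, obs, config, baseParams) {
  stopifnot(inherits(spec, "fit_spec"))
  obs <- as_observation_set(obs)
  if (!is.null(spec$targetSpecies)) {
    miss <- setdiff(spec$targetSpecies, unique(obs$species))
    if (length(miss)) {
      stop("species in fit spec absent from observations: ",
           paste(miss, collapse = ", "))
    }
  }
  nms <- names(spec$freeParams)
  lo <- log(vapply(spec$freeParams, `[`, 0, 1))
  hi <- log(vapply(spec$freeParams, `[`, 0, 2))

  to_theta <- function(p) {                    # log-scale value -> R
    u <- (log(p) - lo) / (hi - lo)
    u <- pmin(pmax(u, 1e-6), 1 - 1e-6)
    stats::qlogis(u)
  }
  to_param <- function(theta) exp(lo + (hi - lo) * stats::plogis(theta))

  nEval <- 0L
  objFun <- function(theta) {
    nEval <<- nEval + 1L
    p <- baseParams
    p[nms] <- as.list(to_param(theta))
    sse_objective(p, obs, config, weights = spec$weights,
                  targetSpecies = spec$targetSpecies)
  }

  base0 <- unlist(baseParams[nms])
  starts <- list(to_theta(pmin(pmax(base0, exp(lo) * 1.001),
                               exp(hi) * 0.999)))
  ## 1-d search is a deterministic golden-section scan of the whole
  ## transformed interval, so extra starts would repeat it verbatim
  if (length(nms) > 1 && spec$nStarts > 1) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(spec$seed)
    for (i in seq_len(spec$nStarts - 1)) {
      starts[[i + 1]] <- stats::qlogis(stats::runif(length(nms), 0.15, 0.85))
    }
  }

  best <- NULL
  trace <- data.frame()
  anySuccess <- FALSE
  for (i in seq_along(starts)) {
    nEval <- 0L
    fit <- if (length(nms) == 1) {
      ## 1-d Nelder-Mead is fragile; use golden-section on the transform
      o <- stats::optimize(function(th) objFun(th), interval = c(-8, 8),
                           tol = 1e-4)
      list(par = o$minimum, value = o$objective)
    } else {
      stats::optim(starts[[i]], objFun, method = "Nelder-Mead",
                   control = list(maxit = spec$maxit, reltol = 1e-8))
    }
    if (fit$value < 1e6) anySuccess <- TRUE
    trace <- rbind(trace, data.frame(start = i, objective = fit$value,
                                     evaluations = nEval))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!anySuccess) {
    stop("optimiser budget exhausted without any successful simulation")
  }
  est <- to_param(best$par)
  names(est) <- nms
  fitted <- baseParams
  fitted[nms] <- as.list(est)
  list(params = fitted, estimates = est, objective = best$value,
       trace = trace, spec = spec)
}
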