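#' Log-normal prior specification for kinetic parameters
#'
#' Each parameter is assigned an independent log-normal prior described by
#' its center (median, on the natural rate scale) and its standard
#' deviation in log10 units. The default centers mirror biologically
#' plausible rate scales: 1e-6 /s/molecule for bimolecular binding, 1e-3 /s
#' for unbinding and 1 /s for catalysis.
#'
#' @param centers Named vector of strictly positive prior centers.
#' @param log10_sd Standard deviation(s) in log10 space (scalar recycled, or
#'   one per parameter); default 1.
#' @return A `prior_spec`.
#' @export
prior_spec <- function(centers, log10_sd = 1) {
  if (is.null(names(centers))) stop("prior centers must be named")
  if (any(centers <= 0)) stop("prior centers must be > 0")
  sd <- rep_len(log10_sd, length(centers))
  if (any(sd <= 0)) stop("log10_sd must be > 0")
  structure(list(centers = centers,
                 log10_sd = stats::setNames(sd, names(centers))),
            class = "prior_spec")
}

#' Default prior for a network's parameters by kinetic role
#'
#' Assigns the binding/unbinding/catalysis centers (1e-6, 1e-3, 1) by the
#' conventional `kf_`/`kr_`/`kc_` parameter-name prefixes; parameters with
#' other names get the geometric middle (1e-3).
#'
#' @param net A [reaction_network()].
#' @param log10_sd Log10 standard deviation (default 1).
#' @return A [prior_spec()].
#' @export
default_prior <- function(net, log10_sd = 1) {
  centers <- vapply(net$parameters, function(p) {
    switch(substr(p, 1, 3),
           kf_ = 1e-6, kr_ = 1e-3, kc_ = 1, 1e-3)
  }, numeric(1))
  prior_spec(centers, log10_sd)
}

#' Sample a parameter ensemble from a prior
#'
#' Draws `n` i.i.d. parameter vectors from the log-normal prior and attaches
#' uniform weights. Reproducible for a fixed seed.
#'
#' @param prior A [prior_spec()].
#' @param n Ensemble size (>= 1).
#' @param seed Integer seed.
#' @return A [parameter_ensemble()].
#' @export
sample_ensemble <- function(prior, n, seed = 1L) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  set.seed(seed)
  p <- length(prior$centers)
  z <- matrix(stats::rnorm(n * p), n, p)
  values <- sweep(z, 2L, prior$log10_sd, `*`)
  values <- sweep(values, 2L, log10(prior$centers), `+`)
  values <- 10^values
  colnames(values) <- names(prior$centers)
  parameter_ensemble(values)
}

#' Simulate noisy observations of selected observables
#'
#' Simulates the network at a ground-truth parameter vector and adds
#' homoscedastic Gaussian noise to each observable (a species or a sum of
#' species), emulating replicate fluorescence time-course measurements.
#' Both the noiseless truth and the noisy copies are returned.
#'
#' @param net A [reaction_network()].
#' @param truth_params Ground-truth parameters.
#' @param observables Named list: each element a character vector of species
#'   to sum (a bare character vector names single-species observables).
#' @param time_grid Simulation/observation time grid.
#' @param noise_sd Gaussian noise standard deviation (same units as the
#'   observables).
#' @param seed Integer seed.
#' @return A list with `time`, `truth` and `observed` (matrices with one
#'   column per observable) and the generating `noise_sd`.
#' @export
synthetic_observations <- function(net, truth_params, observables,
                                   time_grid, noise_sd, seed = 1L) {
  if (is.character(observables)) {
    observables <- stats::setNames(as.list(observables), observables)
  }
  unknown <- setdiff(unlist(observables), species_names(net))
  if (length(unknown)) {
    stop("unknown observable species: ", paste(unknown, collapse = ", "))
  }
  traj <- simulate_network(net, truth_params, time_grid)
  truth <- vapply(observables, function(spp) {
    rowSums(traj$species[, spp, drop = FALSE])
  }, numeric(length(time_grid)))
  set.seed(seed)
  observed <- truth + stats::rnorm(length(truth), sd = noise_sd)
  list(time = as.numeric(time_grid), truth = truth, observed = observed,
       observables = observables, noise_sd = noise_sd)
}

#' Weight an ensemble by Gaussian goodness of fit
#'
#' Computes, for every ensemble member, the Gaussian log-likelihood of the
#' observations given that member's simulated observables, and attaches the
#' normalized weights (max-subtracted exponentiation). An importance-style
#' stand-in for full Bayesian calibration: members that cannot be simulated
#' receive zero weight with a warning.
#'
#' @param ensemble A [parameter_ensemble()].
#' @param net The [reaction_network()].
#' @param observations Result of [synthetic_observations()] (or compatible
#'   list with `time`, `observed`, `observables`, `noise_sd`).
#' @param noise_sd Likelihood standard deviation (defaults to the
#'   generating one).
#' @return A [parameter_ensemble()] with log-likelihood-derived weights.
#' @export
weight_by_fit <- function(ensemble, net, observations,
                          noise_sd = observations$noise_sd) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  n <- length(ensemble)
  ll <- vapply(seq_len(n), function(i) {
    traj <- tryCatch(
      simulate_network(net, ensemble_member(ensemble, i),
                       observations$time),
      error = function(e) NULL)
    if (is.null(traj)) {
      warning("simulation failed for ensemble member ", i,
              "; assigned zero weight")
      return(-Inf)
    }
    pred <- vapply(observations$observables, function(spp) {
      rowSums(traj$species[, spp, drop = FALSE])
    }, numeric(length(observations$time)))
    sum(stats::dnorm(observations$observed, mean = pred, sd = noise_sd,
                     log = TRUE))
  }, numeric(1))
  if (all(!is.finite(ll))) stop("no ensemble member could be simulated")
  w <- softmax_weights(ifelse(is.finite(ll), ll, min(ll[is.finite(ll)]) -
                                1e6))
  parameter_ensemble(ensemble$values, weights = w)
}

#' Define a planted dominance regime
#'
#' Multiplicative overrides on selected rate parameters that force a known
#' dominant branch; used to build ensembles with ground-truth mode labels.
#'
#' @param regime_id Integer or character id (unique across regimes).
#' @param overrides Named vector of positive multiplicative factors applied
#'   to the base parameter values.
#' @return A `planted_regime`.
#' @export
planted_regime <- function(regime_id, overrides) {
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(overrides <= 0))) {
    stop("overrides must be a named vector of positive factors")
  }
  structure(list(regime_id = regime_id, overrides = overrides),
            class = "planted_regime")
}

#' Default three-regime plan for the toy bifurcation fixture
#'
#' Regime 1 forces branch-1 dominance throughout (fast `k1`, slow
#' conversion), regime 2 forces an early hand-over to branch 2 (fast
#' conversion and `k2`), and regime 3 keeps the base rates, which produce a
#' mid-course dominance switch through an on-par period.
#'
#' @return List of three [planted_regime()] objects.
#' @export
toy_regimes <- function() {
  list(planted_regime(1L, c(k1 = 50, kconv = 0.1)),
       planted_regime(2L, c(k1 = 0.02, k2 = 50, kconv = 10)),
       planted_regime(3L, c(k1 = 1)))
}

#' Build an ensemble with planted dominance regimes
#'
#' For each regime, the base parameters are scaled by the regime's overrides
#' and jittered member-by-member with log-normal multiplicative noise. At
#' construction the regimes are validated to be separable: nominal
#' (jitter-free) simulations of any two regimes must yield distinct
#' fingerprints under `cfg`, otherwise an error is raised.
#'
#' @param net A [reaction_network()] (typically [make_toy_bifurcation()]).
#' @param regimes List of [planted_regime()] objects.
#' @param n_per_regime Members drawn per regime.
#' @param jitter_sd Log10 standard deviation of the multiplicative jitter
#'   (0 = exact copies).
#' @param seed Integer seed.
#' @param base_params Base parameter values the overrides multiply.
#' @param target Target species used for the separability validation.
#' @param time_grid Time grid used for the separability validation.
#' @param cfg [dominance_config()] for the validation.
#' @return A list with `ensemble` (a [parameter_ensemble()]) and
#'   `true_labels` (integer regime id per member).
#' @export
planted_regime_ensemble <- function(net, regimes, n_per_regime,
                                    jitter_sd = 0.05, seed = 1L,
                                    base_params = toy_nominal_params(),
                                    target = "T",
                                    time_grid = toy_time_grid(),
                                    cfg = dominance_config()) {
  ids <- vapply(regimes, function(r) as.integer(r$regime_id), integer(1))
  if (anyDuplicated(ids)) stop("regime ids must be unique")
  base <- param_values(base_params, net$parameters)
  nominal <- lapply(regimes, function(r) {
    v <- base
    v[names(r$overrides)] <- v[names(r$overrides)] * r$overrides
    v
  })
  ## separability: nominal fingerprints must differ pairwise
  reg <- new_registry()
  fps <- lapply(nominal, function(v) {
    traj <- simulate_network(net, v, time_grid)
    fingerprint(net, traj, v, target, cfg, reg)$labels
  })
  for (i in seq_along(fps)) {
    for (j in seq_len(i - 1L)) {
      if (identical(fps[[i]], fps[[j]])) {
        stop("regimes ", ids[j], " and ", ids[i],
             " are not separable: identical nominal fingerprints")
      }
    }
  }
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_along(regimes), function(r) {
    jitter <- matrix(stats::rnorm(n_per_regime * length(base),
                                  sd = jitter_sd),
                     n_per_regime, length(base))
    sweep(10^jitter, 2L, nominal[[r]], `*`)
  }))
  colnames(rows) <- net$parameters
  list(ensemble = parameter_ensemble(rows),
       true_labels = rep(ids, each = n_per_regime))
}
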