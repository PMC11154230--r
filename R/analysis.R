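#' Time of death from a completion-marker trajectory
#'
#' The time of death is the midpoint of the times at which the marker
#' (cleaved PARP in the apoptosis models) first reaches 10% and 90% of its
#' trajectory maximum: `tod = (t10 + t90) / 2`. Crossings are the first
#' upward crossings, linearly interpolated between grid points. A flat-zero
#' trajectory has no defined death time and yields `NA`s.
#'
#' @param traj A `trajectory` from [simulate_network()], or a list with
#'   `time` and a species matrix `species`.
#' @param species Marker species name (e.g. `"cPARP"`).
#' @return A `tod_result` list: `t10`, `t90`, `tod` (seconds).
#' @export
time_of_death <- function(traj, species) {
  y <- species_trajectory(traj, species)
  tt <- traj$time
  ymax <- max(y)
  if (!is.finite(ymax) || ymax <= 0) {
    return(structure(list(t10 = NA_real_, t90 = NA_real_, tod = NA_real_),
                     class = "tod_result"))
  }
  t10 <- first_upward_crossing(tt, y, 0.1 * ymax)
  t90 <- first_upward_crossing(tt, y, 0.9 * ymax)
  structure(list(t10 = t10, t90 = t90, tod = (t10 + t90) / 2),
            class = "tod_result")
}

#' @export
print.tod_result <- function(x, ...) {
  cat(sprintf("time of death: %.1f s (t10 = %.1f, t90 = %.1f)\n",
              x$tod, x$t10, x$t90))
  invisible(x)
}

## First time y crosses `level` from below, linear interpolation between
## grid points; t[1] if the trajectory starts at/above the level.
first_upward_crossing <- function(t, y, level) {
  if (y[1] >= level) return(t[1])
  above <- which(y >= level)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' Peak statistics of a perturbed reaction-rate trajectory
#'
#' Compares a perturbed rate trajectory against a reference on the same
#' grid: peak value (maximum), time to peak (first argmax), and the signed
#' percentage changes `dF = 100 (peak_p - peak_r) / peak_r` and
#' `dT = 100 (tpeak_p - tpeak_r) / tpeak_r`.
#'
#' @param reference,perturbed Numeric rate trajectories.
#' @param time Shared time grid (defaults to the index grid).
#' @return A `peak_stats` list: `peak_ref`, `peak_pert`, `tpeak_ref`,
#'   `tpeak_pert`, `pct_change_peak`, `pct_change_time`.
#' @export
peak_stats <- function(reference, perturbed, time = seq_along(reference)) {
  if (length(reference) != length(perturbed) ||
      length(reference) != length(time)) {
    stop("reference, perturbed and time must share one grid")
  }
  peak_ref <- max(reference)
  if (!is.finite(peak_ref) || peak_ref <= 0) {
    stop("reference trajectory has no positive peak")
  }
  peak_pert <- max(perturbed)
  tpeak_ref <- time[which.max(reference)]
  tpeak_pert <- time[which.max(perturbed)]
  structure(list(
    peak_ref = peak_ref, peak_pert = peak_pert,
    tpeak_ref = tpeak_ref, tpeak_pert = tpeak_pert,
    pct_change_peak = 100 * (peak_pert - peak_ref) / peak_ref,
    pct_change_time = if (tpeak_ref != 0) {
      100 * (tpeak_pert - tpeak_ref) / tpeak_ref
    } else NA_real_),
    class = "peak_stats")
}

#' Ensemble peak statistics for one reaction under a perturbation
#'
#' Applies [peak_stats()] member-by-member over a set of ensemble indices
#' and summarizes the signed percentage changes by their median and
#' interquartile range, the robust convention for heavy-tailed ensembles.
#'
#' @param net A [reaction_network()]; `net_perturbed` the perturbed copy.
#' @param net_perturbed Perturbed network (e.g. from [apply_knockdown()]).
#' @param ensemble A [parameter_ensemble()].
#' @param members Integer indices (e.g. one mode's members).
#' @param reaction_id Reaction whose net rate is analysed.
#' @param time_grid Shared simulation grid.
#' @return A list with the per-member data frame `per_member` and the
#'   summary (`median_dF`, `iqr_dF`, `median_dT`, `iqr_dT`).
#' @export
ensemble_peak_stats <- function(net, net_perturbed, ensemble, members,
                                reaction_id, time_grid) {
  rows <- lapply(members, function(i) {
    pv <- ensemble_member(ensemble, i)
    ref <- reaction_rate_trajectory(
      net, simulate_network(net, pv, time_grid), reaction_id)
    per <- reaction_rate_trajectory(
      net_perturbed, simulate_network(net_perturbed, pv, time_grid),
      reaction_id)
    ps <- peak_stats(ref, per, time_grid)
    data.frame(member = i, dF = ps$pct_change_peak,
               dT = ps$pct_change_time)
  })
  per_member <- do.call(rbind, rows)
  list(per_member = per_member,
       median_dF = stats::median(per_member$dF),
       iqr_dF = unname(stats::quantile(per_member$dF, c(0.25, 0.75))),
       median_dT = stats::median(per_member$dT),
       iqr_dT = unname(stats::quantile(per_member$dT, c(0.25, 0.75))))
}

#' In-silico knockdown experiment across execution modes
#'
#' Simulates every ensemble member under wild-type and knockdown conditions
#' and reports, per execution mode, the mean and standard deviation of the
#' time of death plus the knockdown-induced shift
#' `delta_t = mean(ToD_KD) - mean(ToD_WT)`.
#'
#' @param net A [reaction_network()].
#' @param ensemble A [parameter_ensemble()].
#' @param modes An [execution_modes()] object on the same ensemble.
#' @param species Species to knock down.
#' @param fraction Knockdown fraction in \[0, 1\].
#' @param marker Death marker species for [time_of_death()] (default
#'   `"cPARP"`).
#' @param time_grid Shared simulation grid.
#' @param rtol,atol Solver tolerances.
#' @return A `knockdown_result`: per-mode data frame `summary`
#'   (`mode_id`, `n`, `tod_wt_mean`, `tod_wt_sd`, `tod_kd_mean`,
#'   `tod_kd_sd`, `delta_t`) plus per-member `tod_wt` / `tod_kd` vectors.
#' @export
knockdown_experiment <- function(net, ensemble, modes, species, fraction,
                                 marker = "cPARP", time_grid,
                                 rtol = 1e-6, atol = 1e-6) {
  kd_net <- apply_knockdown(net, species, fraction)
  n <- length(ensemble)
  tod_wt <- numeric(n); tod_kd <- numeric(n)
  for (i in seq_len(n)) {
    pv <- ensemble_member(ensemble, i)
    tod_wt[i] <- time_of_death(
      simulate_network(net, pv, time_grid, rtol, atol), marker)$tod
    tod_kd[i] <- time_of_death(
      simulate_network(kd_net, pv, time_grid, rtol, atol), marker)$tod
  }
  ids <- modes$summary$mode_id
  summ <- do.call(rbind, lapply(ids, function(m) {
    idx <- modes$members[[as.character(m)]]
    data.frame(mode_id = m, n = length(idx),
               tod_wt_mean = mean(tod_wt[idx], na.rm = TRUE),
               tod_wt_sd = stats::sd(tod_wt[idx]),
               tod_kd_mean = mean(tod_kd[idx], na.rm = TRUE),
               tod_kd_sd = stats::sd(tod_kd[idx]),
               delta_t = mean(tod_kd[idx], na.rm = TRUE) -
                 mean(tod_wt[idx], na.rm = TRUE))
  }))
  structure(list(summary = summ, tod_wt = tod_wt, tod_kd = tod_kd,
                 species = species, fraction = fraction),
            class = "knockdown_result")
}

#' @export
print.knockdown_result <- function(x, ...) {
  cat(sprintf("knockdown of %s by %.0f%%: per-mode time-of-death shift\n",
              x$species, 100 * x$fraction))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-mode density model of a measurable parameter
#'
#' Fits, for each execution mode, a Gaussian kernel density estimate of the
#' member values of one kinetic parameter in log10 space (bandwidth by
#' Silverman's reference rule), and stores the modes' prior probabilities.
#' Used by [update_mode_probabilities()] to propagate a parameter
#' measurement into the mode posterior.
#'
#' @param ensemble A [parameter_ensemble()].
#' @param modes An [execution_modes()] object.
#' @param parameter Parameter (column) name.
#' @return A `mode_density_model`.
#' @export
mode_density_model <- function(ensemble, modes, parameter) {
  if (!parameter %in% colnames(ensemble$values)) {
    stop("unknown parameter: ", parameter)
  }
  ids <- modes$summary$mode_id
  dens <- lapply(ids, function(m) {
    v <- log10(ensemble$values[modes$members[[as.character(m)]], parameter])
    if (length(v) < 2L || stats::sd(v) == 0) {
      ## degenerate mode: a narrow Gaussian around the common value
      list(point = mean(v), bw = max(1e-3, abs(mean(v)) * 1e-6))
    } else {
      stats::density(v, bw = "nrd0", n = 512L, cut = 4)
    }
  })
  structure(list(priors = stats::setNames(modes$summary$probability, ids),
                 densities = stats::setNames(dens, ids),
                 parameter = parameter),
            class = "mode_density_model")
}

## Evaluate one stored density at log10 value s.
eval_density <- function(d, s) {
  if (!is.null(d$point)) {
    stats::dnorm(s, mean = d$point, sd = d$bw)
  } else {
    if (s < min(d$x) || s > max(d$x)) return(0)
    stats::approx(d$x, d$y, xout = s, rule = 1)$y
  }
}

#' Bayesian update of mode probabilities after a parameter measurement
#'
#' Given a measured value `s` of the model parameter, the posterior
#' probability of mode i is `p_i X_i(s) / sum_j p_j X_j(s)`, where `p_i`
#' are the prior mode probabilities and `X_i` the per-mode densities of the
#' parameter. The posterior is invariant to a common positive rescaling of
#' the densities and always sums to 1.
#'
#' @param model A [mode_density_model()], or a list with `priors` and
#'   numeric `densities` evaluated at `s` (for direct plug-in use).
#' @param s Measured parameter value (natural rate scale for a
#'   `mode_density_model`, whose densities live in log10 space).
#' @return Named numeric vector of posterior mode probabilities.
#' @export
update_mode_probabilities <- function(model, s) {
  if (inherits(model, "mode_density_model")) {
    x <- vapply(model$densities, eval_density, numeric(1), s = log10(s))
  } else {
    x <- as.numeric(model$densities)
  }
  p <- model$priors
  if (length(p) != length(x)) stop("priors and densities length mismatch")
  if (abs(sum(p) - 1) > 1e-9) stop("prior mode probabilities must sum to 1")
  if (any(x < 0)) stop("densities must be nonnegative")
  num <- p * x
  if (sum(num) <= 0) {
    stop("measured value is incompatible with every mode ",
         "(all densities are zero at s)")
  }
  num / sum(num)
}

#' Classify parameter vectors into execution modes
#'
#' Trains a gradient-boosted tree classifier (xgboost, multiclass soft-max,
#' learning rate 0.1, 100 rounds) on log10 parameter values, using a random
#' `split_fraction` / `1 - split_fraction` train/test partition, and
#' reports held-out accuracy plus a gain-based parameter importance
#' ranking — a screen for which kinetic parameters carry mode identity.
#'
#' @param ensemble A [parameter_ensemble()].
#' @param mode_labels Integer mode label per member (>= 2 distinct values).
#' @param split_fraction Training fraction (default 0.75).
#' @param seed Integer seed (split and training are deterministic given it).
#' @param nrounds,eta Boosting rounds and learning rate.
#' @return A `mode_classifier_report`: `accuracy`, `majority_baseline`,
#'   `importance` (data frame ordered by total gain), `confusion` table and
#'   the fitted `model`.
#' @export
classify_modes <- function(ensemble, mode_labels, split_fraction = 0.75,
                           seed = 1L, nrounds = 100L, eta = 0.1) {
  n <- length(ensemble)
  if (length(mode_labels) != n) stop("mode_labels length mismatch")
  if (n < 20L) stop("need at least 20 parameter vectors")
  classes <- sort(unique(mode_labels))
  if (length(classes) < 2L) stop("need at least 2 modes to classify")
  y <- match(mode_labels, classes) - 1L
  X <- log10(ensemble$values)
  set.seed(seed)
  train <- sort(sample.int(n, size = round(split_fraction * n)))
  test <- setdiff(seq_len(n), train)
  if (!length(test)) stop("empty test set; lower split_fraction")
  dtrain <- xgboost::xgb.DMatrix(X[train, , drop = FALSE],
                                 label = y[train])
  fit <- xgboost::xgb.train(
    params = list(booster = "gbtree", objective = "multi:softmax",
                  num_class = length(classes), eta = eta,
                  max_bin = 16L, alpha = 1, lambda = 1,
                  eval_metric = "merror", nthread = 1L, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  pred <- predict(fit, xgboost::xgb.DMatrix(X[test, , drop = FALSE]))
  acc <- mean(pred == y[test])
  baseline <- max(table(y[test])) / length(test)
  imp <- xgboost::xgb.importance(model = fit)
  importance <- data.frame(parameter = imp$Feature,
                           gain = imp$Gain,
                           stringsAsFactors = FALSE)
  structure(list(accuracy = acc, majority_baseline = baseline,
                 importance = importance,
                 confusion = table(predicted = classes[pred + 1L],
                                   truth = classes[y[test] + 1L]),
                 model = fit),
            class = "mode_classifier_report")
}

#' @export
print.mode_classifier_report <- function(x, ...) {
  cat(sprintf(
    "mode classifier: held-out accuracy %.3f (majority baseline %.3f)\n",
    x$accuracy, x$majority_baseline))
  cat("top parameters by gain:\n")
  print(utils::head(x$importance, 5L), row.names = FALSE)
  invisible(x)
}
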