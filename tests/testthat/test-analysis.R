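fake_traj <- function(time, y, name = "M") {
  structure(list(time = time,
                 species = matrix(y, ncol = 1,
                                  dimnames = list(NULL, name)),
                 rates = NULL),
            class = "trajectory")
}

test_that("time of death: linear ramp gives the exact midpoint", {
  tt <- seq(0, 1200, by = 10)
  y <- pmin(tt, 1000)              # linear rise to max over [0, 1000]
  tod <- time_of_death(fake_traj(tt, y), "M")
  expect_equal(tod$t10, 100)
  expect_equal(tod$t90, 900)
  expect_equal(tod$tod, 500)
})

test_that("time of death: step, flat-zero and rescaling behaviour", {
  tt <- seq(0, 100, by = 1)
  step <- ifelse(tt < 50, 0, 1000)
  tod <- time_of_death(fake_traj(tt, step), "M")
  expect_equal(tod$tod, 50, tolerance = 0.02)
  expect_true(is.na(time_of_death(fake_traj(tt, rep(0, 101)), "M")$tod))
  # depends only on fractional thresholds: invariant to positive rescaling
  curve <- 1000 / (1 + exp(-(tt - 40) / 6))
  t1 <- time_of_death(fake_traj(tt, curve), "M")
  t2 <- time_of_death(fake_traj(tt, 7.3 * curve), "M")
  expect_equal(t1$tod, t2$tod)
  expect_lte(t1$t10, t1$t90)
})

test_that("interpolated crossings agree with a refined-grid recomputation", {
  f <- function(t) 500 * (1 + tanh((t - 380) / 90))
  coarse <- seq(0, 1000, length.out = 26)
  fine <- seq(0, 1000, length.out = 251)
  tod_c <- time_of_death(fake_traj(coarse, f(coarse)), "M")
  tod_f <- time_of_death(fake_traj(fine, f(fine)), "M")
  step <- coarse[2] - coarse[1]
  expect_lt(abs(tod_c$t10 - tod_f$t10), step)
  expect_lt(abs(tod_c$t90 - tod_f$t90), step)
  expect_lt(abs(tod_c$tod - tod_f$tod), step)
})

test_that("peak statistics: identity, exact scaling, and shifted peaks", {
  tt <- seq(0, 200, by = 1)
  ref <- exp(-(tt - 100)^2 / 500)
  same <- peak_stats(ref, ref, tt)
  expect_equal(same$pct_change_peak, 0)
  expect_equal(same$pct_change_time, 0)
  half <- peak_stats(ref, 0.5 * ref, tt)
  expect_identical(half$pct_change_peak, -50)
  expect_equal(half$pct_change_time, 0)
  shifted <- exp(-(tt - 88)^2 / 500)
  sh <- peak_stats(ref, shifted, tt)
  expect_equal(sh$pct_change_time, -12)
  expect_error(peak_stats(rep(0, 10), rep(1, 10)), "positive peak")
})

test_that("Bayesian mode update conserves and rescales correctly", {
  m <- list(priors = c(0.5, 0.5), densities = c(2, 1))
  post <- update_mode_probabilities(m, s = NA)
  expect_equal(post, c(2 / 3, 1 / 3))
  expect_equal(sum(post), 1)
  # equal densities reduce the posterior to the prior
  pr <- c(0.2, 0.3, 0.5)
  expect_equal(update_mode_probabilities(
    list(priors = pr, densities = c(4, 4, 4)), NA), pr)
  # support on one mode only
  expect_equal(update_mode_probabilities(
    list(priors = c(0.5, 0.3, 0.2), densities = c(0, 2, 0)), NA),
    c(0, 1, 0))
  # invariant to a common positive rescaling of the densities
  expect_equal(update_mode_probabilities(
    list(priors = pr, densities = c(1, 5, 2) * 1e6), NA),
    update_mode_probabilities(list(priors = pr, densities = c(1, 5, 2)), NA))
  expect_error(update_mode_probabilities(
    list(priors = pr, densities = c(0, 0, 0)), NA), "incompatible")
})

test_that("kernel density model separates modes along a parameter", {
  set.seed(21)
  n <- 60
  vals <- cbind(k1 = 10^c(rnorm(n / 2, -2, 0.1), rnorm(n / 2, 1, 0.1)),
                k2 = 10^rnorm(n, 0, 0.1))
  ens <- parameter_ensemble(vals)
  modes <- execution_modes(rep(1:2, each = n / 2), ens,
                           matrix(1L, n, 3))
  dm <- mode_density_model(ens, modes, "k1")
  post_low <- update_mode_probabilities(dm, 1e-2)
  post_high <- update_mode_probabilities(dm, 10)
  expect_gt(post_low[["1"]], 0.99)
  expect_gt(post_high[["2"]], 0.99)
  expect_equal(sum(post_low), 1)
  expect_error(mode_density_model(ens, modes, "nope"), "unknown parameter")
})

test_that("no-op knockdown leaves every mode's time of death unchanged", {
  toy <- make_toy_bifurcation()
  pr <- planted_regime_ensemble(toy, toy_regimes(), n_per_regime = 3,
                                seed = 13)
  fps <- fingerprint_ensemble(toy, pr$ensemble, "T", toy_time_grid())
  modes <- execution_modes(pr$true_labels, pr$ensemble, fps)
  kd <- knockdown_experiment(toy, pr$ensemble, modes, "A", 0,
                             marker = "T", time_grid = toy_time_grid())
  expect_equal(kd$summary$delta_t, rep(0, 3))
})

test_that("knocking down a rate-limiting species delays the marker", {
  net <- make_aearm()
  values <- rbind(aearm_nominal_params()$values,
                  aearm_nominal_params()$values * 1.2)
  colnames(values) <- net$parameters
  ens <- parameter_ensemble(values)
  modes <- execution_modes(c(1, 1), ens, matrix(1L, 2, 3))
  kd <- knockdown_experiment(net, ens, modes, "eC", 0.5,
                             marker = "cPARP",
                             time_grid = aearm_time_grid(60))
  expect_gt(kd$summary$delta_t, 0)
})

test_that("mode classifier learns a single separating parameter", {
  set.seed(31)
  n <- 100
  vals <- cbind(k1 = 10^c(rnorm(n / 2, -3, 0.2), rnorm(n / 2, 0, 0.2)),
                k2 = 10^rnorm(n, -1, 0.5),
                k3 = 10^rnorm(n, -2, 0.5))
  ens <- parameter_ensemble(vals)
  labels <- rep(1:2, each = n / 2)
  rep1 <- classify_modes(ens, labels, seed = 5)
  expect_gte(rep1$accuracy, 0.95)
  expect_equal(rep1$importance$parameter[1], "k1")
  rep2 <- classify_modes(ens, labels, seed = 5)
  expect_equal(rep1$accuracy, rep2$accuracy)
  # shuffled labels collapse to the majority-class baseline
  set.seed(6)
  rep0 <- classify_modes(ens, sample(labels), seed = 5)
  expect_lt(abs(rep0$accuracy - rep0$majority_baseline), 0.1)
  expect_error(classify_modes(ens, rep(1, n)), "at least 2 modes")
})
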