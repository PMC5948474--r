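# Short chains throughout: these tests exercise the sampler's contracts
# (determinism, constraint preservation, retention schedule), not accuracy.
short_cfg <- function(seed) mcmc_config(600, 300, 10, seed = seed)

test_that("the retention schedule yields (iterations - burn_in)/thin draws", {
  s <- tiny_mfrm_setup()
  fit <- fit_rater_model(s$data, "mfrm", short_cfg(1))
  expect_equal(n_draws(fit), 30)
  expect_equal(nrow(fit$pointwise), 30)
  expect_equal(ncol(fit$pointwise), rating_dims(s$data)$n_obs)
  # the default schedule retains exactly 100 draws
  cfg <- mcmc_config()
  expect_equal((cfg$iterations - cfg$burn_in) / cfg$thin, 100)
  expect_error(mcmc_config(1000, 900, 100), "at least 10 draws")
  expect_error(mcmc_config(1000, 2000, 10))
})

test_that("identical seeds reproduce the fit bit for bit", {
  s <- tiny_mfrm_setup()
  f1 <- fit_rater_model(s$data, "mfrm", short_cfg(7))
  f2 <- fit_rater_model(s$data, "mfrm", short_cfg(7))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("every retained draw satisfies the model constraints", {
  set.seed(77)
  J <- 10; I <- 2; R <- 3; K <- 4
  for (m in c("mfrm", "patz1999", "ueno2008", "uto2016", "hrm")) {
    truth <- draw_true_params(m, J = J, I = I, R = R, K = K)
    data <- simulate_ratings(truth)
    fit <- fit_rater_model(data, m, short_cfg(8))
    s <- fit$samples
    expect_true(all(is.finite(unlist(s))))
    # tuned acceptance rates stay in the engineering band
    acc <- unlist(fit$accept)
    expect_true(all(acc[!is.na(acc)] > 0.1 & acc[!is.na(acc)] < 0.7))
    if (m == "mfrm") {
      expect_true(all(s$beta_rater[, 1] == 0)) # fixed, never moves
      expect_true(all(s$d_cat[, 1] == 0))
      expect_equal(rowSums(s$d_cat[, -1]), rep(0, nrow(s$d_cat)),
                   tolerance = 1e-12)
    }
    if (m == "patz1999") {
      expect_true(all(s$alpha > 0))
      expect_true(all(s$beta_step[, seq(1, by = K, length.out = I)] == 0))
      expect_true(all(s$rho[, seq(1, by = R, length.out = I)] == 0))
    }
    if (m == "ueno2008") {
      expect_true(all(s$eps[, 1] == -1.0))
      eps <- array(t(s$eps), c(K - 1, R, nrow(s$eps)))
      expect_true(all(apply(eps, c(2, 3), function(e) all(diff(e) > 0))))
    }
    if (m == "uto2016") {
      expect_true(all(s$alpha_rater[, 1] == 1))
      expect_true(all(s$eps_rater[, 1] == 0))
      expect_true(all(s$alpha_rater > 0) && all(s$alpha_task > 0))
      b <- array(t(s$b_cat), c(K - 1, I, nrow(s$b_cat)))
      expect_true(all(apply(b, c(2, 3), function(e) all(diff(e) > 0))))
    }
    if (m == "hrm") {
      expect_true(all(s$psi > 0))
      xi <- s$xi
      expect_true(all(xi >= 1 & xi <= K & xi == round(xi)))
      dm <- s$d_step[, seq(1, by = K, length.out = I), drop = FALSE]
      expect_true(all(dm == 0))
    }
  }
})

test_that("EAP estimates are draw means with fixed values and order preserved", {
  set.seed(78)
  truth <- draw_true_params("ueno2008", J = 10, I = 2, R = 3, K = 4)
  data <- simulate_ratings(truth)
  fit <- fit_rater_model(data, "ueno2008", short_cfg(9))
  est <- eap(fit)
  expect_equal(est$theta, colMeans(fit$samples$theta))
  expect_equal(est$b_task, colMeans(fit$samples$b_task))
  expect_equal(est$eps[1, 1], -1.0)
  # means of ordered draws stay ordered
  expect_true(all(apply(est$eps, 1, function(e) all(diff(e) > 0))))
})

test_that("HRM ideal-rating point estimates are posterior modal categories", {
  set.seed(79)
  truth <- draw_true_params("hrm", J = 8, I = 2, R = 4, K = 5)
  data <- simulate_ratings(truth)
  fit <- fit_rater_model(data, "hrm", short_cfg(10))
  est <- eap(fit)
  xi_draws <- matrix(as.integer(fit$samples$xi), n_draws(fit))
  modes <- apply(xi_draws, 2, function(v) which.max(tabulate(v, 5)))
  expect_equal(as.vector(t(est$xi)), modes)
  expect_true(all(est$xi %in% 1:5))
})

test_that("units without observations trigger a warning and stay near the prior mean", {
  df <- expand.grid(examinee = 1:8, task = 1:2, rater = 1:2)
  df$rating <- sample(1:3, nrow(df), replace = TRUE)
  data <- rating_data(df, K = 3, rater_ids = 1:3) # rater 3 never observed
  expect_warning(fit <- fit_rater_model(data, "mfrm", short_cfg(11)),
                 "no observed ratings")
  expect_true(all(fit$samples$beta_rater[, 3] == 0))
})

test_that("posterior CSV export and config YAML round-trip", {
  s <- tiny_mfrm_setup()
  fit <- fit_rater_model(s$data, "mfrm", short_cfg(12))
  f <- withr::local_tempfile(fileext = ".csv")
  write_posterior_csv(fit, f)
  tab <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(tab), n_draws(fit))
  expect_true("theta[1]" %in% names(tab))
  expect_equal(tab[["beta_task[1]"]], unname(fit$samples$beta_task[, 1]))

  cfgf <- withr::local_tempfile(fileext = ".yaml")
  write_config_yaml(mcmc_config(2000, 1000, 10, seed = 3), cfgf)
  cfg <- read_config_yaml(cfgf)
  expect_equal(cfg$iterations, 2000L)
  expect_equal(cfg$seed, 3)
  prf <- withr::local_tempfile(fileext = ".yaml")
  write_prior_yaml(prior_spec("uto2016", 5), prf)
  pr <- read_prior_yaml(prf)
  expect_equal(pr$mu_ord, c(-1.5, -0.75, 0.75, 1.5))
  expect_equal(pr$model, "uto2016")
})

test_that("tidy and glance summarise a fit in broom style", {
  s <- tiny_mfrm_setup()
  fit <- fit_rater_model(s$data, "mfrm", short_cfg(13))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("block", "index", "estimate", "std_error"))
  d <- rating_dims(s$data)
  expect_equal(nrow(td), d$J + d$I + d$R + d$K)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_params, count_params("mfrm", d$J, d$I, d$R, d$K))
})

test_that("ability re-estimation given fixed parameters is self-consistent", {
  set.seed(80)
  truth <- draw_true_params("mfrm", J = 20, I = 3, R = 4, K = 5)
  data <- simulate_ratings(truth)
  fit <- fit_rater_model(data, "mfrm", mcmc_config(2000, 1000, 10, seed = 14))
  est <- eap(fit)
  ab <- estimate_ability_given_params(data, est)
  # quadrature EAP on the same complete data stays close to the MCMC EAP
  expect_lt(rmse(ab$theta, est$theta), 0.1)
  expect_gt(cor(ab$theta, est$theta), 0.98)
  # an examinee rated top category everywhere moves above the mean
  x <- as_rating_array(data)
  x[, 1, ] <- 5L
  ab2 <- estimate_ability_given_params(
    raterirt:::array_to_rating_data(x, 5), est)
  expect_gt(ab2$theta[1], mean(ab2$theta))
  # all-missing examinee falls back to the prior mean with a warning
  x3 <- as_rating_array(data)
  x3[, 2, ] <- -1L
  expect_warning(
    ab3 <- estimate_ability_given_params(
      raterirt:::array_to_rating_data(x3, 5, e_ids = 1:20), est),
    "prior mean")
  expect_equal(ab3$theta[2], 0)
})

test_that("sparse judge-pair data still yield usable abilities", {
  set.seed(81)
  truth <- draw_true_params("ueno2008", J = 20, I = 3, R = 4, K = 5)
  data <- simulate_ratings(truth)
  fit <- fit_rater_model(data, "ueno2008", mcmc_config(2000, 1000, 10, seed = 15))
  est <- eap(fit)
  red <- judge_pair(data, seed = 16)
  ab_full <- estimate_ability_given_params(data, est)
  ab_red <- estimate_ability_given_params(red, est)
  expect_gt(cor(ab_red$theta, ab_full$theta), 0.7)
  # fewer ratings, larger error against the complete-data abilities
  expect_gt(rmse(ab_red$theta, ab_full$theta), 0)
})

test_that("posterior concentrates with plentiful data per parameter", {
  # one task, few raters, many examinees: rater/task parameters are
  # informed by thousands of ratings and land close to truth
  set.seed(82)
  truth <- draw_true_params("mfrm", J = 300, I = 2, R = 3, K = 4)
  data <- simulate_ratings(truth)
  fit <- fit_rater_model(data, "mfrm", mcmc_config(3000, 1500, 15, seed = 17))
  est <- eap(fit)
  expect_lt(rmse(raterirt:::rater_task_params(est),
                 raterirt:::rater_task_params(truth)), 0.12)
})
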