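#' MCMC configuration
#'
#' The default schedule retains the posterior means of draws taken from
#' iteration 10,000 to 20,000 at intervals of 100, i.e. 100 retained draws
#' per parameter. `(iterations - burn_in) / thin` must be at least 10.
#' The configuration round-trips to YAML via [write_config_yaml()].
#'
#' @param iterations Total chain length (default 20000).
#' @param burn_in Burn-in iterations discarded (default 10000); proposal
#'   scales adapt only during this phase.
#' @param thin Thinning interval (default 100).
#' @param seed Optional integer seed applied at the start of the fit.
#' @return A list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(iterations = 20000, burn_in = 10000, thin = 100,
                        seed = NULL) {
  stopifnot(burn_in >= 0, burn_in < iterations, thin >= 1)
  if ((iterations - burn_in) / thin < 10) {
    stop("config must retain at least 10 draws: (iterations - burn_in)/thin >= 10",
         call. = FALSE)
  }
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @param config An `mcmc_config` object.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname mcmc_config
#' @export
read_config_yaml <- function(path) {
  o <- yaml::read_yaml(path)
  mcmc_config(o$iterations, o$burn_in, o$thin, o$seed)
}

#' Fit a rater-effect model by MCMC
#'
#' Runs a single-chain Metropolis-within-Gibbs sampler (see the package
#' vignette for the update scheme) and returns the thinned post-burn-in
#' draws. Priors default to the generating distributions of
#' [draw_true_params()] with \eqn{\theta \sim N(0, 1)}. Point estimates are
#' obtained from the returned object with [eap()]; model-comparison scores
#' with [criterion_scores()].
#'
#' @param data A [rating_data()] object (or data frame plus `K`).
#' @param model Model id: `"mfrm"`, `"patz1999"`, `"ueno2008"`, `"uto2016"`
#'   or `"hrm"`.
#' @param config An [mcmc_config()].
#' @param priors A [prior_spec()]; defaults to the generating distributions.
#' @param K Category count when `data` is a plain data frame.
#' @return An object of class `"rater_fit"` with elements `samples` (one
#'   matrix of retained draws per parameter block), `pointwise` (retained
#'   draws x observations matrix of log-probabilities), `loglik` (total
#'   log-likelihood per retained draw), `accept` (post-burn-in acceptance
#'   rate per block) and metadata.
#' @examples
#' truth <- draw_true_params("mfrm", J = 15, I = 2, R = 3, K = 3, seed = 1)
#' data <- simulate_ratings(truth, seed = 2)
#' fit <- fit_rater_model(data, "mfrm",
#'                        mcmc_config(600, 300, 30, seed = 3))
#' eap(fit)
#' @export
fit_rater_model <- function(data, model, config = mcmc_config(),
                            priors = NULL, K = NULL) {
  model <- match_model(model)
  data <- as_rating_data(data, K)
  d <- rating_dims(data)
  if (is.null(priors)) priors <- prior_spec(model, d$K)
  stopifnot(inherits(config, "mcmc_config"))
  idx <- obs_index(data)
  check_coverage(idx, d)
  if (!is.null(config$seed)) set.seed(config$seed)
  xi_init <- hrm_xi_init(idx, d)
  res <- cpp_fit_model(model, idx$i, idx$j, idx$r, idx$x,
                       d$I, d$J, d$R, d$K,
                       config$iterations, config$burn_in, config$thin,
                       unclass(priors), xi_init)
  structure(list(
    model = model, samples = res$samples, pointwise = res$pointwise,
    loglik = as.numeric(res$loglik), accept = res$accept, config = config,
    dims = d, data_ids = list(examinee = attr(data, "examinee_ids"),
                              task = attr(data, "task_ids"),
                              rater = attr(data, "rater_ids"))
  ), class = "rater_fit")
}

check_coverage <- function(idx, d) {
  miss <- c(
    if (length(setdiff(seq_len(d$J), idx$j)) > 0) "examinee(s)",
    if (length(setdiff(seq_len(d$I), idx$i)) > 0) "task(s)",
    if (length(setdiff(seq_len(d$R), idx$r)) > 0) "rater(s)"
  )
  if (length(miss)) {
    warning("some ", paste(miss, collapse = ", "),
            " have no observed ratings; their parameters are held near the prior mean",
            call. = FALSE)
  }
}

# initial ideal ratings: rounded mean observed rating per (task, examinee)
hrm_xi_init <- function(idx, d) {
  s <- matrix(0, d$I, d$J)
  n <- matrix(0, d$I, d$J)
  ij <- cbind(idx$i, idx$j)
  for (t in seq_along(idx$i)) {
    s[ij[t, , drop = FALSE]] <- s[ij[t, , drop = FALSE]] + idx$x[t]
    n[ij[t, , drop = FALSE]] <- n[ij[t, , drop = FALSE]] + 1
  }
  xi <- round(s / pmax(n, 1))
  xi[n == 0] <- ceiling(d$K / 2)
  as.integer(pmin(pmax(xi, 1), d$K))
}

#' Number of retained draws of a fit
#' @param fit A `rater_fit` object.
#' @export
n_draws <- function(fit) length(fit$loglik)

#' @export
print.rater_fit <- function(x, ...) {
  cat(sprintf(
    "<rater_fit: %s> %d retained draws (%d iterations, burn-in %d, thin %d)\n",
    x$model, n_draws(x), x$config$iterations, x$config$burn_in, x$config$thin))
  cat(sprintf("  data: J=%d, I=%d, R=%d, K=%d, %d ratings\n",
              x$dims$J, x$dims$I, x$dims$R, x$dims$K, x$dims$n_obs))
  acc <- unlist(x$accept)
  cat("  acceptance:", paste(sprintf("%s=%.2f", names(acc), acc), collapse = ", "),
      "\n")
  invisible(x)
}

#' Expected-a-posteriori point estimates from a fit
#'
#' Per-parameter arithmetic means of the retained draws, returned as a
#' parameter bundle of the fitted model's class. Identifiability-fixed
#' parameters are returned at their fixed values. The HRM's latent ideal
#' ratings are category-valued, so their point estimate is the per-outcome
#' posterior modal category rather than a mean.
#'
#' @param fit A `rater_fit` object.
#' @return A [rater_params] bundle (including the EAP abilities).
#' @export
eap <- function(fit) {
  stopifnot(inherits(fit, "rater_fit"))
  if (n_draws(fit) == 0) stop("empty sample set", call. = FALSE)
  m <- lapply(fit$samples, colMeans)
  d <- fit$dims
  th <- m$theta
  switch(fit$model,
    mfrm = mfrm_params(m$beta_task, zap(m$beta_rater, 1), zap_d(m$d_cat), th),
    patz1999 = patz_params(m$alpha,
                           zap_col1(matrix(m$beta_step, d$I, d$K, byrow = TRUE)),
                           zap_col1(matrix(m$rho, d$I, d$R, byrow = TRUE)), th),
    ueno2008 = ueno_params(m$alpha, m$b_task,
                           matrix(m$eps, d$R, d$K - 1, byrow = TRUE), th),
    uto2016 = uto_params(m$alpha_task, fix1(m$alpha_rater, 1),
                         matrix(m$b_cat, d$I, d$K - 1, byrow = TRUE),
                         zap(m$eps_rater, 1), th),
    hrm = {
      xi_draws <- matrix(as.integer(fit$samples$xi), n_draws(fit))
      xi_mode <- apply(xi_draws, 2, function(v) {
        tb <- tabulate(v, d$K)
        which.max(tb)
      })
      hrm_params(m$beta_task, zap_d_rows(matrix(m$d_step, d$I, d$K, byrow = TRUE)),
                 matrix(xi_mode, d$I, d$J, byrow = TRUE), m$sigma, m$psi, th)
    }
  )
}

zap <- function(v, k) { v[k] <- 0; v }
fix1 <- function(v, k) { v[k] <- 1; v }
zap_col1 <- function(m) { m[, 1] <- 0; m }
zap_d <- function(d) { d[1] <- 0; d[-1] <- d[-1] - mean(d[-1]); d }
zap_d_rows <- function(m) {
  m[, 1] <- 0
  m[, -1] <- m[, -1, drop = FALSE] - rowMeans(m[, -1, drop = FALSE])
  m
}

#' Tidy summary of a fitted model
#'
#' One row per scalar parameter with its EAP estimate and posterior standard
#' deviation, in broom style.
#'
#' @param x A `rater_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `block`, `index`, `estimate`, `std_error`.
#' @export
tidy.rater_fit <- function(x, ...) {
  purrr::map_dfr(names(x$samples), function(nm) {
    s <- x$samples[[nm]]
    tibble::tibble(block = nm, index = seq_len(ncol(s)),
                   estimate = colMeans(s), std_error = apply(s, 2, sd))
  })
}

#' One-line summary of a fitted model
#'
#' @param x A `rater_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the model id, dimensions, parameter count,
#'   mean log-likelihood over retained draws and mean acceptance rate.
#' @export
glance.rater_fit <- function(x, ...) {
  d <- x$dims
  tibble::tibble(
    model = x$model, J = d$J, I = d$I, R = d$R, K = d$K, n_obs = d$n_obs,
    n_params = count_params(x$model, d$J, d$I, d$R, d$K),
    n_draws = n_draws(x),
    mean_log_lik = mean(x$loglik),
    mean_acceptance = mean(unlist(x$accept), na.rm = TRUE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Export retained posterior draws to CSV
#'
#' One column per scalar parameter (named `block[index]`), one row per
#' retained draw.
#'
#' @param fit A `rater_fit` object.
#' @param path Output file path.
#' @export
write_posterior_csv <- function(fit, path) {
  cols <- purrr::imap(fit$samples, function(s, nm) {
    colnames(s) <- sprintf("%s[%d]", nm, seq_len(ncol(s)))
    s
  })
  df <- as.data.frame(do.call(cbind, unname(cols)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Ability estimation with rater and task parameters held fixed
#'
#' Computes the expected-a-posteriori ability of every examinee under a
#' standard-normal prior with all rater/task/category parameters fixed at
#' the supplied values. Because the examinees are conditionally independent
#' given fixed parameters, each posterior is one-dimensional and is
#' integrated exactly by quadrature on a fine grid; no Monte-Carlo noise
#' enters. Designed for re-scoring sparse designs (e.g. [judge_pair()]
#' data) with parameters estimated from complete data.
#'
#' @param data A [rating_data()] object; may be heavily missing.
#' @param params A [rater_params] bundle (e.g. from [eap()]).
#' @param grid Quadrature grid for the ability (default 241 points on
#'   \[-6, 6\]).
#' @return A tibble with columns `examinee` and `theta`. Examinees with no
#'   observed ratings get the prior mean 0, with a warning.
#' @export
estimate_ability_given_params <- function(data, params,
                                          grid = seq(-6, 6, length.out = 241)) {
  data <- as_rating_data(data, params$K)
  d <- rating_dims(data)
  pd <- params_dims(params)
  if (d$I != pd$I || d$R != pd$R || d$K != pd$K || d$J != pd$J) {
    stop("parameter and data dimensions do not match", call. = FALSE)
  }
  idx <- obs_index(data)
  G <- length(grid)
  lpost <- matrix(dnorm(grid, log = TRUE), d$J, G, byrow = TRUE)
  for (i in seq_len(d$I)) {
    for (r in seq_len(d$R)) {
      sel <- which(idx$i == i & idx$r == r)
      if (!length(sel)) next
      lpm <- log_prob_matrix(params, i, r, grid) # G x K
      for (t in sel) {
        lpost[idx$j[t], ] <- lpost[idx$j[t], ] + lpm[, idx$x[t]]
      }
    }
  }
  w <- exp(lpost - apply(lpost, 1, max))
  theta <- as.numeric((w %*% grid) / rowSums(w))
  nobs <- tabulate(idx$j, d$J)
  if (any(nobs == 0)) {
    warning(sum(nobs == 0),
            " examinee(s) have no ratings; ability set to the prior mean 0",
            call. = FALSE)
    theta[nobs == 0] <- 0
  }
  tibble::tibble(examinee = attr(data, "examinee_ids"), theta = theta)
}
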