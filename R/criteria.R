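# Model-comparison criteria. All four scores are reported on a common
# "larger is better" log scale: AIC' = logL(EAP) - p, BIC' = logL(EAP) -
# (p/2) ln n, WAIC' = lppd - p_waic, ML = log evidence. The conventional
# -2x deviance versions are available through `scale = "deviance"` in
# criterion_scores().

#' AIC-type score of a fitted model
#'
#' Log-likelihood at the EAP estimates minus the parameter count (larger is
#' better). The parameter count follows [count_params()].
#'
#' @param fit A `rater_fit` object.
#' @param data The [rating_data()] the model was fitted to.
#' @return Scalar score.
#' @export
aic_score <- function(fit, data) {
  loglik_at_eap(fit, data) - n_params_fit(fit)
}

#' BIC-type score of a fitted model
#'
#' Log-likelihood at the EAP estimates minus `(p / 2) * log(n_obs)`, where
#' `n_obs` is the number of non-missing ratings (the likelihood's factor
#' count). Larger is better.
#'
#' @inheritParams aic_score
#' @export
bic_score <- function(fit, data) {
  n <- rating_dims(as_rating_data(data, fit$dims$K))$n_obs
  if (n == 0) stop("no observations", call. = FALSE)
  loglik_at_eap(fit, data) - n_params_fit(fit) / 2 * log(n)
}

loglik_at_eap <- function(fit, data) {
  # the HRM's ideal ratings are counted as parameters by count_params(), so
  # the criterion likelihood conditions on them (matching the models'
  # conventional accounting); the other models have no latent stage
  log_likelihood(eap(fit), as_rating_data(data, fit$dims$K),
                 hrm_conditional = fit$model == "hrm")
}

n_params_fit <- function(fit) {
  d <- fit$dims
  count_params(fit$model, d$J, d$I, d$R, d$K)
}

#' Widely applicable information criterion (log scale)
#'
#' `lppd - p_waic`, where `lppd = sum_obs log mean_s p_s(obs)` and
#' `p_waic = sum_obs var_s log p_s(obs)` (the variance form of the
#' penalty). Larger is better. Accepts either a `rater_fit` or a raw
#' draws-by-observations matrix of log-probabilities.
#'
#' @param x A `rater_fit`, or a numeric matrix of pointwise
#'   log-probabilities (rows = posterior draws, columns = observations).
#' @return Scalar score.
#' @export
waic_score <- function(x) {
  lp <- if (inherits(x, "rater_fit")) x$pointwise else as.matrix(x)
  S <- nrow(lp)
  if (S < 2) stop("WAIC needs at least 2 posterior draws", call. = FALSE)
  m <- apply(lp, 2, max)
  lppd <- sum(m + log(colMeans(exp(sweep(lp, 2, m)))))
  p_waic <- sum(apply(lp, 2, var))
  lppd - p_waic
}

#' Log marginal likelihood of a fitted model
#'
#' Estimates log evidence, \eqn{\log \int p(data \mid \eta) p(\eta)
#' d\eta}, from the retained draws. The default estimator is the harmonic
#' mean of the likelihood over posterior draws (known to be noisy; the
#' estimator is pluggable via `estimator`).
#'
#' @param fit A `rater_fit` object.
#' @param estimator Either `"harmonic"` or a function mapping the vector of
#'   per-draw total log-likelihoods to a scalar log-evidence estimate.
#' @return Scalar estimate.
#' @export
log_marginal_likelihood <- function(fit, estimator = "harmonic") {
  ll <- if (inherits(fit, "rater_fit")) fit$loglik else as.numeric(fit)
  if (!all(is.finite(ll))) stop("degenerate likelihood draws", call. = FALSE)
  if (is.function(estimator)) return(estimator(ll))
  log_ml_harmonic(ll)
}

#' @rdname log_marginal_likelihood
#' @param loglik Numeric vector of per-draw total log-likelihoods.
#' @export
log_ml_harmonic <- function(loglik) {
  # 1 / ML = mean_s exp(-loglik_s), computed through log-sum-exp
  -(logsumexp(-loglik) - log(length(loglik)))
}

#' Criterion table for a set of fitted models
#'
#' Computes AIC, WAIC, BIC and the log marginal likelihood for each fit and
#' appends per-criterion ranks (rank 1 = maximal score; ties get averaged
#' ranks).
#'
#' @param fits A named list of `rater_fit` objects (names default to the
#'   model ids).
#' @param data The common [rating_data()].
#' @param scale `"log"` (default, larger is better) or `"deviance"`
#'   (conventional -2x scale, smaller is better; ranks are unchanged).
#' @return A tibble with columns `model`, `aic`, `waic`, `bic`, `log_ml`,
#'   `n_params`, `n_obs` and `rank_aic`, `rank_waic`, `rank_bic`,
#'   `rank_log_ml`.
#' @export
criterion_scores <- function(fits, data, scale = c("log", "deviance")) {
  scale <- match.arg(scale)
  if (is.null(names(fits))) names(fits) <- vapply(fits, `[[`, "", "model")
  data <- as_rating_data(data, fits[[1]]$dims$K)
  tab <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(
      model = nm,
      aic = aic_score(f, data), waic = waic_score(f),
      bic = bic_score(f, data), log_ml = log_marginal_likelihood(f),
      n_params = n_params_fit(f), n_obs = f$dims$n_obs
    )
  })
  for (cr in c("aic", "waic", "bic", "log_ml")) {
    tab[[paste0("rank_", cr)]] <- rank_scores(tab[[cr]])
  }
  if (scale == "deviance") {
    for (cr in c("aic", "waic", "bic", "log_ml")) tab[[cr]] <- -2 * tab[[cr]]
  }
  tab
}

rank_scores <- function(scores) rank(-scores, ties.method = "average")

#' Rank models on one criterion
#'
#' Rank 1 is assigned to the maximal score ("the optimal model"); tied
#' scores receive the average of the tied ranks.
#'
#' @param scores A criterion table from [criterion_scores()], or any data
#'   frame with a `model` column and the criterion column.
#' @param criterion One of `"aic"`, `"waic"`, `"bic"`, `"log_ml"`.
#' @return A tibble with columns `model`, `score`, `rank`, ordered by rank.
#' @export
rank_models <- function(scores, criterion = c("aic", "waic", "bic", "log_ml")) {
  criterion <- match.arg(criterion)
  if (nrow(scores) < 2) stop("need at least 2 models to rank", call. = FALSE)
  if (!criterion %in% names(scores)) {
    stop("criterion column `", criterion, "` missing", call. = FALSE)
  }
  out <- tibble::tibble(model = scores$model, score = scores[[criterion]],
                        rank = rank_scores(scores[[criterion]]))
  dplyr::arrange(out, .data$rank)
}
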