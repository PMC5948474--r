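# Numerically stable primitives -------------------------------------------

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x < 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log softmax of a cumulative-logit matrix (rows = units, cols = K)
log_softmax_rows <- function(z) {
  m <- apply(z, 1, max)
  z <- z - m
  z - log(rowSums(exp(z)))
}

# Log category probabilities of a graded-response family from a matrix of
# boundary logits `a` (rows = units, cols = K-1, decreasing within a row):
# P_k = sigma(a_{k-1}) - sigma(a_k), with sigma(a_0) = 1, sigma(a_K) = 0.
# Differences are computed in log space so extreme logits stay finite.
log_grm_from_boundaries <- function(a) {
  a <- as.matrix(a)
  Km1 <- ncol(a)
  lp <- matrix(NA_real_, nrow(a), Km1 + 1)
  lp[, 1] <- -log1pexp(a[, 1])
  lp[, Km1 + 1] <- -log1pexp(-a[, Km1])
  if (Km1 >= 2) {
    for (k in 2:Km1) {
      hi <- a[, k - 1]; lo <- a[, k]
      lp[, k] <- lo + log(expm1(pmax(hi - lo, 1e-300))) -
        log1pexp(hi) - log1pexp(lo)
    }
  }
  lp
}

# Cumulative-sum logits for the partial-credit family: z_k = sum_{m<=k} eta_m
# where eta is a J x K matrix of per-step terms.
pcm_logits <- function(eta) {
  t(apply(eta, 1, cumsum))
}

# Probability functions -----------------------------------------------------

#' Category probabilities of the graded response model (GRM)
#'
#' The GRM models the probability of category k as the difference of two
#' boundary curves, \eqn{P_k = P^*_{k-1} - P^*_k}, where
#' \eqn{P^*_k = [1 + \exp(-\alpha(\theta - b_k))]^{-1}} for
#' \eqn{k = 1, \dots, K-1}, \eqn{P^*_0 = 1} and \eqn{P^*_K = 0}.
#'
#' @param theta Ability value(s); scalar or vector.
#' @param alpha Positive discrimination.
#' @param b Strictly increasing difficulty thresholds (length K-1).
#' @return A probability vector of length `K` (or a `length(theta)` x K
#'   matrix for vector `theta`); rows sum to 1.
#' @examples
#' probs_grm(0, alpha = 1, b = c(-1, 0, 1))
#' @export
probs_grm <- function(theta, alpha, b) {
  stopifnot(alpha > 0)
  if (length(b) > 1 && any(diff(b) <= 0)) {
    stop("thresholds `b` must be strictly increasing", call. = FALSE)
  }
  a <- outer(theta, b, function(th, bb) alpha * (th - bb))
  drop_rows(exp(log_grm_from_boundaries(a)), theta)
}

#' Category probabilities of the generalized partial credit model (GPCM)
#'
#' Adjacent-category model: a softmax over the cumulative sums
#' \eqn{\sum_{m \le k} \alpha(\theta - \beta_m)}. The step difficulties may
#' be given directly (`beta_step`, with the first element 0) or in the
#' decomposed form \eqn{\beta_m = \beta + d_m} (`beta` plus thresholds `d`
#' with `d[1] = 0`). With `alpha = 1` the model reduces to the partial
#' credit model (PCM); sharing `d` across items yields the rating scale
#' model (RSM).
#'
#' @inheritParams probs_grm
#' @param beta_step Step difficulties, length K, first element 0.
#' @param beta,d Decomposed form: positional difficulty plus thresholds.
#' @return Probability vector over the K categories (rows sum to 1).
#' @examples
#' probs_gpcm(1, alpha = 2, beta_step = c(0, 0.5))
#' @export
probs_gpcm <- function(theta, alpha, beta_step = NULL, beta = NULL, d = NULL) {
  stopifnot(alpha > 0)
  if (is.null(beta_step)) {
    stopifnot(!is.null(beta), !is.null(d))
    beta_step <- beta + d
  }
  K <- length(beta_step)
  if (K < 2) stop("need K >= 2 categories", call. = FALSE)
  eta <- outer(theta, beta_step, function(th, b) alpha * (th - b))
  drop_rows(exp(log_softmax_rows(pcm_logits(eta))), theta)
}

drop_rows <- function(p, theta) if (length(theta) == 1) drop(p) else p

#' Category probabilities of the many-facet Rasch model (MFRM)
#'
#' A PCM with an additive rater severity: softmax over
#' \eqn{\sum_{m \le k} (\theta - \beta_i - \beta_r - d_m)}.
#'
#' @param theta Ability value(s).
#' @param task,rater 1-based task and rater index.
#' @param params An [mfrm_params()] bundle.
#' @return Probability vector over the K categories.
#' @export
probs_mfrm <- function(theta, task, rater, params) {
  d <- params_dims(params)
  check_index(task, d$I, "task"); check_index(rater, d$R, "rater")
  eta <- outer(theta - params$beta_task[task] - params$beta_rater[rater],
               params$d_cat, `-`)
  drop_rows(exp(log_softmax_rows(pcm_logits(eta))), theta)
}

#' Category probabilities of the GPCM with per-task rater severity
#'
#' Softmax over \eqn{\sum_{m \le k} \alpha_i(\theta - \beta_{im} -
#' \rho_{ir})}: each rater has a separate severity for each task.
#'
#' @inheritParams probs_mfrm
#' @param params A [patz_params()] bundle.
#' @export
probs_patz <- function(theta, task, rater, params) {
  d <- params_dims(params)
  check_index(task, d$I, "task"); check_index(rater, d$R, "rater")
  a <- params$alpha[task]
  eta <- a * outer(theta - params$rho[task, rater], params$beta_step[task, ], `-`)
  drop_rows(exp(log_softmax_rows(pcm_logits(eta))), theta)
}

#' Category probabilities of the GRM with per-rater thresholds
#'
#' Boundary curves \eqn{[1 + \exp(-\alpha_i(\theta - b_i -
#' \epsilon_{rk}))]^{-1}}: each rater has its own ordered category
#' thresholds, so the model expresses rater range restriction (a rater who
#' overuses few categories has widely spaced thresholds around them).
#'
#' @inheritParams probs_mfrm
#' @param params A [ueno_params()] bundle.
#' @export
probs_ueno <- function(theta, task, rater, params) {
  d <- params_dims(params)
  check_index(task, d$I, "task"); check_index(rater, d$R, "rater")
  a <- outer(theta - params$b_task[task], params$eps[rater, ], `-`) *
    params$alpha[task]
  drop_rows(exp(log_grm_from_boundaries(a)), theta)
}

#' Category probabilities of the GRM with rater severity and consistency
#'
#' Boundary curves \eqn{[1 + \exp(-\alpha_i \alpha_r(\theta - b_{ik} -
#' \epsilon_r))]^{-1}}: \eqn{\alpha_r} is the rater's consistency (a rater
#' discrimination) and \eqn{\epsilon_r} the rater's severity.
#'
#' @inheritParams probs_mfrm
#' @param params A [uto_params()] bundle.
#' @export
probs_uto <- function(theta, task, rater, params) {
  d <- params_dims(params)
  check_index(task, d$I, "task"); check_index(rater, d$R, "rater")
  aa <- params$alpha_task[task] * params$alpha_rater[rater]
  a <- outer(theta - params$eps_rater[rater], params$b_cat[task, ], `-`) * aa
  drop_rows(exp(log_grm_from_boundaries(a)), theta)
}

#' HRM stage 1: ideal-rating probabilities
#'
#' The hierarchical rater model first draws a latent ideal rating for each
#' (task, examinee) outcome from a PCM: softmax over
#' \eqn{\sum_{m \le k} (\theta - \beta_i - d_{im})}.
#'
#' @inheritParams probs_mfrm
#' @param params An [hrm_params()] bundle.
#' @export
probs_hrm_ideal <- function(theta, task, params) {
  d <- params_dims(params)
  check_index(task, d$I, "task")
  eta <- outer(theta - params$beta_task[task], params$d_step[task, ], `-`)
  drop_rows(exp(log_softmax_rows(pcm_logits(eta))), theta)
}

#' HRM stage 2: observed-rating probabilities given the ideal rating
#'
#' A Gaussian signal-detection kernel over the categories:
#' \eqn{p(x = k \mid \xi) \propto \exp\{-[k - (\xi + \sigma_r)]^2 /
#' (2\psi_r^2)\}} for \eqn{k = 1, \dots, K}. \eqn{\sigma_r} shifts the
#' rating (severity), \eqn{\psi_r} blurs it (the reciprocal of
#' \eqn{\psi_r^2} is the rater's consistency).
#'
#' @param xi Ideal rating, integer in 1..K.
#' @param rater 1-based rater index.
#' @param params An [hrm_params()] bundle.
#' @export
probs_hrm_rating <- function(xi, rater, params) {
  d <- params_dims(params)
  check_index(rater, d$R, "rater")
  stopifnot(xi >= 1, xi <= params$K, xi == round(xi))
  if (params$psi[rater] <= 0) stop("psi must be positive", call. = FALSE)
  k <- seq_len(params$K)
  z <- -(k - (xi + params$sigma[rater]))^2 / (2 * params$psi[rater]^2)
  exp(z - logsumexp(z))
}

check_index <- function(idx, n, what) {
  if (any(idx < 1 | idx > n)) stop(what, " index out of range", call. = FALSE)
}

# Log-probability arrays ----------------------------------------------------

# J x K matrix of log category probabilities for a (task, rater) pair with a
# vector of abilities; used by the likelihood and quadrature routines.
log_prob_matrix <- function(params, task, rater, theta) {
  switch(params_model(params),
    mfrm = {
      eta <- outer(theta - params$beta_task[task] - params$beta_rater[rater],
                   params$d_cat, `-`)
      log_softmax_rows(pcm_logits(eta))
    },
    patz1999 = {
      eta <- params$alpha[task] *
        outer(theta - params$rho[task, rater], params$beta_step[task, ], `-`)
      log_softmax_rows(pcm_logits(eta))
    },
    ueno2008 = {
      a <- params$alpha[task] *
        outer(theta - params$b_task[task], params$eps[rater, ], `-`)
      log_grm_from_boundaries(a)
    },
    uto2016 = {
      aa <- params$alpha_task[task] * params$alpha_rater[rater]
      a <- aa * outer(theta - params$eps_rater[rater], params$b_cat[task, ], `-`)
      log_grm_from_boundaries(a)
    },
    hrm = {
      # observed-data probabilities, marginal over the latent ideal rating
      K <- params$K
      eta <- outer(theta - params$beta_task[task], params$d_step[task, ], `-`)
      lpcm <- log_softmax_rows(pcm_logits(eta)) # J x K over xi
      k <- seq_len(K)
      z <- -outer(k + params$sigma[rater], k, `-`)^2 / (2 * params$psi[rater]^2)
      # z[xi, x]: log kernel; normalize over x within each xi row
      lsd <- z - apply(z, 1, logsumexp)
      # log sum_xi exp(lpcm[, xi] + lsd[xi, x])
      out <- matrix(NA_real_, length(theta), K)
      for (x in k) {
        m <- lpcm + matrix(lsd[, x], length(theta), K, byrow = TRUE)
        mm <- apply(m, 1, max)
        out[, x] <- mm + log(rowSums(exp(m - mm)))
      }
      out
    }
  )
}

#' Log-likelihood of a model on rating data
#'
#' Sums the log category probability over all non-missing ratings, invoking
#' local independence across examinees, tasks and raters. Missing entries
#' contribute exactly zero. For the HRM the observed-data likelihood
#' marginalizes the latent ideal rating per observation,
#' \eqn{p(x_{ijr} \mid \theta) = \sum_\xi p(\xi \mid \theta) p(x \mid \xi)}.
#'
#' @param params A [rater_params] bundle.
#' @param data A [rating_data()] object (or data frame plus `K`).
#' @param K Category count when `data` is a plain data frame.
#' @param pointwise If `TRUE`, also return the per-observation log
#'   probabilities.
#' @param hrm_conditional For the HRM only: condition on the ideal ratings
#'   `params$xi` instead of marginalizing them (the convention used by the
#'   information criteria, where the ideal ratings are counted as
#'   parameters).
#' @return The scalar log-likelihood, or (with `pointwise = TRUE`) a list
#'   with elements `log_lik` and `pointwise`.
#' @export
log_likelihood <- function(params, data, K = NULL, pointwise = FALSE,
                           hrm_conditional = FALSE) {
  data <- as_rating_data(data, K)
  d <- rating_dims(data)
  pd <- params_dims(params)
  if (d$J != pd$J || d$I != pd$I || d$R != pd$R || d$K != pd$K) {
    stop("parameter and data dimensions do not match", call. = FALSE)
  }
  idx <- obs_index(data)
  lp <- numeric(length(idx$i))
  if (hrm_conditional && params_model(params) == "hrm") {
    for (t in seq_along(idx$i)) {
      pk <- probs_hrm_rating(params$xi[idx$i[t], idx$j[t]], idx$r[t], params)
      lp[t] <- log(pk[idx$x[t]])
    }
  } else {
    for (i in seq_len(d$I)) {
      for (r in seq_len(d$R)) {
        sel <- which(idx$i == i & idx$r == r)
        if (!length(sel)) next
        lpm <- log_prob_matrix(params, i, r, params$theta[idx$j[sel]])
        lp[sel] <- lpm[cbind(seq_along(sel), idx$x[sel])]
      }
    }
  }
  if (pointwise) list(log_lik = sum(lp), pointwise = lp) else sum(lp)
}
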