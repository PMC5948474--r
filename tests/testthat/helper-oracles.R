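# Naive, literal transcriptions of the model equations, kept deliberately
# independent of the package's stabilized implementations. Used as oracles.

sigmoid <- function(x) 1 / (1 + exp(-x))

naive_grm <- function(theta, alpha, b) {
  K <- length(b) + 1
  pstar <- c(1, sigmoid(alpha * (theta - b)), 0)
  pstar[1:K] - pstar[2:(K + 1)]
}

# softmax is invariant to a common offset; subtracting the maximum keeps the
# naive transcription finite for extreme random draws
softmax <- function(z) { z <- z - max(z); exp(z) / sum(exp(z)) }

naive_gpcm <- function(theta, alpha, beta_step) {
  softmax(cumsum(alpha * (theta - beta_step)))
}

naive_mfrm <- function(theta, beta_i, beta_r, d) {
  softmax(cumsum(theta - beta_i - beta_r - d))
}

naive_patz <- function(theta, alpha_i, beta_im, rho_ir) {
  softmax(cumsum(alpha_i * (theta - beta_im - rho_ir)))
}

naive_ueno <- function(theta, alpha_i, b_i, eps_r) {
  K <- length(eps_r) + 1
  pstar <- c(1, sigmoid(alpha_i * (theta - b_i - eps_r)), 0)
  pstar[1:K] - pstar[2:(K + 1)]
}

naive_uto <- function(theta, alpha_i, alpha_r, b_ik, eps_r) {
  K <- length(b_ik) + 1
  pstar <- c(1, sigmoid(alpha_i * alpha_r * (theta - b_ik - eps_r)), 0)
  pstar[1:K] - pstar[2:(K + 1)]
}

naive_hrm_ideal <- function(theta, beta_i, d_i) {
  softmax(cumsum(theta - beta_i - d_i))
}

naive_hrm_rating <- function(xi, sigma_r, psi_r, K) {
  w <- exp(-((1:K) - (xi + sigma_r))^2 / (2 * psi_r^2))
  w / sum(w)
}

# expected rating under a probability vector
expected_rating <- function(p) sum(seq_along(p) * p)

# random parameter draws on realistic scales for property tests
rand_d <- function(K) {
  d <- c(0, rnorm(K - 1))
  d[-1] <- d[-1] - mean(d[-1])
  d
}
rand_ordered <- function(K) sort(rnorm(K - 1, 0, 1.2))

# a small complete data set with known truth, shared across fit tests
tiny_mfrm_setup <- function(J = 12, I = 2, R = 3, K = 3, seed = 99) {
  truth <- draw_true_params("mfrm", J = J, I = I, R = R, K = K, seed = seed)
  list(truth = truth, data = simulate_ratings(truth, seed = seed + 1))
}
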