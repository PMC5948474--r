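test_that("GRM probabilities match worked values and boundary semantics", {
  expect_equal(probs_grm(0, 1, c(-1, 0, 1)),
               c(0.26894, 0.23106, 0.23106, 0.26894), tolerance = 1e-4)
  # at theta = b_k the k-th boundary curve is exactly 0.5
  b <- c(-0.7, 0.2, 1.4)
  for (k in seq_along(b)) {
    p <- probs_grm(b[k], 1.3, b)
    expect_equal(sum(p[(k + 1):4]), 0.5, tolerance = 1e-12)
  }
  # alpha -> 0 flattens every boundary curve to 0.5
  p <- probs_grm(0.3, 1e-9, c(-1, 0, 1))
  expect_equal(p, c(0.5, 0, 0, 0.5), tolerance = 1e-6)
  expect_error(probs_grm(0, 1, c(1, 0)), "increasing")
  expect_error(probs_grm(0, -1, c(0, 1)))
})

test_that("GPCM probabilities match worked values and decomposition identity", {
  expect_equal(probs_gpcm(0, 1, beta_step = c(0, 0)), c(0.5, 0.5))
  expect_equal(probs_gpcm(1, 2, beta_step = c(0, 0.5)),
               c(0.26894, 0.73106), tolerance = 1e-4)
  # step form beta_ik = beta + d_ik equals the decomposed form
  d <- c(0, -0.4, 0.1, 0.3)
  expect_equal(probs_gpcm(0.7, 1.4, beta_step = 0.9 + d),
               probs_gpcm(0.7, 1.4, beta = 0.9, d = d), tolerance = 1e-12)
  expect_error(probs_gpcm(0, 1, beta_step = 0), "K >= 2")
})

test_that("MFRM probabilities match the worked example and are translation invariant", {
  p <- mfrm_params(beta_task = 0, beta_rater = c(0, 0.5),
                   d_cat = c(0, -0.3, 0.3), theta = 1)
  expect_equal(probs_mfrm(1, 1, 2, p),
               c(0.16824, 0.37443, 0.45733), tolerance = 1e-4)
  # depends on (theta, beta_i, beta_r) only through theta - beta_i - beta_r
  for (delta in c(-1.3, 0.4, 2)) {
    p2 <- mfrm_params(beta_task = 0, beta_rater = c(0, 0.5 + delta),
                      d_cat = c(0, -0.3, 0.3), theta = 1)
    expect_equal(probs_mfrm(1 + delta, 1, 2, p2), probs_mfrm(1, 1, 2, p),
                 tolerance = 1e-12)
  }
  expect_error(probs_mfrm(0, 3, 1, p), "out of range")
})

test_that("Patz1999 matches worked values and reduces to the MFRM", {
  p <- patz_params(alpha = 2, beta_step = matrix(c(0, 0.5), 1),
                   rho = matrix(0, 1, 1), theta = 1)
  expect_equal(probs_patz(1, 1, 1, p), c(0.26894, 0.73106), tolerance = 1e-4)
  # all exponents equal -> uniform
  pu <- patz_params(alpha = 1.7, beta_step = matrix(0, 1, 4),
                    rho = matrix(0, 1, 2), theta = 0)
  expect_equal(probs_patz(0, 1, 1, pu), rep(0.25, 4), tolerance = 1e-12)
  # alpha_i = 1, rho_ir = beta_r, beta_im = beta_i + d_m recovers the MFRM
  d <- c(0, -0.3, 0.3); br <- c(0, 0.6, -0.2)
  mf <- mfrm_params(0, br, d, theta = 0.8)
  # beta_im = d_m (first step 0) and rho_ir = beta_r
  pz2 <- patz_params(alpha = 1, beta_step = matrix(d, 1),
                     rho = matrix(br, 1), theta = 0.8)
  for (r in 1:3) {
    expect_equal(probs_patz(0.8, 1, r, pz2), probs_mfrm(0.8, 1, r, mf),
                 tolerance = 1e-12)
  }
  expect_error(patz_params(alpha = -1, beta_step = matrix(0, 1, 2),
                           rho = matrix(0, 1, 1), theta = 0), "positive")
})

test_that("Ueno2008 matches the worked example; wider category widens probability", {
  p <- ueno_params(alpha = 1, b_task = 0,
                   eps = matrix(c(-1, 0, 1, 2), 1), theta = 0)
  expect_equal(probs_ueno(0, 1, 1, p),
               c(0.26894, 0.23106, 0.23106, 0.14974, 0.11920), tolerance = 1e-4)
  # widening the gap eps_{k+1} - eps_k raises category-k probability
  p2 <- ueno_params(alpha = 1, b_task = 0,
                    eps = matrix(c(-1, 0, 1.8, 2.6), 1), theta = 0)
  expect_gt(probs_ueno(0, 1, 1, p2)[3], probs_ueno(0, 1, 1, p)[3])
  # theta -> +Inf concentrates on category K
  expect_equal(probs_ueno(40, 1, 1, p)[5], 1, tolerance = 1e-6)
  expect_error(ueno_params(1, 0, matrix(c(-1, -2, 0, 1), 1), 0), "increasing")
})

test_that("Uto2016 consistency parameter sharpens/flattens the categories", {
  p1 <- uto_params(alpha_task = 1, alpha_rater = 1,
                   b_cat = matrix(c(-1, 0, 1), 1), eps_rater = 0, theta = 0)
  expect_equal(probs_uto(0, 1, 1, p1),
               c(0.26894, 0.23106, 0.23106, 0.26894), tolerance = 1e-4)
  p2 <- uto_params(alpha_task = 1, alpha_rater = c(1, 2),
                   b_cat = matrix(c(-1, 0, 1), 1), eps_rater = c(0, 0),
                   theta = 0)
  expect_equal(probs_uto(0, 1, 2, p2),
               c(0.11920, 0.38080, 0.38080, 0.11920), tolerance = 1e-4)
  # alpha_r -> 0 flattens toward the (0.5, 0, ..., 0, 0.5) limit
  p3 <- uto_params(alpha_task = 1, alpha_rater = c(1, 1e-9),
                   b_cat = matrix(c(-1, 0, 1), 1), eps_rater = c(0, 0),
                   theta = 0)
  expect_equal(probs_uto(0, 1, 2, p3), c(0.5, 0, 0, 0.5), tolerance = 1e-6)
  expect_error(uto_params(-1, 1, matrix(c(0, 1), 1), 0, 0), "positive")
})

test_that("HRM stages match worked values and the MFRM reduction", {
  # a rater severity of 0.5 folded into the task difficulty reproduces the
  # MFRM worked example
  hp <- hrm_params(beta_task = 0.5, d_step = matrix(c(0, -0.3, 0.3), 1),
                   xi = matrix(2, 1, 1), sigma = 0, psi = 0.5, theta = 1)
  # stage 1 equals the MFRM with zero rater severity
  mf <- mfrm_params(0.5, 0, c(0, -0.3, 0.3), theta = 1)
  expect_equal(probs_hrm_ideal(1, 1, hp), probs_mfrm(1, 1, 1, mf),
               tolerance = 1e-12)
  expect_equal(probs_hrm_ideal(1, 1, hp),
               c(0.16824, 0.37443, 0.45733), tolerance = 1e-4)
  # stage 2 worked example
  hp5 <- hrm_params(beta_task = 0, d_step = matrix(c(0, rep(0, 4)), 1),
                    xi = matrix(3, 1, 1), sigma = 0, psi = 0.5, theta = 0)
  expect_equal(probs_hrm_rating(3, 1, hp5),
               c(0.00026, 0.10645, 0.78657, 0.10645, 0.00026), tolerance = 2e-5)
  # symmetric about xi at the scale midpoint when sigma = 0
  expect_equal(probs_hrm_rating(3, 1, hp5), rev(probs_hrm_rating(3, 1, hp5)))
  # psi -> Inf flattens to uniform
  hpu <- hrm_params(0, matrix(rep(0, 5), 1), matrix(3, 1, 1), 0, 1e6, 0)
  expect_equal(probs_hrm_rating(3, 1, hpu), rep(0.2, 5), tolerance = 1e-6)
  expect_error(hrm_params(0, matrix(c(0, 0), 1), matrix(1, 1, 1), 0, -1, 0),
               "positive")
})

test_that("probability vectors are normalized and match naive oracles on random draws", {
  set.seed(401)
  for (rep in 1:200) {
    K <- sample(2:6, 1)
    th <- rnorm(1, 0, 2)
    a <- exp(rnorm(1, 0.1, sqrt(0.4)))
    bo <- rand_ordered(K)
    d <- rand_d(K)
    p1 <- probs_grm(th, a, bo)
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    expect_equal(p1, naive_grm(th, a, bo), tolerance = 1e-10)
    bs <- c(0, rnorm(K - 1))
    p2 <- probs_gpcm(th, a, beta_step = bs)
    expect_equal(sum(p2), 1, tolerance = 1e-12)
    expect_equal(p2, naive_gpcm(th, a, bs), tolerance = 1e-10)
  }
})

test_that("every model's severity parameter shifts the expected rating monotonically", {
  set.seed(402)
  K <- 5; th <- 0.3
  d <- rand_d(K)
  sev <- c(-0.5, 0, 0.5, 1)
  # MFRM: higher beta_r -> lower expected rating
  er <- vapply(sev, function(s) {
    p <- mfrm_params(0, c(0, s), d, th)
    expected_rating(probs_mfrm(th, 1, 2, p))
  }, numeric(1))
  expect_true(all(diff(er) < 0))
  # Patz1999: higher rho -> lower expected rating
  er <- vapply(sev, function(s) {
    p <- patz_params(1.2, matrix(c(0, rnorm(K - 1, 0, 0)), 1),
                     matrix(c(0, s), 1), th)
    expected_rating(probs_patz(th, 1, 2, p))
  }, numeric(1))
  expect_true(all(diff(er) < 0))
  # Ueno2008: shifting all thresholds up (a severer rater) lowers it
  e0 <- c(-1, -0.3, 0.4, 1.1)
  er <- vapply(sev, function(s) {
    p <- ueno_params(1, 0, rbind(e0, e0 + s), th)
    expected_rating(probs_ueno(th, 1, 2, p))
  }, numeric(1))
  expect_true(all(diff(er) < 0))
  # Uto2016: higher eps_r -> lower expected rating
  er <- vapply(sev, function(s) {
    p <- uto_params(1, c(1, 1), matrix(sort(rnorm(K - 1)), 1), c(0, s), th)
    expected_rating(probs_uto(th, 1, 2, p))
  }, numeric(1))
  expect_true(all(diff(er) < 0))
  # HRM: sigma_r shifts the rating center xi + sigma_r, raising the
  # expected observed rating (severity enters with the opposite sign here)
  er <- vapply(sev, function(s) {
    p <- hrm_params(0, matrix(rep(0, K), 1), matrix(3, 1, 1), s, 0.7, th)
    expected_rating(probs_hrm_rating(3, 1, p))
  }, numeric(1))
  expect_true(all(diff(er) > 0))
})

test_that("log_likelihood sums log-probabilities over non-missing entries only", {
  p <- mfrm_params(beta_task = c(0.2, -0.1), beta_rater = c(0, 0.4),
                   d_cat = c(0, -0.5, 0.5), theta = c(0.3, -0.8))
  df <- tibble::tibble(
    examinee = c(1, 2, 1), task = c(1, 1, 2), rater = c(1, 2, 2),
    rating = c(3, 1, 2)
  )
  data <- rating_data(df, K = 3, examinee_ids = 1:2, task_ids = 1:2,
                      rater_ids = 1:2)
  manual <- log(probs_mfrm(0.3, 1, 1, p)[3]) +
    log(probs_mfrm(-0.8, 1, 2, p)[1]) +
    log(probs_mfrm(0.3, 2, 2, p)[2])
  expect_equal(log_likelihood(p, data), manual, tolerance = 1e-12)
  pw <- log_likelihood(p, data, pointwise = TRUE)
  expect_length(pw$pointwise, 3)
  expect_equal(sum(pw$pointwise), pw$log_lik)
  # dimension mismatch errors
  p3 <- mfrm_params(0, c(0, 0.4), c(0, -0.5, 0.5), theta = c(0.3, -0.8))
  expect_error(log_likelihood(p3, data), "dimensions")
})

test_that("HRM observed-data likelihood marginalizes the ideal rating", {
  hp <- hrm_params(beta_task = 0.2, d_step = matrix(c(0, -0.4, 0.4), 1),
                   xi = matrix(1, 1, 1), sigma = 0.3, psi = 0.8, theta = 0.5)
  df <- tibble::tibble(examinee = 1, task = 1, rater = 1, rating = 2)
  data <- rating_data(df, K = 3)
  pk <- probs_hrm_ideal(0.5, 1, hp)
  marg <- sum(vapply(1:3, function(k) {
    hp2 <- hp; hp2$xi[1, 1] <- k
    pk[k] * probs_hrm_rating(k, 1, hp2)[2]
  }, numeric(1)))
  expect_equal(log_likelihood(hp, data), log(marg), tolerance = 1e-10)
})
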