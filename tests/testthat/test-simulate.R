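test_that("true-parameter draws respect constraints and seeds", {
  for (m in c("mfrm", "patz1999", "ueno2008", "uto2016", "hrm")) {
    p1 <- draw_true_params(m, J = 8, I = 3, R = 4, K = 5, seed = 31)
    p2 <- draw_true_params(m, J = 8, I = 3, R = 4, K = 5, seed = 31)
    expect_equal(p1, p2) # identical seed, identical draw
  }
  # Ueno thresholds ordered with the first-rater fix applied
  pu <- draw_true_params("ueno2008", J = 5, I = 2, R = 50, K = 5, seed = 5)
  expect_true(all(apply(pu$eps, 1, function(e) all(diff(e) > 0))))
  expect_equal(pu$eps[1, 1], -1.0)
})

test_that("generating distributions have the stated moments", {
  set.seed(61)
  # many raters in one draw to estimate moments cheaply
  p <- draw_true_params("ueno2008", J = 2000, I = 400, R = 5000, K = 5)
  expect_lt(abs(mean(p$theta)), 3 / sqrt(2000))
  # log-normal alpha: median about exp(0.1)
  expect_equal(median(p$alpha), exp(0.1), tolerance = 0.05)
  # each ordered-threshold component near its prescribed mean
  mu <- c(-1.50, -0.75, 0.75, 1.50)
  est <- colMeans(p$eps[-1, ])
  expect_true(all(abs(est - mu) < 3 * sqrt(0.25) / sqrt(4999) + 0.05))
})

test_that("simulated rating frequencies match the model probabilities", {
  p <- mfrm_params(beta_task = 0.3, beta_rater = c(0, -0.5),
                   d_cat = c(0, -0.6, 0.6), theta = rep(0.2, 4000))
  data <- simulate_ratings(p, seed = 8)
  x <- as_rating_array(data)
  pk <- probs_mfrm(0.2, 1, 2, p)
  freq <- tabulate(x[1, , 2], 3) / 4000
  se <- sqrt(pk * (1 - pk) / 4000)
  expect_true(all(abs(freq - pk) < 3 * se + 1e-3))
  # determinism
  data2 <- simulate_ratings(p, seed = 8)
  expect_equal(as_rating_array(data2), x)
})

test_that("bias transforms alter the prescribed share of entries and nothing else", {
  truth <- draw_true_params("mfrm", J = 100, I = 5, R = 5, K = 5, seed = 21)
  data <- simulate_ratings(truth, seed = 22)
  x0 <- as_rating_array(data)
  for (rule in c("A", "B", "C", "D", "E")) {
    x1 <- as_rating_array(apply_transform(data, rule, seed = 23))
    changed <- sum(x1 != x0)
    expect_true(all(x1 >= 1 & x1 <= 5)) # never leaves the scale
    units <- switch(rule, A = 5, B = 5, C = 5, D = 5, E = 25)
    per_unit <- switch(rule, A = 350, B = 350, C = 350, D = 350, E = 70)
    max_changed <- round(0.6 * units) * per_unit
    expect_lte(changed, max_changed)
    # at least the unselected 40% of units are untouched, so strictly
    # fewer than all entries change, and some do
    expect_gt(changed, 0)
  }
  # rule A raises within-outcome rating variance on average
  xa <- as_rating_array(apply_transform(data, "A", seed = 24))
  v0 <- mean(apply(x0, c(1, 2), var))
  va <- mean(apply(xa, c(1, 2), var))
  expect_gt(va, v0)
  # rule F composes all five rules; still within scale, same seed reproducible
  xf1 <- as_rating_array(apply_transform(data, "F", seed = 25))
  xf2 <- as_rating_array(apply_transform(data, "F", seed = 25))
  expect_equal(xf1, xf2)
  expect_true(all(xf1 >= 1 & xf1 <= 5))
  expect_error(apply_transform(judge_pair(data, seed = 1), "A"), "complete")
})

test_that("rule A changes about 70% of entries for 60% of raters", {
  truth <- draw_true_params("mfrm", J = 100, I = 5, R = 5, K = 5, seed = 41)
  data <- simulate_ratings(truth, seed = 42)
  x0 <- as_rating_array(data)
  x1 <- as_rating_array(apply_transform(data, "A", seed = 43))
  per_rater <- vapply(1:5, function(r) sum(x1[, , r] != x0[, , r]), integer(1))
  # 3 of 5 raters selected; each had 350 of 500 entries redrawn uniformly,
  # of which about 1/K land on the original category by chance
  expect_equal(sum(per_rater > 0), 3)
  sel <- per_rater[per_rater > 0]
  expect_true(all(sel >= 350 * 0.7 & sel <= 350))
})

test_that("judge-pair reduction keeps exactly two balanced raters per outcome", {
  truth <- draw_true_params("mfrm", J = 30, I = 5, R = 5, K = 5, seed = 51)
  data <- simulate_ratings(truth, seed = 52)
  red <- judge_pair(data, seed = 53)
  expect_equal(rating_dims(red)$n_obs, 2 * 5 * 30)
  x <- as_rating_array(red)
  # every (task, examinee) slice has exactly 2 non-missing entries
  expect_true(all(apply(x != -1L, c(1, 2), sum) == 2))
  # retained values agree with the source data
  x0 <- as_rating_array(data)
  expect_true(all(x[x != -1L] == x0[x != -1L]))
  # per-task balance: each rater retained 2J/R times, within 1
  counts <- apply(x != -1L, c(1, 3), sum)
  expect_true(all(abs(counts - 2 * 30 / 5) <= 1))
  one_rater <- rating_data(tibble::tibble(examinee = 1:3, task = 1, rater = 1,
                                          rating = 2), K = 5)
  expect_error(judge_pair(one_rater), "2 raters")
})
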