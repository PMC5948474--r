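# Generating distributions used both for truth simulation and as default
# priors: log alpha_i ~ N(0.1, var 0.4); log alpha_r, log psi_r ~ N(0, var
# 0.5); all location parameters and abilities ~ N(0, 1); ordered threshold
# blocks (b_ik, eps_rk) ~ multivariate normal with mean mu_ord and covariance
# var_ord on the diagonal, cov_ord off it, then sorted ascending.
prior_defaults <- function(K) {
  list(
    sd_theta = 1, sd_loc = 1,
    mu_logalpha = 0.1, sd_logalpha = sqrt(0.4),
    mu_logpsi = 0, sd_logpsi = sqrt(0.5),
    mu_ord = ordered_means(K), var_ord = 0.25, cov_ord = 0.16
  )
}

# Published means for K = 5; symmetric equal spacing on [-1.5, 1.5] otherwise.
ordered_means <- function(K) {
  if (K == 5) c(-1.50, -0.75, 0.75, 1.50) else seq(-1.5, 1.5, length.out = K - 1)
}

#' Default prior specification for a model
#'
#' Returns the per-block prior descriptors used by [fit_rater_model()]; they
#' coincide with the generating distributions of [draw_true_params()], the
#' only internally consistent default for expected-a-posteriori estimation.
#' The specification round-trips to YAML via [write_prior_yaml()].
#'
#' @param model Model id.
#' @param K Number of rating categories.
#' @return A named list of class `"prior_spec"`.
#' @export
prior_spec <- function(model, K = 5) {
  structure(c(list(model = match_model(model), K = as.integer(K)),
              prior_defaults(K)),
            class = "prior_spec")
}

#' @rdname prior_spec
#' @param prior A `prior_spec` object.
#' @param path File path for the YAML round trip.
#' @export
write_prior_yaml <- function(prior, path) {
  yaml::write_yaml(unclass(prior), path)
  invisible(path)
}

#' @rdname prior_spec
#' @export
read_prior_yaml <- function(path) {
  o <- yaml::read_yaml(path)
  o$K <- as.integer(o$K)
  structure(o, class = "prior_spec")
}

draw_ordered_block <- function(n, K, pr) {
  m <- K - 1
  Sig <- matrix(pr$cov_ord, m, m); diag(Sig) <- pr$var_ord
  L <- chol(Sig)
  z <- matrix(rnorm(n * m), n, m) %*% L +
    matrix(pr$mu_ord, n, m, byrow = TRUE)
  t(apply(z, 1, sort))
}

#' Draw true model parameters from the generating distributions
#'
#' Samples a complete parameter bundle for one model:
#' \eqn{\log \alpha_i \sim N(0.1, 0.4)}; \eqn{\log \alpha_r, \log \psi_r \sim
#' N(0, 0.5)} (second argument a variance);
#' location parameters (\eqn{\beta_i, \beta_r, \beta_{ik}, \epsilon_r,
#' \rho_{ir}, d_{ik}, d_k, b_i, \sigma_r}) and abilities \eqn{\theta_j} from
#' N(0, 1); ordered threshold blocks (\eqn{b_{ik}, \epsilon_{rk}}) from a
#' multivariate normal with mean (-1.5, -0.75, 0.75, 1.5) and covariance
#' 0.25 (diagonal) / 0.16 (off-diagonal), sorted ascending. All
#' identifiability fixes are applied after drawing (fixed entries set,
#' sum-to-zero blocks recentred). For the HRM the latent ideal ratings `xi`
#' are drawn from the stage-1 PCM.
#'
#' @param model Model id.
#' @param J,I,R,K Design dimensions.
#' @param seed Optional integer seed.
#' @return A [rater_params] bundle.
#' @export
draw_true_params <- function(model, J, I, R, K = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- match_model(model)
  pr <- prior_defaults(K)
  theta <- rnorm(J)
  switch(model,
    mfrm = {
      d <- c(0, rnorm(K - 1))
      d[-1] <- d[-1] - mean(d[-1])
      mfrm_params(rnorm(I), c(0, rnorm(R - 1)), d, theta)
    },
    patz1999 = {
      beta <- cbind(0, matrix(rnorm(I * (K - 1)), I, K - 1))
      rho <- cbind(0, matrix(rnorm(I * (R - 1)), I, R - 1))
      patz_params(exp(rnorm(I, pr$mu_logalpha, pr$sd_logalpha)), beta, rho, theta)
    },
    ueno2008 = {
      eps <- draw_ordered_block(R, K, pr)
      eps[1, ] <- fix_first_threshold(eps[1, ])
      ueno_params(exp(rnorm(I, pr$mu_logalpha, pr$sd_logalpha)), rnorm(I),
                  eps, theta)
    },
    uto2016 = {
      ar <- exp(rnorm(R, 0, sqrt(0.5))); ar[1] <- 1
      er <- rnorm(R); er[1] <- 0
      uto_params(exp(rnorm(I, pr$mu_logalpha, pr$sd_logalpha)), ar,
                 draw_ordered_block(I, K, pr), er, theta)
    },
    hrm = {
      d <- cbind(0, matrix(rnorm(I * (K - 1)), I, K - 1))
      d[, -1] <- d[, -1, drop = FALSE] -
        rowMeans(d[, -1, drop = FALSE])
      beta <- rnorm(I)
      sigma <- rnorm(R)
      psi <- exp(rnorm(R, pr$mu_logpsi, pr$sd_logpsi))
      xi <- matrix(NA_integer_, I, J)
      tmp <- hrm_params(beta, d, matrix(1L, I, J), sigma, psi, theta)
      for (i in seq_len(I)) {
        p <- probs_hrm_ideal(theta, i, tmp)
        xi[i, ] <- sample_rows(p)
      }
      hrm_params(beta, d, xi, sigma, psi, theta)
    }
  )
}

# set the first rater's first threshold to -1.0 keeping strict order
fix_first_threshold <- function(e) {
  e[1] <- -1.0
  for (k in seq_along(e)[-1]) if (e[k] <= e[k - 1]) e[k] <- e[k - 1] + 0.25
  e
}

sample_rows <- function(p) {
  p <- if (is.matrix(p)) p else matrix(p, 1)
  u <- runif(nrow(p))
  cs <- t(apply(p, 1, cumsum))
  as.integer(rowSums(u > cs) + 1L)
}

#' Simulate complete rating data from a model
#'
#' Each rating \eqn{x_{ijr}} is drawn independently from the model's category
#' distribution at the supplied parameters; for the HRM a fresh ideal rating
#' is drawn from the stage-1 PCM and the observed rating from the
#' signal-detection stage.
#'
#' @param params A [rater_params] bundle (true parameters).
#' @param seed Optional integer seed.
#' @return A complete [rating_data()] tensor (no missing entries) with
#'   integer ids `1..J`, `1..I`, `1..R`.
#' @export
simulate_ratings <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- params_dims(params)
  m <- params_model(params)
  x <- array(-1L, c(d$I, d$J, d$R))
  if (m == "hrm") {
    for (i in seq_len(d$I)) {
      xi <- sample_rows(probs_hrm_ideal(params$theta, i, params))
      for (r in seq_len(d$R)) {
        pk <- t(vapply(xi, function(k) probs_hrm_rating(k, r, params),
                       numeric(d$K)))
        x[i, , r] <- sample_rows(pk)
      }
    }
  } else {
    pf <- switch(m, mfrm = probs_mfrm, patz1999 = probs_patz,
                 ueno2008 = probs_ueno, uto2016 = probs_uto)
    for (i in seq_len(d$I)) {
      for (r in seq_len(d$R)) {
        p <- pf(params$theta, i, r, params)
        x[i, , r] <- sample_rows(p)
      }
    }
  }
  array_to_rating_data(x, d$K)
}

#' Inject rater/task bias patterns into rating data
#'
#' Applies one of six transformation rules that emulate assessment settings
#' in which some raters or tasks carry a systematic characteristic. Each rule
#' selects a random 60% of the relevant units (raters, tasks, or
#' task-by-rater cells) and alters a random 70% of each selected unit's
#' ratings:
#'
#' * `"A"` low-consistency raters: selected raters' chosen ratings replaced
#'   by uniform draws from 1..K.
#' * `"B"` low-discrimination tasks: as A, but selecting tasks.
#' * `"C"` range-restricted raters: two categories k' > k'' are drawn once;
#'   chosen ratings collapse to k' when above the rater's mean rating,
#'   else to k''.
#' * `"D"` per-task category-difficulty shifts: as C, but selecting tasks.
#' * `"E"` task-dependent rater severity: an offset k''' in
#'   {-(K-1)..-1, 1..K-1} is drawn once; selected (task, rater) cells'
#'   chosen ratings are shifted by it and clipped to 1..K.
#' * `"F"` all of the above, applied in the order A, B, C, D, E with
#'   independent unit selections.
#'
#' Unit means for rules C/D are taken over the unit's ratings before
#' transformation. Counts are rounded: `round(0.6 * units)` units,
#' `round(0.7 * entries)` entries per unit.
#'
#' @param data A [rating_data()] object with no missing entries.
#' @param rule One of `"A"`..`"F"`.
#' @param fraction_units,fraction_ratings Selection fractions (defaults 0.6
#'   and 0.7).
#' @param seed Optional integer seed.
#' @return The transformed [rating_data()] object.
#' @export
apply_transform <- function(data, rule, fraction_units = 0.6,
                            fraction_ratings = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rule <- match.arg(toupper(rule), LETTERS[1:6])
  stopifnot(fraction_units > 0, fraction_units <= 1,
            fraction_ratings > 0, fraction_ratings <= 1)
  data <- as_rating_data(data)
  d <- rating_dims(data)
  if (d$n_obs != d$I * d$J * d$R) {
    stop("bias transforms require complete data (no missing entries)",
         call. = FALSE)
  }
  if (rule %in% c("C", "D") && d$K < 3) {
    warning("rules C/D are degenerate for K < 3")
  }
  x <- as_rating_array(data)
  x <- transform_array(x, rule, d$K, fraction_units, fraction_ratings)
  array_to_rating_data(x, d$K, attr(data, "examinee_ids"),
                       attr(data, "task_ids"), attr(data, "rater_ids"))
}

transform_array <- function(x, rule, K, fu, fr) {
  dm <- dim(x)
  pick_units <- function(n) sample.int(n, max(1, round(fu * n)))
  pick_entries <- function(n) sample.int(n, round(fr * n))
  unit_cells <- function(margin, u) {
    # matrix of array indices of the unit's cells
    switch(margin,
      rater = as.matrix(expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]), r = u)),
      task = as.matrix(expand.grid(i = u, j = seq_len(dm[2]), r = seq_len(dm[3])))
    )
  }
  randomize <- function(x, margin) {
    n_units <- if (margin == "rater") dm[3] else dm[1]
    for (u in pick_units(n_units)) {
      cells <- unit_cells(margin, u)
      sel <- cells[pick_entries(nrow(cells)), , drop = FALSE]
      x[sel] <- sample.int(K, nrow(sel), replace = TRUE)
    }
    x
  }
  collapse <- function(x, margin) {
    ks <- sort(sample.int(K, 2)) # k'' < k'
    n_units <- if (margin == "rater") dm[3] else dm[1]
    for (u in pick_units(n_units)) {
      cells <- unit_cells(margin, u)
      avg <- mean(x[cells])
      sel <- cells[pick_entries(nrow(cells)), , drop = FALSE]
      x[sel] <- ifelse(x[sel] > avg, ks[2], ks[1])
    }
    x
  }
  shift <- function(x) {
    off <- sample(c(-(K - 1):-1, 1:(K - 1)), 1)
    cells_ir <- as.matrix(expand.grid(i = seq_len(dm[1]), r = seq_len(dm[3])))
    sel_u <- sample.int(nrow(cells_ir), max(1, round(fu * nrow(cells_ir))))
    for (u in sel_u) {
      cells <- cbind(i = cells_ir[u, 1], j = seq_len(dm[2]), r = cells_ir[u, 2])
      sel <- cells[pick_entries(nrow(cells)), , drop = FALSE]
      x[sel] <- pmin(pmax(x[sel] + off, 1L), K)
    }
    x
  }
  switch(rule,
    A = randomize(x, "rater"),
    B = randomize(x, "task"),
    C = collapse(x, "rater"),
    D = collapse(x, "task"),
    E = shift(x),
    F = {
      for (rl in c("A", "B", "C", "D", "E")) {
        x <- transform_array(x, rl, K, fu, fr)
      }
      x
    }
  )
}

#' Reduce complete data to a judge-pair design
#'
#' Keeps exactly two raters per (task, examinee) outcome, setting all other
#' ratings to missing. The assignment is balanced within each task: every
#' rater's retained count differs by at most one, and no outcome gets the
#' same rater twice.
#'
#' @param data A [rating_data()] object (complete).
#' @param seed Optional integer seed.
#' @return A [rating_data()] object with `2 * I * J` non-missing ratings.
#' @export
judge_pair <- function(data, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data <- as_rating_data(data)
  d <- rating_dims(data)
  if (d$R < 2) stop("judge-pair design needs at least 2 raters", call. = FALSE)
  x <- as_rating_array(data)
  out <- array(-1L, dim(x))
  for (i in seq_len(d$I)) {
    pairs <- balanced_pairs(d$J, d$R)
    for (j in seq_len(d$J)) {
      out[i, j, pairs[j, ]] <- x[i, j, pairs[j, ]]
    }
  }
  array_to_rating_data(out, d$K, attr(data, "examinee_ids"),
                       attr(data, "task_ids"), attr(data, "rater_ids"))
}

# J x 2 matrix of distinct rater indices; each rater used either
# floor(2J/R) or ceiling(2J/R) times
balanced_pairs <- function(J, R) {
  pool <- sample(rep(sample.int(R), length.out = 2 * J))
  m <- matrix(pool, J, 2)
  for (j in seq_len(J)) {
    tries <- 0
    while (m[j, 1] == m[j, 2] && tries < 100) {
      # swap the duplicate with a random slot elsewhere
      jj <- sample.int(J, 1)
      if (jj != j && m[jj, 1] != m[j, 1] && m[jj, 2] != m[j, 1]) {
        tmp <- m[jj, 1]; m[jj, 1] <- m[j, 2]; m[j, 2] <- tmp
      }
      tries <- tries + 1
    }
    if (m[j, 1] == m[j, 2]) { # R = 2 edge case fallback
      m[j, ] <- sample.int(R, 2)
    }
  }
  m
}

#' Write a small deterministic demo data set
#'
#' Generates a complete report-scale rating study (J = 30 examinees, I = 5
#' tasks, R = 5 raters, K = 5 categories) from the MFRM and writes
#' `ratings.csv` (long format, see [write_ratings()]) plus `truth.json`
#' (the generating parameters, see [write_params_json()]) — a ready-made
#' fixture for demos and pipelines. Identical seeds produce byte-identical
#' files.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed (default 1).
#' @return Named character vector with the two file paths, invisibly.
#' @export
write_demo_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- draw_true_params("mfrm", J = 30, I = 5, R = 5, K = 5, seed = seed)
  data <- simulate_ratings(truth, seed = seed + 1)
  paths <- c(ratings = file.path(dir, "ratings.csv"),
             truth = file.path(dir, "truth.json"))
  write_ratings(data, paths[["ratings"]])
  write_params_json(truth, paths[["truth"]])
  invisible(paths)
}
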