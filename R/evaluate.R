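#' Accuracy metrics
#'
#' `rmse()` is the root mean square error between estimates and true values;
#' `mae()` the mean absolute error; `sd_abs_error()` the standard deviation
#' of the absolute errors (population convention, divide by n).
#'
#' @param estimates,truth Numeric vectors of equal length.
#' @return Scalar metric.
#' @examples
#' rmse(c(1, 3), c(0, 0)) # sqrt(5)
#' @export
rmse <- function(estimates, truth) {
  check_lengths(estimates, truth)
  sqrt(mean((estimates - truth)^2))
}

#' @rdname rmse
#' @export
mae <- function(estimates, truth) {
  check_lengths(estimates, truth)
  mean(abs(estimates - truth))
}

#' @rdname rmse
#' @export
sd_abs_error <- function(estimates, truth) {
  check_lengths(estimates, truth)
  e <- abs(estimates - truth)
  sqrt(mean((e - mean(e))^2))
}

check_lengths <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1) {
    stop("`estimates` and `truth` must have equal length >= 1", call. = FALSE)
  }
}

#' Parameter-recovery simulation experiment
#'
#' For each design setting and each model: draw true parameters from the
#' generating distributions, simulate complete rating data, refit the same
#' model, and compute (i) the RMSE pooled over all rater and task
#' characteristic parameters and (ii) the RMSE of the EAP abilities —
#' repeated `reps` times.
#'
#' @param settings A data frame with columns `J`, `R`, `I`, `K` (one row per
#'   design), e.g. `tibble(J = 100, R = 10, I = 5, K = 5)`.
#' @param models Character vector of model ids.
#' @param config An [mcmc_config()] used for every fit.
#' @param reps Number of repetitions per (setting, model) cell (default 10).
#' @param seed Optional integer seed for the whole experiment.
#' @return A tibble with one row per (setting, model, repetition):
#'   columns `J`, `R`, `I`, `K`, `model`, `rep`, `rmse_params`,
#'   `rmse_theta`. Aggregate with [summarise_recovery()].
#' @export
run_recovery_experiment <- function(settings, models = MODEL_IDS,
                                    config = mcmc_config(), reps = 10,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  settings <- tibble::as_tibble(settings)
  purrr::pmap_dfr(settings, function(J, R, I, K, ...) {
    purrr::map_dfr(models, function(m) {
      purrr::map_dfr(seq_len(reps), function(rep) {
        truth <- draw_true_params(m, J = J, I = I, R = R, K = K)
        data <- simulate_ratings(truth)
        fit <- fit_rater_model(data, m, config)
        est <- eap(fit)
        tibble::tibble(
          J = J, R = R, I = I, K = K, model = m, rep = rep,
          rmse_params = rmse(rater_task_params(est), rater_task_params(truth)),
          rmse_theta = rmse(est$theta, truth$theta)
        )
      })
    })
  })
}

#' @rdname run_recovery_experiment
#' @param results A tibble from `run_recovery_experiment()`.
#' @return `summarise_recovery()`: mean and SD of both RMSEs per
#'   (setting, model) over repetitions.
#' @export
summarise_recovery <- function(results) {
  results |>
    dplyr::group_by(.data$J, .data$R, .data$I, .data$K, .data$model) |>
    dplyr::summarise(
      mean_rmse_params = mean(.data$rmse_params),
      sd_rmse_params = sd(.data$rmse_params),
      mean_rmse_theta = mean(.data$rmse_theta),
      sd_rmse_theta = sd(.data$rmse_theta),
      .groups = "drop"
    )
}

#' Bias-injection model-selection experiment
#'
#' Per repetition: draw MFRM truth at the given design, simulate complete
#' data, apply each transformation rule of [apply_transform()], fit all
#' candidate models to the transformed data, score them with the four
#' information criteria, rank per criterion, and compute each model's
#' ability RMSE against the pre-transformation true abilities.
#'
#' @param rules Character vector of rule ids, subset of `"A"`..`"F"`.
#' @param models Character vector of model ids to fit (default all five).
#' @param config An [mcmc_config()] used for every fit.
#' @param reps Repetitions (default 10).
#' @param J,R,I,K Design dimensions (defaults 100, 5, 5, 5).
#' @param seed Optional integer seed.
#' @return A tibble with one row per (rule, repetition, model): criterion
#'   scores, per-criterion ranks and `rmse_theta`. Aggregate with
#'   [summarise_bias()].
#' @export
run_bias_experiment <- function(rules = LETTERS[1:6], models = MODEL_IDS,
                                config = mcmc_config(), reps = 10,
                                J = 100, R = 5, I = 5, K = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(seq_len(reps), function(rep) {
    truth <- draw_true_params("mfrm", J = J, I = I, R = R, K = K)
    data <- simulate_ratings(truth)
    purrr::map_dfr(rules, function(rl) {
      tdata <- apply_transform(data, rl)
      fits <- lapply(models, function(m) fit_rater_model(tdata, m, config))
      names(fits) <- models
      tab <- criterion_scores(fits, tdata)
      tab$rmse_theta <- vapply(fits, function(f) {
        rmse(eap(f)$theta, truth$theta)
      }, numeric(1))
      dplyr::bind_cols(tibble::tibble(rule = rl, rep = rep), tab)
    })
  })
}

#' @rdname run_bias_experiment
#' @param results A tibble from `run_bias_experiment()`.
#' @return `summarise_bias()`: mean and SD of each criterion rank and of the
#'   ability RMSE per (rule, model).
#' @export
summarise_bias <- function(results) {
  results |>
    dplyr::group_by(.data$rule, .data$model) |>
    dplyr::summarise(
      dplyr::across(dplyr::starts_with("rank_"),
                    list(mean = mean, sd = sd)),
      mean_rmse_theta = mean(.data$rmse_theta),
      sd_rmse_theta = sd(.data$rmse_theta),
      .groups = "drop"
    )
}

#' Descriptive statistics of rating data
#'
#' Computes, for every rater and every task: the mean rating, the item-rest
#' (I-R) correlation — the Pearson correlation between the unit's ratings
#' and the mean of the remaining units' ratings on the same outcomes — and
#' the appearance rate of each category. For raters, the mean rating per
#' task is also returned (to inspect task-dependent severity).
#'
#' @param data A [rating_data()] object.
#' @return A list with tibbles `raters`, `tasks` and `rater_task_means`.
#'   Undefined correlations (fewer than 2 paired observations, or zero
#'   variance) are reported as `NA`.
#' @export
descriptive_stats <- function(data) {
  data <- as_rating_data(data)
  d <- rating_dims(data)
  idx <- obs_index(data)
  x <- as_rating_array(data)
  xx <- ifelse(x == -1L, NA_real_, as.numeric(x))

  rate_cols <- function(v) {
    v <- v[!is.na(v)]
    setNames(as.list(tabulate(v, d$K) / length(v)), paste0("rate_", seq_len(d$K)))
  }
  ir_cor <- function(own, rest_mean) {
    ok <- !is.na(own) & !is.na(rest_mean)
    if (sum(ok) < 2) return(NA_real_)
    if (sd(own[ok]) == 0 || sd(rest_mean[ok]) == 0) return(NA_real_)
    cor(own[ok], rest_mean[ok])
  }

  raters <- purrr::map_dfr(seq_len(d$R), function(r) {
    own <- as.vector(xx[, , r])
    rest <- apply(xx[, , -r, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
    rest[is.nan(rest)] <- NA_real_
    tibble::tibble(
      rater = attr(data, "rater_ids")[r],
      mean_rating = mean(own, na.rm = TRUE),
      ir_cor = ir_cor(own, as.vector(rest)),
      !!!rate_cols(own)
    )
  })
  tasks <- purrr::map_dfr(seq_len(d$I), function(i) {
    own <- as.vector(xx[i, , ])
    rest <- apply(xx[-i, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE)
    rest[is.nan(rest)] <- NA_real_
    tibble::tibble(
      task = attr(data, "task_ids")[i],
      mean_rating = mean(own, na.rm = TRUE),
      ir_cor = ir_cor(own, as.vector(rest)),
      !!!rate_cols(own)
    )
  })
  rt <- purrr::map_dfr(seq_len(d$R), function(r) {
    purrr::map_dfr(seq_len(d$I), function(i) {
      tibble::tibble(rater = attr(data, "rater_ids")[r],
                     task = attr(data, "task_ids")[i],
                     mean_rating = mean(xx[i, , r], na.rm = TRUE))
    })
  })
  list(raters = raters, tasks = tasks, rater_task_means = rt)
}

#' Full analysis of an observed rating data set
#'
#' Fits all candidate models, computes the criterion table, then emulates a
#' sparse re-scoring study: the data are reduced to a judge-pair design
#' (two raters per outcome), abilities are re-estimated with the rater and
#' task parameters held at their complete-data EAP estimates, and the
#' RMSE / MAE / SD of absolute error between complete-data and
#' reduced-data abilities are reported per model.
#'
#' @param data A [rating_data()] object.
#' @param models Character vector of model ids (default all five).
#' @param config An [mcmc_config()].
#' @param seed Optional integer seed (fits and the judge-pair draw).
#' @return A list with `criteria` (criterion table), `ability_error`
#'   (tibble model / rmse / mae / sd), `fits` and the reduced data.
#' @export
run_actual_data_analysis <- function(data, models = MODEL_IDS,
                                     config = mcmc_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data <- as_rating_data(data)
  fits <- lapply(models, function(m) fit_rater_model(data, m, config))
  names(fits) <- models
  criteria <- criterion_scores(fits, data)
  reduced <- judge_pair(data)
  ability_error <- purrr::map_dfr(models, function(m) {
    est <- eap(fits[[m]])
    full_theta <- est$theta
    red <- estimate_ability_given_params(reduced, est)
    tibble::tibble(
      model = m,
      rmse = rmse(red$theta, full_theta),
      mae = mae(red$theta, full_theta),
      sd = sd_abs_error(red$theta, full_theta)
    )
  })
  list(criteria = criteria, ability_error = ability_error, fits = fits,
       reduced_data = reduced)
}
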