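#' Category response curves
#'
#' Plots the probability of each rating category as a function of ability
#' for one (task, rater) pair of a parameter bundle — the standard item
#' response curve display for polytomous models.
#'
#' @param params A [rater_params] bundle.
#' @param task,rater 1-based indices (rater ignored for the HRM stage-1
#'   curves).
#' @param theta_range Ability range to plot over.
#' @return A ggplot object.
#' @export
plot_irc <- function(params, task = 1, rater = 1,
                     theta_range = c(-4, 4)) {
  th <- seq(theta_range[1], theta_range[2], length.out = 201)
  p <- exp(log_prob_matrix(params, task, rater, th))
  df <- tibble::tibble(
    theta = rep(th, params$K),
    category = factor(rep(seq_len(params$K), each = length(th))),
    probability = as.vector(p)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$theta, .data$probability,
                                   colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(theta), y = "P(category)",
      title = sprintf("%s response curves (task %d, rater %d)",
                      params_model(params), task, rater)
    ) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of a fitted model
#'
#' `type = "trace"` shows the total log-likelihood across retained draws
#' (a quick mixing check); `type = "ability"` shows the EAP abilities with
#' posterior-SD error bars.
#'
#' @param object A `rater_fit` object.
#' @param type `"trace"` or `"ability"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rater_fit <- function(object, type = c("trace", "ability"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    df <- tibble::tibble(draw = seq_along(object$loglik),
                         log_lik = object$loglik)
    ggplot2::ggplot(df, ggplot2::aes(.data$draw, .data$log_lik)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "retained draw", y = "log-likelihood",
                    title = paste(object$model, "log-likelihood trace")) +
      ggplot2::theme_minimal()
  } else {
    s <- object$samples$theta
    df <- tibble::tibble(
      examinee = factor(object$data_ids$examinee,
                        levels = object$data_ids$examinee),
      theta = colMeans(s), sd = apply(s, 2, sd)
    )
    ggplot2::ggplot(df, ggplot2::aes(.data$examinee, .data$theta)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$theta - .data$sd,
                                            ymax = .data$theta + .data$sd)) +
      ggplot2::labs(y = expression(hat(theta)), x = "examinee",
                    title = paste(object$model, "EAP abilities")) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
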