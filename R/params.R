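#' Parameter bundles for the rater-effect models
#'
#' Each of the five models carries its own set of task, rater and category
#' parameters plus the examinee abilities `theta` (logit scale). The
#' constructors validate the model's identifiability constraints:
#'
#' * `mfrm_params()`: many-facet Rasch model. Task difficulties `beta_task`
#'   (length I), rater severities `beta_rater` (length R, first fixed at 0),
#'   category thresholds `d_cat` (length K, `d_cat[1] = 0`,
#'   `sum(d_cat[-1]) = 0`).
#' * `patz_params()`: GPCM with a per-task rater severity. Discriminations
#'   `alpha` (length I, positive), step difficulties `beta_step` (I x K,
#'   first column 0), severities `rho` (I x R, first column 0).
#' * `ueno_params()`: GRM with per-rater category thresholds (range
#'   restriction). `alpha`, task difficulties `b_task` (length I), thresholds
#'   `eps` (R x (K-1), strictly increasing within each rater,
#'   `eps[1, 1] = -1`).
#' * `uto_params()`: GRM with rater severity and consistency.
#'   `alpha_task` (length I, positive), `alpha_rater` (length R, positive,
#'   first fixed at 1), category difficulties `b_cat` (I x (K-1), strictly
#'   increasing within each task), severities `eps_rater` (length R, first
#'   fixed at 0).
#' * `hrm_params()`: hierarchical rater model. A PCM with `beta_task`
#'   (length I) and thresholds `d_step` (I x K, first column 0, rows of
#'   columns 2..K summing to 0) generates a latent ideal rating `xi`
#'   (I x J, integers 1..K); a Gaussian signal-detection stage with rater
#'   severity `sigma` (length R) and spread `psi` (length R, positive;
#'   `1/psi^2` is the rater's consistency) generates the observed rating.
#'
#' @param beta_task,beta_rater,d_cat,alpha,beta_step,rho,b_task,eps,
#'   alpha_task,alpha_rater,b_cat,eps_rater,d_step,xi,sigma,psi Model
#'   parameters, see Details.
#' @param theta Numeric vector of J examinee abilities.
#' @return A list of class `c("<model>_params", "rater_params")`.
#' @name rater_params
NULL

new_params <- function(model, fields, theta) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  structure(
    c(fields, list(theta = as.numeric(theta))),
    model = model,
    class = c(paste0(sub("[0-9]+$", "", model), "_params"), "rater_params")
  )
}

check <- function(ok, msg) if (!all(ok)) stop(msg, call. = FALSE)

#' @rdname rater_params
#' @export
mfrm_params <- function(beta_task, beta_rater, d_cat, theta) {
  K <- length(d_cat)
  check(K >= 2, "need K >= 2 category thresholds")
  check(abs(beta_rater[1]) < 1e-8, "first rater severity must be fixed at 0")
  check(abs(d_cat[1]) < 1e-8, "d_cat[1] must be 0")
  check(abs(sum(d_cat[-1])) < 1e-6, "d_cat[2..K] must sum to 0")
  new_params("mfrm", list(
    beta_task = as.numeric(beta_task), beta_rater = as.numeric(beta_rater),
    d_cat = as.numeric(d_cat), K = K
  ), theta)
}

#' @rdname rater_params
#' @export
patz_params <- function(alpha, beta_step, rho, theta) {
  beta_step <- as.matrix(beta_step); rho <- as.matrix(rho)
  I <- length(alpha); K <- ncol(beta_step)
  check(alpha > 0, "alpha must be positive")
  check(nrow(beta_step) == I && nrow(rho) == I, "dimension mismatch")
  check(abs(beta_step[, 1]) < 1e-8, "beta_step[, 1] must be 0")
  check(abs(rho[, 1]) < 1e-8, "reference rater severity must be fixed at 0")
  new_params("patz1999", list(
    alpha = as.numeric(alpha), beta_step = beta_step, rho = rho, K = K
  ), theta)
}

#' @rdname rater_params
#' @export
ueno_params <- function(alpha, b_task, eps, theta) {
  eps <- as.matrix(eps)
  K <- ncol(eps) + 1L
  check(alpha > 0, "alpha must be positive")
  check(length(b_task) == length(alpha), "dimension mismatch")
  check(apply(eps, 1, function(e) all(diff(e) > 0)),
        "rater thresholds must be strictly increasing")
  check(abs(eps[1, 1] + 1) < 1e-8, "eps[1, 1] must be fixed at -1.0")
  new_params("ueno2008", list(
    alpha = as.numeric(alpha), b_task = as.numeric(b_task), eps = eps, K = K
  ), theta)
}

#' @rdname rater_params
#' @export
uto_params <- function(alpha_task, alpha_rater, b_cat, eps_rater, theta) {
  b_cat <- as.matrix(b_cat)
  K <- ncol(b_cat) + 1L
  check(alpha_task > 0, "alpha_task must be positive")
  check(alpha_rater > 0, "alpha_rater must be positive")
  check(abs(alpha_rater[1] - 1) < 1e-8, "alpha_rater[1] must be fixed at 1")
  check(abs(eps_rater[1]) < 1e-8, "eps_rater[1] must be fixed at 0")
  check(apply(b_cat, 1, function(b) all(diff(b) > 0)),
        "task category difficulties must be strictly increasing")
  new_params("uto2016", list(
    alpha_task = as.numeric(alpha_task), alpha_rater = as.numeric(alpha_rater),
    b_cat = b_cat, eps_rater = as.numeric(eps_rater), K = K
  ), theta)
}

#' @rdname rater_params
#' @export
hrm_params <- function(beta_task, d_step, xi, sigma, psi, theta) {
  d_step <- as.matrix(d_step); xi <- as.matrix(xi)
  K <- ncol(d_step)
  check(abs(d_step[, 1]) < 1e-8, "d_step[, 1] must be 0")
  check(abs(rowSums(d_step[, -1, drop = FALSE])) < 1e-6,
        "d_step[i, 2..K] must sum to 0")
  check(xi >= 1 & xi <= K & xi == round(xi), "xi entries must be in 1..K")
  check(psi > 0, "psi must be positive")
  check(ncol(xi) == length(theta), "xi must be I x J")
  new_params("hrm", list(
    beta_task = as.numeric(beta_task), d_step = d_step,
    xi = matrix(as.integer(xi), nrow(xi)), sigma = as.numeric(sigma),
    psi = as.numeric(psi), K = K
  ), theta)
}

params_model <- function(params) attr(params, "model")

params_dims <- function(params) {
  m <- params_model(params)
  J <- length(params$theta)
  switch(m,
    mfrm = list(J = J, I = length(params$beta_task),
                R = length(params$beta_rater), K = params$K),
    patz1999 = list(J = J, I = length(params$alpha), R = ncol(params$rho),
                    K = params$K),
    ueno2008 = list(J = J, I = length(params$alpha), R = nrow(params$eps),
                    K = params$K),
    uto2016 = list(J = J, I = length(params$alpha_task),
                   R = length(params$alpha_rater), K = params$K),
    hrm = list(J = J, I = length(params$beta_task), R = length(params$sigma),
               K = params$K)
  )
}

#' @export
print.rater_params <- function(x, ...) {
  d <- params_dims(x)
  cat(sprintf("<%s parameters> J=%d, I=%d, R=%d, K=%d\n",
              params_model(x), d$J, d$I, d$R, d$K))
  invisible(x)
}

#' Number of parameters of each model
#'
#' Evaluates the conventional parameter-count formulas used by the information
#' criteria: MFRM `I+K+R+J-2`; Patz1999 `I(K+R-1)+J`; Ueno2008
#' `2I+R(K-1)-1+J`; Uto2016 `IK+2(R-1)+J`; HRM `I(K-1+J)+2R+J`. Note that
#' the HRM count includes the I x J latent ideal ratings, and the MFRM
#' formula counts one more than the free parameters implied by its
#' identifiability constraints; both conventions are kept for
#' comparability with the models' literature.
#'
#' @param model One of `"mfrm"`, `"patz1999"`, `"ueno2008"`, `"uto2016"`,
#'   `"hrm"`.
#' @param J,I,R,K Numbers of examinees, tasks, raters and categories.
#' @return Integer parameter count.
#' @examples
#' count_params("mfrm", J = 100, I = 5, R = 10, K = 5) # 118
#' @export
count_params <- function(model, J, I, R, K) {
  stopifnot(J >= 1, I >= 1, R >= 1, K >= 2)
  as.integer(switch(match_model(model),
    mfrm = I + K + R + J - 2,
    patz1999 = I * (K + R - 1) + J,
    ueno2008 = 2 * I + R * (K - 1) - 1 + J,
    uto2016 = I * K + 2 * (R - 1) + J,
    hrm = I * (K - 1 + J) + 2 * R + J
  ))
}

# Pooled vector of all rater and task characteristic parameters, used for
# parameter-recovery RMSE. Identifiability-fixed entries are excluded (their
# error is identically zero); sum-determined elements are included. Abilities
# and HRM ideal ratings are excluded (ability error is reported separately).
rater_task_params <- function(params) {
  switch(params_model(params),
    mfrm = c(params$beta_task, params$beta_rater[-1], params$d_cat[-1]),
    patz1999 = c(params$alpha, params$beta_step[, -1],
                 params$rho[, -1, drop = FALSE]),
    ueno2008 = c(params$alpha, params$b_task, as.vector(params$eps)[-1]),
    uto2016 = c(params$alpha_task, params$alpha_rater[-1],
                as.vector(params$b_cat), params$eps_rater[-1]),
    hrm = c(params$beta_task, params$d_step[, -1], params$sigma, params$psi)
  )
}

#' Serialize model parameters to JSON
#'
#' Writes a parameter bundle to the package's documented JSON schema
#' `{"model": id, "K": int, "task": {...}, "rater": {...},
#' "category": {...}, "ability": [...]}`; fixed entries are stored
#' explicitly and the constraint fields are flagged. `read_params_json()`
#' reverses the mapping and re-validates all constraints.
#'
#' @param params A [rater_params] object.
#' @param path Output (input) file path.
#' @return `path` invisibly; `read_params_json()` returns the parameter
#'   bundle.
#' @export
write_params_json <- function(params, path) {
  m <- params_model(params)
  grp <- switch(m,
    mfrm = list(task = list(beta_task = params$beta_task),
                rater = list(beta_rater = params$beta_rater, fixed = "beta_rater[1]"),
                category = list(d_cat = params$d_cat, fixed = "d_cat[1], sum d_cat[2..K]=0")),
    patz1999 = list(task = list(alpha = params$alpha, beta_step = params$beta_step,
                                fixed = "beta_step[,1]"),
                    rater = list(rho = params$rho, fixed = "rho[,1]"),
                    category = list()),
    ueno2008 = list(task = list(alpha = params$alpha, b_task = params$b_task),
                    rater = list(eps = params$eps, fixed = "eps[1,1]=-1"),
                    category = list()),
    uto2016 = list(task = list(alpha_task = params$alpha_task, b_cat = params$b_cat),
                   rater = list(alpha_rater = params$alpha_rater,
                                eps_rater = params$eps_rater,
                                fixed = "alpha_rater[1]=1, eps_rater[1]=0"),
                   category = list()),
    hrm = list(task = list(beta_task = params$beta_task, d_step = params$d_step,
                           fixed = "d_step[,1], row sums"),
               rater = list(sigma = params$sigma, psi = params$psi),
               category = list(xi = params$xi))
  )
  obj <- c(list(model = m, K = params$K), grp, list(ability = params$theta))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- as.numeric(o$ability)
  switch(o$model,
    mfrm = mfrm_params(o$task$beta_task, o$rater$beta_rater, o$category$d_cat, th),
    patz1999 = patz_params(o$task$alpha, o$task$beta_step, o$rater$rho, th),
    ueno2008 = ueno_params(o$task$alpha, o$task$b_task, o$rater$eps, th),
    uto2016 = uto_params(o$task$alpha_task, o$rater$alpha_rater, o$task$b_cat,
                         o$rater$eps_rater, th),
    hrm = hrm_params(o$task$beta_task, o$task$d_step, o$category$xi,
                     o$rater$sigma, o$rater$psi, th),
    stop("unknown model id: ", o$model, call. = FALSE)
  )
}
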