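#' Rating data in long format
#'
#' Performance-assessment ratings form a three-way layout: each rater r awards
#' a category \eqn{x_{ijr} \in \{1, \dots, K\}} to the outcome of examinee j on
#' task i; a value of \eqn{-1} (or an absent row) marks a missing rating.
#' `rating_data()` validates a long-format data frame with columns
#' `examinee`, `task`, `rater`, `rating` and returns a tibble that carries the
#' category count `K` and the stable id-to-index maps as attributes. All other
#' functions in the package accept this object (or any data frame with the
#' same columns, which is coerced on the fly).
#'
#' Ids may be arbitrary strings or integers; they are mapped to 1-based
#' indices in order of first appearance unless explicit id universes are
#' supplied, which allows units with no observed ratings to be represented.
#'
#' @param data A data frame with columns `examinee`, `task`, `rater`,
#'   `rating`.
#' @param K Number of rating categories (>= 2).
#' @param examinee_ids,task_ids,rater_ids Optional explicit id vectors fixing
#'   the index order (defaults: first appearance in `data`).
#' @return A tibble of class `"rating_data"` with one row per non-missing
#'   rating and attributes `K`, `examinee_ids`, `task_ids`, `rater_ids`.
#' @examples
#' df <- tibble::tibble(
#'   examinee = c(1, 1, 2), task = 1, rater = c(1, 2, 1), rating = c(3, 2, 5)
#' )
#' rating_data(df, K = 5)
#' @export
rating_data <- function(data, K, examinee_ids = NULL, task_ids = NULL,
                        rater_ids = NULL) {
  stopifnot(is.data.frame(data), K >= 2, K == round(K))
  need <- c("examinee", "task", "rater", "rating")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)[need]
  bad <- !(data$rating == -1 | (data$rating >= 1 & data$rating <= K &
                                  data$rating == round(data$rating)))
  if (any(bad)) {
    stop("rating outside {-1, 1..", K, "} in row(s) ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(data$examinee, data$task, data$rater, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (examinee, task, rater) key in row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  ids <- function(given, seen, what) {
    if (is.null(given)) return(unique(seen))
    if (!all(seen %in% given)) stop("unknown ", what, " id in `data`", call. = FALSE)
    given
  }
  e_ids <- ids(examinee_ids, data$examinee, "examinee")
  t_ids <- ids(task_ids, data$task, "task")
  r_ids <- ids(rater_ids, data$rater, "rater")
  data <- data[data$rating != -1, , drop = FALSE]
  if (nrow(data) == 0) stop("no non-missing ratings", call. = FALSE)
  new_rating_data(data, K, e_ids, t_ids, r_ids)
}

new_rating_data <- function(data, K, e_ids, t_ids, r_ids) {
  structure(
    tibble::as_tibble(data),
    K = as.integer(K),
    examinee_ids = e_ids, task_ids = t_ids, rater_ids = r_ids,
    class = c("rating_data", class(tibble::tibble()))
  )
}

as_rating_data <- function(data, K = NULL) {
  if (inherits(data, "rating_data")) return(data)
  if (is.null(K)) stop("`K` must be given for a plain data frame", call. = FALSE)
  rating_data(data, K)
}

#' Dimensions of a rating data set
#'
#' @param data A [rating_data()] object.
#' @return A list with elements `J` (examinees), `I` (tasks), `R` (raters),
#'   `K` (categories) and `n_obs` (non-missing ratings).
#' @export
rating_dims <- function(data) {
  stopifnot(inherits(data, "rating_data"))
  list(
    J = length(attr(data, "examinee_ids")),
    I = length(attr(data, "task_ids")),
    R = length(attr(data, "rater_ids")),
    K = attr(data, "K"),
    n_obs = nrow(data)
  )
}

#' Convert rating data to a dense task x examinee x rater array
#'
#' Missing cells are filled with `-1`.
#'
#' @param data A [rating_data()] object.
#' @return An integer array of dimension `c(I, J, R)`.
#' @export
as_rating_array <- function(data) {
  stopifnot(inherits(data, "rating_data"))
  d <- rating_dims(data)
  x <- array(-1L, c(d$I, d$J, d$R))
  idx <- obs_index(data)
  x[cbind(idx$i, idx$j, idx$r)] <- as.integer(data$rating)
  x
}

# 1-based integer indices of the observed ratings
obs_index <- function(data) {
  list(
    i = match(data$task, attr(data, "task_ids")),
    j = match(data$examinee, attr(data, "examinee_ids")),
    r = match(data$rater, attr(data, "rater_ids")),
    x = as.integer(data$rating)
  )
}

# rebuild a rating_data from a dense array, keeping the id maps
array_to_rating_data <- function(x, K, e_ids = NULL, t_ids = NULL, r_ids = NULL) {
  dm <- dim(x)
  if (is.null(t_ids)) t_ids <- seq_len(dm[1])
  if (is.null(e_ids)) e_ids <- seq_len(dm[2])
  if (is.null(r_ids)) r_ids <- seq_len(dm[3])
  keep <- which(x != -1L, arr.ind = TRUE)
  ord <- order(keep[, 1], keep[, 2], keep[, 3])
  keep <- keep[ord, , drop = FALSE]
  df <- tibble::tibble(
    examinee = e_ids[keep[, 2]],
    task = t_ids[keep[, 1]],
    rater = r_ids[keep[, 3]],
    rating = as.integer(x[keep])
  )
  new_rating_data(df, K, e_ids, t_ids, r_ids)
}

#' Read ratings from a long-format CSV file
#'
#' The file must have a header `examinee,task,rater,rating`. Ratings of `-1`
#' and absent (examinee, task, rater) combinations both denote missing data.
#'
#' @param path Path to a CSV file.
#' @param K Number of rating categories.
#' @return A [rating_data()] tibble.
#' @export
read_ratings <- function(path, K) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rating_data(df, K)
}

#' Write ratings to a long-format CSV file
#'
#' One row per non-missing rating, ordered by (task, examinee, rater) so the
#' output is deterministic and `read_ratings(write_ratings(x))` round-trips.
#'
#' @param data A [rating_data()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(data, path) {
  data <- as_rating_data(data)
  idx <- obs_index(data)
  ord <- order(idx$i, idx$j, idx$r)
  df <- data.frame(
    examinee = data$examinee[ord], task = data$task[ord],
    rater = data$rater[ord], rating = data$rating[ord]
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.rating_data <- function(x, ...) {
  d <- rating_dims(x)
  cat(sprintf(
    "<rating_data> %d ratings: J=%d examinees, I=%d tasks, R=%d raters, K=%d categories\n",
    d$n_obs, d$J, d$I, d$R, d$K
  ))
  NextMethod()
}
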