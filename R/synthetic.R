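#' Generate item ratings for a synthetic choice experiment
#'
#' Emulates the rating phase of the food-choice design: items are rated on
#' a -10..10 scale, items rated below zero are excluded, and rating/
#' redrawing continues until `n_items` non-negative ratings are retained.
#' The default rating source is integer-uniform on -10..10; supply
#' `rating_sampler` to emulate other rating distributions (it receives a
#' count and must return that many candidate ratings on the -10..10
#' scale; negatives are filtered out here).
#'
#' @param n_items Number of retained (non-negative) ratings, >= 2.
#' @param rating_sampler Optional `function(n)` returning `n` candidate
#'   ratings.
#' @return Numeric vector of `n_items` ratings in `[0, 10]`.
#' @examples
#' set.seed(1)
#' r <- generate_item_ratings(70)
#' range(r)
#' @export
generate_item_ratings <- function(n_items, rating_sampler = NULL) {
  if (!is.numeric(n_items) || length(n_items) != 1L || n_items < 2)
    stop("n_items must be a single number >= 2", call. = FALSE)
  n_items <- as.integer(n_items)
  if (is.null(rating_sampler))
    rating_sampler <- function(n) sample.int(21L, n, replace = TRUE) - 11L
  kept <- numeric(0)
  guard <- 0L
  while (length(kept) < n_items) {
    draw <- rating_sampler(n_items - length(kept))
    if (any(!is.finite(draw)) || any(draw > 10) || any(draw < -10))
      stop("rating_sampler must return finite ratings on the -10..10 scale",
           call. = FALSE)
    kept <- c(kept, draw[draw >= 0])
    guard <- guard + 1L
    if (guard > 10000L)
      stop("rating_sampler produced too few non-negative ratings",
           call. = FALSE)
  }
  kept[seq_len(n_items)]
}

#' Build random trial pairs from an item set
#'
#' Each trial draws two distinct items uniformly at random and assigns
#' them to the left/right screen positions uniformly, emulating the
#' randomised spatial placement of the choice phase.
#'
#' @param items Numeric vector of item ratings (from
#'   [generate_item_ratings()]), length >= 2.
#' @param n_trials Number of trials, >= 1.
#' @return Data frame with columns `trial_id`, `v_left`, `v_right`.
#' @examples
#' set.seed(1)
#' build_trial_pairs(generate_item_ratings(10), 5)
#' @export
build_trial_pairs <- function(items, n_trials) {
  if (!is.numeric(items) || length(items) < 2)
    stop("need at least 2 items", call. = FALSE)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("n_trials must be a single number >= 1", call. = FALSE)
  n_trials <- as.integer(n_trials)
  n <- length(items)
  first <- sample.int(n, n_trials, replace = TRUE)
  second <- sample.int(n - 1L, n_trials, replace = TRUE)
  second <- second + (second >= first)   # distinct partner
  flip <- stats::runif(n_trials) < 0.5   # uniform side assignment
  left_idx <- ifelse(flip, second, first)
  right_idx <- ifelse(flip, first, second)
  data.frame(trial_id = seq_len(n_trials),
             v_left = items[left_idx],
             v_right = items[right_idx])
}

#' Read and write trial tables as CSV
#'
#' The trial-input schema is `trial_id, v_left, v_right` with a header
#' row. Externally supplied CSVs in this schema bypass the synthetic
#' generator entirely.
#'
#' @param path CSV file path.
#' @return `read_trials_csv()` returns the validated trial data frame;
#'   `write_trials_csv()` returns `path` invisibly.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "v_left", "v_right")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial CSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("trial CSV is empty", call. = FALSE)
  if (any(!is.finite(df$v_left)) || any(!is.finite(df$v_right)))
    stop("trial CSV ratings must be finite numbers", call. = FALSE)
  df[need]
}

#' @rdname read_trials_csv
#' @param trials Data frame with columns `trial_id`, `v_left`, `v_right`.
#' @export
write_trials_csv <- function(trials, path) {
  need <- c("trial_id", "v_left", "v_right")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  utils::write.csv(trials[need], path, row.names = FALSE)
  invisible(path)
}
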