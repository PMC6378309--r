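#' Model parameters for the proactive sampling simulator
#'
#' Bundles the seven free parameters of the sampling model together with the
#' timing and initial-fixation constants. Defaults are the reference
#' simulation vector used throughout the package.
#'
#' @param sigma0 Standard deviation of the baseline sampling distribution
#'   (rating units). The fixated item's sampling variance is `sigma0^2`,
#'   which is also the prior belief variance for both items.
#' @param delta Per-sample decrement of the decision threshold
#'   `theta_t = 1 - delta * t` (dimensionless, > 0).
#' @param gamma Discount factor applied to the mean of the non-fixated
#'   item's sampling distribution (in `[0, 1]`).
#' @param kappa Variance inflation of the non-fixated item's sampling
#'   distribution: its sampling variance is `kappa * sigma0^2` (>= 1).
#' @param lam Per-update expansion ("forgetting") factor on the belief
#'   variance of the non-fixated item (>= 1).
#' @param omega Slope of the logistic saccade-switch policy on the
#'   posterior uncertainty (standard-deviation) ratio (> 0).
#' @param omega0 Intercept of the switch policy; more negative values
#'   encode a stronger repositioning cost (saccades become rarer).
#' @param p_first_left Probability that the first fixation of a trial lands
#'   on the left item (in `[0, 1]`).
#' @param sample_time_min_ms,sample_time_max_ms Bounds of the uniform
#'   per-sample duration distribution, in milliseconds.
#'
#' @return An object of class `ps_params`: a validated named list.
#' @examples
#' p <- model_params()
#' p$sigma0
#' model_params(sigma0 = 6, delta = 0.01)
#' @export
model_params <- function(sigma0 = 4, delta = 0.005, gamma = 0.1,
                         kappa = 2, lam = 1.1, omega = 2.5, omega0 = -6.5,
                         p_first_left = 0.74,
                         sample_time_min_ms = 50, sample_time_max_ms = 150) {
  p <- list(sigma0 = sigma0, delta = delta, gamma = gamma, kappa = kappa,
            lam = lam, omega = omega, omega0 = omega0,
            p_first_left = p_first_left,
            sample_time_min_ms = sample_time_min_ms,
            sample_time_max_ms = sample_time_max_ms)
  validate_params(p)
  structure(p, class = "ps_params")
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid parameter '", field, "': ", what, call. = FALSE)
  }
  for (f in names(p)) chk(num1(p[[f]]), f, "must be a single finite number")
  chk(p$sigma0 > 0, "sigma0", "must be > 0")
  chk(p$delta > 0, "delta", "must be > 0")
  chk(p$gamma >= 0 && p$gamma <= 1, "gamma", "must be in [0, 1]")
  chk(p$kappa >= 1, "kappa", "must be >= 1")
  chk(p$lam >= 1, "lam", "must be >= 1")
  chk(p$omega > 0, "omega", "must be > 0")
  chk(p$p_first_left >= 0 && p$p_first_left <= 1, "p_first_left",
      "must be in [0, 1]")
  chk(p$sample_time_min_ms > 0, "sample_time_min_ms", "must be > 0")
  chk(p$sample_time_max_ms >= p$sample_time_min_ms, "sample_time_max_ms",
      "must be >= sample_time_min_ms")
  invisible(p)
}

#' @export
print.ps_params <- function(x, ...) {
  cat("Proactive-sampling model parameters:\n")
  for (f in names(x)) cat(sprintf("  %-20s %g\n", f, x[[f]]))
  invisible(x)
}

#' Read model parameters (and a seed) from a key:value config file
#'
#' Plain-text configuration: one `key: value` (or `key = value`) pair per
#' line; blank lines and lines starting with `#` are ignored. Recognised
#' keys are the fields of [model_params()] plus `seed`. Missing keys fall
#' back to the defaults of [model_params()].
#'
#' @param path Path to the config file.
#' @return A list with elements `params` (a `ps_params`) and `seed`
#'   (integer, or `NA` if the file does not set one).
#' @examples
#' tf <- tempfile()
#' writeLines(c("sigma0: 6", "seed: 42"), tf)
#' cfg <- read_config(tf)
#' cfg$params$sigma0; cfg$seed
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: '", ln, "'",
                              call. = FALSE)
    val <- suppressWarnings(as.numeric(m[3]))
    if (is.na(val)) stop("non-numeric value for config key '", m[2], "'",
                         call. = FALSE)
    kv[[m[2]]] <- val
  }
  known <- c(names(formals(model_params)), "seed")
  bad <- setdiff(names(kv), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  seed <- if (!is.null(kv$seed)) as.integer(kv$seed) else NA_integer_
  kv$seed <- NULL
  params <- do.call(model_params, kv)
  list(params = params, seed = seed)
}

#' Write model parameters to a key:value config file
#'
#' Inverse of [read_config()]; round-trips every field exactly.
#'
#' @param params A `ps_params` object.
#' @param path Output file path.
#' @param seed Optional seed to record alongside the parameters.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, seed = NULL) {
  stopifnot(inherits(params, "ps_params"))
  lines <- vapply(names(params),
                  function(f) sprintf("%s: %.17g", f, params[[f]]), "")
  if (!is.null(seed)) lines <- c(lines, sprintf("seed: %d", as.integer(seed)))
  writeLines(lines, path)
  invisible(path)
}
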