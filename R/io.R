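#' Configuration for a reproducible simulation run
#'
#' Bundles model parameters with the experiment size, the mandatory seed,
#' the output directory and run flags. `trials_csv`, when given, bypasses
#' the synthetic experiment generator and loads the trial set from disk.
#'
#' @param params A [model_params()] object.
#' @param n_items Number of retained item ratings for the synthetic
#'   experiment.
#' @param n_trials Number of choice trials.
#' @param seed Integer master seed (mandatory).
#' @param out_dir Output directory (created if missing).
#' @param trials_csv Optional path to an external trial CSV
#'   (`trial_id, v_left, v_right`).
#' @param trace Write per-sample traces (`trace.csv`; large).
#' @param run_addm Also run the aDDM baseline on the harvested fixation
#'   schedules and write its trial table.
#' @return An object of class `ps_run_config`.
#' @export
run_config <- function(params = model_params(), n_items = 70,
                       n_trials = 1000, seed, out_dir,
                       trials_csv = NULL, trace = FALSE, run_addm = FALSE) {
  stopifnot(inherits(params, "ps_params"))
  validate_params(params)
  if (missing(seed) || !is.finite(seed))
    stop("invalid config: a seed is required", call. = FALSE)
  if (missing(out_dir) || !is.character(out_dir))
    stop("invalid config: out_dir is required", call. = FALSE)
  if (!is.numeric(n_items) || n_items < 2)
    stop("invalid config field 'n_items': must be >= 2", call. = FALSE)
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("invalid config field 'n_trials': must be >= 1", call. = FALSE)
  structure(list(params = params, n_items = as.integer(n_items),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 out_dir = out_dir, trials_csv = trials_csv,
                 trace = isTRUE(trace), run_addm = isTRUE(run_addm)),
            class = "ps_run_config")
}

#' Run a full simulation to disk
#'
#' Generates (or loads) the trial set, simulates every trial, and writes
#' `trials.csv`, `fixations.csv` and a `manifest.txt` recording the full
#' configuration, seed and package version. The same configuration always
#' produces byte-identical files. Durations and reaction times are
#' rounded to whole milliseconds at serialization (full precision is kept
#' internally).
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the written paths and the in-memory
#'   results.
#' @examples
#' out <- tempfile()
#' cfg <- run_config(n_items = 10, n_trials = 5, seed = 1, out_dir = out)
#' run_simulate(cfg)
#' list.files(out)
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "ps_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir))
    stop("cannot create output directory: ", config$out_dir, call. = FALSE)

  if (!is.null(config$trials_csv)) {
    trials <- read_trials_csv(config$trials_csv)
  } else {
    set.seed(derive_seed(config$seed, 0L))
    items <- generate_item_ratings(config$n_items)
    trials <- build_trial_pairs(items, config$n_trials)
  }
  results <- simulate_batch(trials, config$params, seed = config$seed,
                            trace = config$trace)
  tr <- trials_frame(results)
  fx <- fixations_frame(results)
  tr$rt_ms <- round(tr$rt_ms)
  fx$duration_ms <- round(fx$duration_ms)

  trials_path <- file.path(config$out_dir, "trials.csv")
  fix_path <- file.path(config$out_dir, "fixations.csv")
  utils::write.csv(tr, trials_path, row.names = FALSE)
  utils::write.csv(fx, fix_path, row.names = FALSE)

  if (config$trace) {
    traces <- do.call(rbind, lapply(results, function(r)
      cbind(trial_id = r$spec$trial_id, r$trace)))
    utils::write.csv(traces, file.path(config$out_dir, "trace.csv"),
                     row.names = FALSE)
  }
  if (config$run_addm) {
    addm <- simulate_addm_batch(trials, fx, addm_params(),
                                seed = config$seed)
    addm$rt_ms <- round(addm$rt_ms)
    utils::write.csv(addm, file.path(config$out_dir, "addm_trials.csv"),
                     row.names = FALSE)
  }

  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("prosamp"))),
    sprintf("seed: %d", config$seed),
    sprintf("n_items: %d", config$n_items),
    sprintf("n_trials: %d", nrow(trials)),
    sprintf("trials_source: %s",
            if (is.null(config$trials_csv)) "synthetic" else config$trials_csv),
    sprintf("trace: %s", config$trace),
    sprintf("run_addm: %s", config$run_addm),
    vapply(names(config$params),
           function(f) sprintf("%s: %.17g", f, config$params[[f]]), ""))
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))

  invisible(list(trials_csv = trials_path, fixations_csv = fix_path,
                 manifest = file.path(config$out_dir, "manifest.txt"),
                 results = results))
}

read_fixations_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "fixation_index", "item", "n_samples",
            "duration_ms", "is_last")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fixation CSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Summarize simulated runs from their CSVs
#'
#' Reads a trial table and a fixation table (the schemas written by
#' [run_simulate()]), validates them against each other, computes every
#' standard summary panel ([summarize_results()]) and writes one CSV per
#' panel into `out_dir`. Nothing is written unless all panels compute.
#'
#' @param trials_path Path to `trials.csv`.
#' @param fixations_path Path to `fixations.csv`.
#' @param out_dir Output directory for the panel CSVs.
#' @return Invisibly, the named list of panels.
#' @export
run_summarize <- function(trials_path, fixations_path, out_dir) {
  if (!file.exists(trials_path))
    stop("file not found: ", trials_path, call. = FALSE)
  tr <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  need <- c("trial_id", "v_left", "v_right", "choice", "rt_ms",
            "n_fixations", "n_samples_total")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("trial CSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(tr) == 0L) stop("trial CSV is empty", call. = FALSE)
  fx <- read_fixations_csv(fixations_path)
  if (!all(fx$trial_id %in% tr$trial_id))
    stop("fixation CSV references unknown trial_id", call. = FALSE)
  if (!all(tr$trial_id %in% fx$trial_id))
    stop("trial without fixations in fixation CSV", call. = FALSE)

  panels <- summarize_results(list(trials = tr, fixations = fx))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flat <- list(
    fig2A_choice_vs_drating = panels$choice_vs_drating,
    fig2B_choice_vs_duradv = panels$choice_vs_duradv,
    fig2C_choice_lastfix_left = panels$choice_by_lastfix$left,
    fig2C_choice_lastfix_right = panels$choice_by_lastfix$right,
    fig2D_rt_vs_absdiff = panels$rt_vs_absdiff,
    fig3A_middur_hist = panels$middur_hist,
    fig3B_nfix_vs_absdiff = panels$nfix_vs_absdiff,
    fig4A_middur_vs_rating = panels$middur_vs_rating,
    fig4B_middur_vs_absdiff = panels$middur_vs_absdiff,
    fig4C_middur_vs_index = panels$middur_vs_index,
    fig4D_dur_by_type = panels$dur_by_type,
    fig5_last_surface = panels$last_surface)
  for (nm in names(flat)) {
    if (is.null(flat[[nm]])) next
    utils::write.csv(flat[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(panels)
}

#' Run the aDDM baseline on a simulated run and compare choice curves
#'
#' Loads a trial and fixation table written by [run_simulate()], replays
#' the fixation schedules through the aDDM baseline, writes its trial
#' table (`addm_trials.csv`) and the paired psychometric curves
#' (`addm_comparison.csv`).
#'
#' @inheritParams run_summarize
#' @param params An [addm_params()] object.
#' @param seed Integer master seed for the aDDM noise.
#' @return Invisibly, the [compare_choice_curves()] result.
#' @export
run_compare_addm <- function(trials_path, fixations_path, out_dir,
                             params = addm_params(), seed) {
  tr <- read_trials_csv(trials_path)
  fx <- read_fixations_csv(fixations_path)
  full_tr <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  addm <- simulate_addm_batch(tr, fx, params, seed = seed)
  cmp <- compare_choice_curves(list(trials = full_tr, fixations = fx), addm)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  addm_out <- addm
  addm_out$rt_ms <- round(addm_out$rt_ms)
  utils::write.csv(addm_out, file.path(out_dir, "addm_trials.csv"),
                   row.names = FALSE)
  both <- rbind(cbind(model = "proactive", as.data.frame(cmp$bayes)),
                cbind(model = "addm", as.data.frame(cmp$addm)))
  utils::write.csv(both, file.path(out_dir, "addm_comparison.csv"),
                   row.names = FALSE)
  invisible(cmp)
}
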