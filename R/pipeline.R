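#' Analysis run configuration
#'
#' The pipeline constants: surface sampling spacing (0.01 mm, the
#' consecutive-coordinate spacing of the original analysis), active tip
#' length (5.00 mm), effective-range threshold (5.00 mm), the lateral sign
#' reference, ICP parameters, and the quantile convention.
#'
#' @param spacing_mm Surface sampling spacing (default 0.01 mm).
#' @param tip_length_mm Active tip length (default 5.00 mm).
#' @param threshold_mm Effective range (default 5.00 mm, strict <).
#' @param nerve_reference \code{"surface"} (default: distances to the
#'   segmented nerve surface, as with measured STLs) or \code{"centerline"}
#'   (distances to the nerve centerline, the point-to-line oracle; requires a
#'   reference centerline).
#' @param tip_mode \code{"all"} (default: minimal Euclidean distance over all
#'   tip points) or \code{"extreme"} (single deepest point only).
#' @param lateral_ref Unit vector mapping positive lateral to the subject's
#'   right; unsigned statistics never depend on it.
#' @param icp_max_iter,icp_tol_mm,icp_subsample_max ICP parameters (see
#'   \code{\link{icp_rigid}}).
#' @param quantile_rule Quartile convention (see \code{\link{summarize_metric}}).
#' @param alpha Normality-gate significance level (default 0.05).
#' @param seed Integer seed for any randomness in a run.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(spacing_mm = 0.01, tip_length_mm = 5.00,
                       threshold_mm = 5.00,
                       nerve_reference = c("surface", "centerline"),
                       tip_mode = c("all", "extreme"),
                       lateral_ref = c(1, 0, 0),
                       icp_max_iter = 100L, icp_tol_mm = 1e-6,
                       icp_subsample_max = 50000L,
                       quantile_rule = c("pn1", "linear"),
                       alpha = 0.05, seed = 1L) {
  nerve_reference <- match.arg(nerve_reference)
  tip_mode <- match.arg(tip_mode)
  quantile_rule <- match.arg(quantile_rule)
  for (f in c(spacing_mm, tip_length_mm, threshold_mm, icp_tol_mm))
    if (!is.numeric(f) || f <= 0)
      .np_stopf("run_config lengths and tolerances must be > 0")
  structure(list(spacing_mm = spacing_mm, tip_length_mm = tip_length_mm,
                 threshold_mm = threshold_mm,
                 nerve_reference = nerve_reference, tip_mode = tip_mode,
                 lateral_ref = as.numeric(lateral_ref),
                 icp_max_iter = as.integer(icp_max_iter),
                 icp_tol_mm = icp_tol_mm,
                 icp_subsample_max = as.integer(icp_subsample_max),
                 quantile_rule = quantile_rule, alpha = alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run or generator configuration as JSON
#' @param path JSON file path.
#' @return \code{read_config}: a \code{run_config}.
#' @export
read_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, lst[names(lst) %in% names(formals(run_config))])
}

#' @rdname read_config
#' @param config A \code{run_config} or \code{synth_config}.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.np_log <- function(logfile, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE, sep = "")
}

#' Write a synthetic cohort to disk
#'
#' Generates \code{n_trials} trials and writes, under \code{out_dir}:
#' \code{trial_###_nerve.stl} / \code{trial_###_needle.stl} pairs,
#' \code{trial_###_landmarks.csv}, a ground-truth table
#' (\code{ground_truth.csv}), the unposed reference nerve
#' (\code{reference_nerve.stl}), its centerline
#' (\code{reference_centerline.csv}), reference landmarks, and a manifest.
#' Deterministic under \code{(config, seed)}.
#'
#' @param config A \code{synth_config}.
#' @param n_trials Number of trials.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed (default \code{config$seed}).
#' @param offsets Optional per-trial offsets (see \code{\link{generate_cohort}}).
#' @param dialect STL dialect (default binary).
#' @return \code{out_dir}, invisibly.
#' @export
run_synth <- function(config, n_trials, out_dir, seed = config$seed,
                      offsets = NULL, dialect = "binary") {
  stopifnot(inherits(config, "synth_config"))
  trials <- generate_cohort(config, n_trials, seed = seed, offsets = offsets)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run_synth.log")

  ref <- generate_nerve(config)
  write_stl(ref$mesh, file.path(out_dir, "reference_nerve.stl"), dialect)
  write.csv(data.frame(x = ref$centerline[, 1], y = ref$centerline[, 2],
                       z = ref$centerline[, 3]),
            file.path(out_dir, "reference_centerline.csv"), row.names = FALSE)
  write_landmarks(.landmark_template(),
                  file.path(out_dir, "reference_landmarks.csv"))

  gt <- lapply(trials, function(tr) {
    write_stl(tr$nerve, file.path(out_dir, paste0(tr$trial_id, "_nerve.stl")),
              dialect)
    write_stl(tr$needle, file.path(out_dir, paste0(tr$trial_id, "_needle.stl")),
              dialect)
    write_landmarks(tr$landmarks,
                    file.path(out_dir, paste0(tr$trial_id, "_landmarks.csv")))
    data.frame(trial_id = tr$trial_id,
               true_lateral_mm = tr$truth$true_lateral_mm,
               true_depth_mm = tr$truth$true_depth_mm,
               true_euclidean_mm = tr$truth$true_euclidean_mm,
               seed = seed)
  })
  write.csv(do.call(rbind, gt), file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
  write_config(config, file.path(out_dir, "synth_config.json"))
  .np_log(logfile, "wrote %d synthetic trial(s) to %s", n_trials,
          normalizePath(out_dir))
  invisible(out_dir)
}

.discover_trials <- function(trials_dir) {
  nerves <- sort(list.files(trials_dir, pattern = "_nerve\\.stl$"))
  ids <- sub("_nerve\\.stl$", "", nerves)
  ids[file.exists(file.path(trials_dir, paste0(ids, "_needle.stl")))]
}

#' Run the end-to-end cohort analysis on an STL trial directory
#'
#' Discovers \code{<id>_nerve.stl} / \code{<id>_needle.stl} pairs (plus
#' optional \code{<id>_landmarks.csv}), registers every trial nerve onto the
#' reference (the \code{reference_nerve.stl} in the directory if present,
#' otherwise the first trial's nerve), carries the transform to the needle,
#' computes the accuracy metrics and the cohort table, and writes
#' \code{per_trial.csv}, \code{summary.csv}, \code{scatter.csv}, a manifest
#' and a log under \code{out_dir}.
#'
#' @param trials_dir Directory of per-trial STL pairs.
#' @param out_dir Output directory.
#' @param config A \code{run_config}.
#' @param reference_id Optional trial id to use as the reference instead of
#'   \code{reference_nerve.stl} / the first trial.
#' @return Invisibly, a list with \code{results}, \code{summary},
#'   \code{scatter} and \code{skipped}.
#' @export
run_analysis <- function(trials_dir, out_dir, config = run_config(),
                         reference_id = NULL) {
  if (!dir.exists(trials_dir))
    .np_stopf("trial directory not found: %s", trials_dir)
  ids <- .discover_trials(trials_dir)
  if (length(ids) == 0L)
    .np_stopf("no <id>_nerve.stl / <id>_needle.stl pairs found in %s",
              trials_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run_analysis.log")
  .np_log(logfile, "found %d trial(s) in %s", length(ids), trials_dir)

  load_trial <- function(id) {
    lmf <- file.path(trials_dir, paste0(id, "_landmarks.csv"))
    structure(list(
      trial_id = id,
      nerve = read_stl(file.path(trials_dir, paste0(id, "_nerve.stl"))),
      needle = read_stl(file.path(trials_dir, paste0(id, "_needle.stl"))),
      landmarks = if (file.exists(lmf)) read_landmarks(lmf) else NULL,
      truth = NULL), class = "trial_record")
  }

  ref_stl <- file.path(trials_dir, "reference_nerve.stl")
  if (!is.null(reference_id)) {
    ref_mesh <- read_stl(file.path(trials_dir, paste0(reference_id, "_nerve.stl")))
    ref_lm <- NULL
    lmf <- file.path(trials_dir, paste0(reference_id, "_landmarks.csv"))
    if (file.exists(lmf)) ref_lm <- read_landmarks(lmf)
  } else if (file.exists(ref_stl)) {
    ref_mesh <- read_stl(ref_stl)
    lmf <- file.path(trials_dir, "reference_landmarks.csv")
    ref_lm <- if (file.exists(lmf)) read_landmarks(lmf) else NULL
  } else {
    ref_mesh <- read_stl(file.path(trials_dir, paste0(ids[1], "_nerve.stl")))
    lmf <- file.path(trials_dir, paste0(ids[1], "_landmarks.csv"))
    ref_lm <- if (file.exists(lmf)) read_landmarks(lmf) else NULL
    .np_log(logfile, "no reference_nerve.stl: using first trial '%s' as reference",
            ids[1])
  }
  clf <- file.path(trials_dir, "reference_centerline.csv")
  cl <- NULL
  if (file.exists(clf)) {
    df <- read.csv(clf)
    cl <- point_cloud(as.matrix(df[, c("x", "y", "z")]), config$spacing_mm)
  }
  reference <- make_reference(ref_mesh, config, centerline = cl,
                              landmarks = ref_lm)

  rows <- list(); skipped <- character(0)
  for (id in ids) {
    res <- tryCatch(assess_trial(load_trial(id), reference, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[id]] <- conditionMessage(res)
      .np_log(logfile, "SKIP %s: %s", id, conditionMessage(res))
    } else {
      .np_log(logfile, "%s: euclidean %.3f, lateral %+.3f, depth %+.3f mm (icp rms %.4g, %d it)",
              id, res$euclidean_mm, res$lateral_signed_mm, res$depth_signed_mm,
              res$icp_rms_mm, res$icp_iterations)
      rows[[id]] <- as.data.frame(res)
    }
  }
  if (length(rows) == 0L)
    .np_stopf("all %d trial(s) failed; see %s", length(ids), logfile)

  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summary <- cohort_table(results, config$threshold_mm, config$alpha,
                          config$quantile_rule)
  scatter <- scatter_coordinates(results)
  write.csv(results, file.path(out_dir, "per_trial.csv"), row.names = FALSE)
  write.csv(as.data.frame(summary), file.path(out_dir, "summary.csv"),
            row.names = FALSE)
  write.csv(scatter, file.path(out_dir, "scatter.csv"), row.names = FALSE)
  write_config(config, file.path(out_dir, "run_config.json"))
  .np_log(logfile, "analyzed %d/%d trial(s); outputs in %s",
          nrow(results), length(ids), out_dir)
  invisible(list(results = results, summary = summary, scatter = scatter,
                 skipped = skipped))
}

#' Command-line entry point
#'
#' Dispatches \code{synth}, \code{analyze} and \code{report} subcommands; see
#' \code{inst/cli/needleplace} for the Rscript wrapper. Example:
#' \preformatted{
#'   needleplace synth   --out cohort/ --n 40 --seed 7 --lateral 3 --depth 4
#'   needleplace analyze --trials cohort/ --out results/ --spacing 0.05
#'   needleplace report  --results results/
#' }
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
needleplace_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: needleplace <synth|analyze|report> [options]"
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  status <- tryCatch({
    switch(cmd,
      synth = {
        opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
          optparse::make_option("--out", type = "character"),
          optparse::make_option("--n", type = "integer", default = 40L),
          optparse::make_option("--seed", type = "integer", default = 1L),
          optparse::make_option("--lateral", type = "double", default = 0),
          optparse::make_option("--depth", type = "double", default = 0),
          optparse::make_option("--noise", type = "double", default = 0),
          optparse::make_option("--config", type = "character", default = NULL)
        )), args = rest)
        if (is.null(opts$out)) .np_stopf("synth: --out is required")
        cfg <- synth_config(true_lateral_mm = opts$lateral,
                            true_depth_mm = opts$depth,
                            surface_noise_sd_mm = opts$noise,
                            seed = opts$seed)
        run_synth(cfg, opts$n, opts$out, seed = opts$seed)
        0L
      },
      analyze = {
        opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
          optparse::make_option("--trials", type = "character"),
          optparse::make_option("--out", type = "character"),
          optparse::make_option("--config", type = "character", default = NULL),
          optparse::make_option("--spacing", type = "double", default = NA)
        )), args = rest)
        if (is.null(opts$trials) || is.null(opts$out))
          .np_stopf("analyze: --trials and --out are required")
        cfg <- if (!is.null(opts$config)) read_config(opts$config) else run_config()
        if (!is.na(opts$spacing)) cfg$spacing_mm <- opts$spacing
        run_analysis(opts$trials, opts$out, cfg)
        0L
      },
      report = {
        opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
          optparse::make_option("--results", type = "character")
        )), args = rest)
        if (is.null(opts$results)) .np_stopf("report: --results is required")
        f <- file.path(opts$results, "summary.csv")
        if (!file.exists(f)) .np_stopf("no summary.csv in %s", opts$results)
        s <- read.csv(f, stringsAsFactors = FALSE)
        class(s) <- c("cohort_summary", class(s))
        print(s)
        0L
      },
      { message(usage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
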