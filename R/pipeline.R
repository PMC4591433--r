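# End-to-end orchestration: transient removal -> alignment -> grouping ->
# group-aggregated nonlinearity testing -> lag/dimension estimation ->
# delay embedding.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with the defaults used
#' throughout: drop a 0.5 s transient, 100 IAAFT surrogates per trial with
#' the CV-score threshold 1.96, first-trial reference, average-linkage
#' dendrogram cut into 5 groups, AMI-first lag policy, and FNN with
#' `f = 10`, a 100-sample Theiler window, dimensions up to 5 and a 1%
#' selection threshold.
#'
#' @param transient Seconds dropped from the start of each trial.
#' @param n_surrogates Surrogates per trial for the nonlinearity test.
#' @param surrogate_method `"iaaft"`, `"ft"` or `"aaft"`.
#' @param gamma_threshold CV-score rejection threshold.
#' @param timerev_delay Delay of the time-reversal statistic, samples.
#' @param reference Alignment reference policy (`"first"`, `"medoid"`, or a
#'   trial id).
#' @param linkage Dendrogram linkage.
#' @param k_groups Number of dendrogram groups (used when `cutoff` is
#'   `NULL`).
#' @param cutoff Optional height cutoff overriding `k_groups`.
#' @param max_lag Largest lag scanned; default `NULL` means half the
#'   steady-trial length.
#' @param ami_bins AMI histogram bins.
#' @param f_ratio,theiler,d_max,fnn_threshold FNN settings.
#' @param fnn_decimate Decimation factor for FNN on long trials.
#' @param seed Master RNG seed; every stochastic stage derives its seed
#'   from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(transient = 0.5, n_surrogates = 100,
                            surrogate_method = "iaaft",
                            gamma_threshold = 1.96, timerev_delay = 1,
                            reference = "first", linkage = "average",
                            k_groups = 5, cutoff = NULL, max_lag = NULL,
                            ami_bins = 16, f_ratio = 10, theiler = 100,
                            d_max = 5, fnn_threshold = 0.01,
                            fnn_decimate = 1, seed = 1) {
  cfg <- list(transient = transient, n_surrogates = as.integer(n_surrogates),
              surrogate_method = surrogate_method,
              gamma_threshold = gamma_threshold,
              timerev_delay = as.integer(timerev_delay),
              reference = reference, linkage = linkage,
              k_groups = if (is.null(cutoff)) as.integer(k_groups) else NULL,
              cutoff = cutoff, max_lag = max_lag,
              ami_bins = as.integer(ami_bins), f_ratio = f_ratio,
              theiler = as.integer(theiler), d_max = as.integer(d_max),
              fnn_threshold = fnn_threshold,
              fnn_decimate = as.integer(fnn_decimate),
              seed = as.integer(seed))
  if (cfg$transient < 0) stop("`transient` must be >= 0")
  if (cfg$n_surrogates < 1) stop("`n_surrogates` must be >= 1")
  if (cfg$gamma_threshold <= 0) stop("`gamma_threshold` must be > 0")
  if (cfg$f_ratio <= 0) stop("`f_ratio` must be > 0")
  if (cfg$fnn_threshold <= 0) stop("`fnn_threshold` must be > 0")
  if (!is.null(cfg$cutoff) && cfg$cutoff <= 0) stop("`cutoff` must be > 0")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' YAML or JSON, chosen by the file extension; the round trip is lossless.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param config A [pipeline_config()] (for writing).
#' @return `read_config()` returns a [pipeline_config()].
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: .", ext)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(lst, path)
  else if (ext == "json")
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported config format: .", ext)
  invisible(path)
}

#' Number of pairwise trial comparisons avoided by grouping
#'
#' Comparing every reconstructed trajectory against every other (including
#' itself) costs `N (N + 1) / 2` comparisons; grouping the trials first
#' replaces this with within-group checks only.
#'
#' @param n_trials Number of trials `N`.
#' @return `N (N + 1) / 2`.
#' @export
pair_comparison_budget <- function(n_trials) {
  n <- as.numeric(n_trials)
  if (any(n < 1)) stop("`n_trials` must be >= 1")
  n * (n + 1) / 2
}

#' Run the full analysis pipeline
#'
#' Executes, in order: trial loading, transient removal, phase-resetting
#' correction by circular shifting against the reference, dendrogram
#' grouping, group-aggregated surrogate nonlinearity testing
#' (time-reversal asymmetry, CV score), per-trial and per-group lag
#' estimation, per-group FNN embedding-dimension estimation on the group
#' average, and delay embedding of the group averages. Alignment must
#' precede grouping, and grouping precedes embedding: averaging or
#' comparing trials without correcting the stimulus-induced phase shift
#' mixes incompatible phases and destroys the waveform structure.
#'
#' @param manifest Path to an ensemble manifest CSV (see
#'   [read_ensemble()]), or an [lfp_ensemble()] directly.
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory; when given, writes
#'   `report.json`, `per_trial.csv`, `per_group.csv`, aligned trial files,
#'   and one trajectory CSV per group.
#' @param dt Sampling interval override for manifests without a `dt`
#'   column.
#' @return List of class `pipeline_report` with `per_trial` and
#'   `per_group` data frames, the `alignment`, `dendrogram`, `assignment`
#'   and `group_averages` objects, per-group `trajectories`, and
#'   `provenance` (config, seed, package version).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         outdir = NULL, dt = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ens <- if (inherits(manifest, "lfp_ensemble")) manifest
         else read_ensemble(manifest, dt = dt)
  if (length(ens$trials) < 2L) stop("pipeline needs at least 2 trials")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # 1. transient removal
  steady <- stage("transient_removal",
    if (config$transient > 0)
      ensemble_map(ens, drop_transient, t_cut = config$transient) else ens)
  n_steady <- length(steady$trials[[1]]$values)
  max_lag <- if (is.null(config$max_lag)) floor(n_steady / 2)
             else min(config$max_lag, n_steady - 1L)

  # 2. phase-resetting correction
  alignment <- stage("alignment",
    align_ensemble(steady, reference = config$reference))
  aligned <- alignment$ensemble

  # 3. dendrogram grouping
  dend <- stage("grouping",
    build_dendrogram(pairwise_distances(aligned),
                     linkage = config$linkage))
  assignment <- if (!is.null(config$cutoff))
    cut_dendrogram(dend, cutoff = config$cutoff)
  else
    cut_dendrogram(dend, k = config$k_groups)

  # 4. per-trial nonlinearity statistics (seeded per trial for
  #    reproducibility regardless of evaluation order)
  n_tr <- length(aligned$trials)
  tests <- lapply(seq_len(n_tr), function(i) {
    stage(paste0("nonlinearity[", aligned$trial_ids[i], "]"),
      surrogate_test(aligned$trials[[i]], n = config$n_surrogates,
                     method = config$surrogate_method,
                     delay = config$timerev_delay,
                     threshold = config$gamma_threshold,
                     seed = config$seed + i))
  })
  lambda0 <- vapply(tests, `[[`, numeric(1), "lambda0")
  gcv <- vapply(tests, `[[`, numeric(1), "gamma_cv")

  # 5. per-trial lags
  trial_lags <- vapply(seq_len(n_tr), function(i) {
    le <- tryCatch(estimate_lag(aligned$trials[[i]], max_lag = max_lag,
                                n_bins = config$ami_bins),
                   error = function(e) NULL)
    if (is.null(le)) NA_integer_ else le$chosen_lag
  }, integer(1))

  per_trial <- data.frame(alignment$result,
                          group = assignment$labels,
                          lambda0 = lambda0, gamma_cv = gcv,
                          lag = trial_lags, stringsAsFactors = FALSE)

  # 6. group-level statistics, lags, embedding dimension, trajectories
  averages <- group_average(aligned, assignment)
  gg <- group_gamma(gcv, assignment$labels,
                    threshold = config$gamma_threshold)
  groups <- gg$group
  grp_rows <- lapply(seq_along(groups), function(j) {
    avg <- averages[[j]]
    le <- tryCatch(estimate_lag(avg, max_lag = max_lag,
                                n_bins = config$ami_bins),
                   error = function(e) NULL)
    lag <- if (is.null(le)) NA_integer_ else le$chosen_lag
    dE <- NA_integer_
    if (!is.na(lag)) {
      fc <- tryCatch(
        fnn_fraction(avg, lag = lag, dims = seq_len(config$d_max),
                     f_ratio = config$f_ratio, theiler = config$theiler,
                     threshold = config$fnn_threshold,
                     decimate = config$fnn_decimate),
        error = function(e) NULL)
      if (!is.null(fc)) dE <- fc$d_E
    }
    data.frame(group = groups[j], n_trials = gg$n_trials[j],
               mean_gamma = gg$mean_gamma[j], reject = gg$reject[j],
               acf_first_zero = if (is.null(le)) NA_integer_
                                else le$acf_first_zero,
               ami_first_min = if (is.null(le)) NA_integer_
                               else le$ami_first_min,
               lag = lag, d_E = dE)
  })
  per_group <- do.call(rbind, grp_rows)

  trajectories <- lapply(seq_along(groups), function(j) {
    lag <- per_group$lag[j]
    dE <- per_group$d_E[j]
    if (is.na(lag) || is.na(dE)) return(NULL)
    embed_delay(averages[[j]], lag = lag, dim = dE,
                source_id = names(averages)[j])
  })
  names(trajectories) <- names(averages)

  report <- structure(
    list(per_trial = per_trial, per_group = per_group,
         alignment = alignment, dendrogram = dend,
         assignment = assignment, group_averages = averages,
         trajectories = trajectories,
         provenance = list(seed = config$seed, config = unclass(config),
                           package_version =
                             as.character(packageVersion("lfpattractor")))),
    class = "pipeline_report")

  if (!is.null(outdir)) write_pipeline_outputs(report, aligned, outdir)
  report
}

write_pipeline_outputs <- function(report, aligned, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$per_trial, file.path(outdir, "per_trial.csv"),
            row.names = FALSE)
  write.csv(report$per_group, file.path(outdir, "per_group.csv"),
            row.names = FALSE)
  write.csv(report$dendrogram$merges, file.path(outdir, "merge_tree.csv"),
            row.names = FALSE)
  write_ensemble(aligned, file.path(outdir, "aligned"))
  for (nm in names(report$trajectories)) {
    tr <- report$trajectories[[nm]]
    if (!is.null(tr))
      write.csv(as.data.frame(unclass(tr)),
                file.path(outdir, paste0("trajectory_", nm, ".csv")),
                row.names = FALSE)
  }
  json <- list(per_trial = report$per_trial, per_group = report$per_group,
               provenance = report$provenance)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d trials in %d groups\n",
              nrow(x$per_trial), nrow(x$per_group)))
  print(x$per_group)
  invisible(x)
}
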