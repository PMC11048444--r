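#' Experiment presets
#'
#' Named configurations for the three benchmark hierarchies (each 100
#' subjects, 1024 voxels, 300 time points, TR 2 s; subject PCA C = 295,
#' group PCA K = 300, SET cutoff gamma = 0.4, FWE 0.001):
#' \describe{
#'   \item{5L2D}{five levels, two-way branching, equal blocks (62 components).}
#'   \item{3L3D}{three levels, three-way branching, equal blocks (39).}
#'   \item{3L3Ddirich}{as 3L3D with block sizes drawn Dirichlet(3, 3, 3).}
#'   \item{small}{a light three-level binary hierarchy (128 voxels, 8
#'     subjects) for quick runs.}
#' }
#'
#' @param name preset name.
#' @param ... overrides for any configuration field (e.g. `n_subjects`).
#' @returns A configuration list for [run_experiment()].
#' @export
hpca_preset <- function(name = c("5L2D", "3L3D", "3L3Ddirich", "small"), ...) {
  name <- match.arg(name)
  cfg <- switch(name,
    "5L2D" = list(spec = hierarchy_spec(5, 2, 1024),
                  n_subjects = 100, n_timepoints = 300, tr = 2,
                  n_subject_pcs = 295, n_group_pcs = 300),
    "3L3D" = list(spec = hierarchy_spec(3, 3, 1024),
                  n_subjects = 100, n_timepoints = 300, tr = 2,
                  n_subject_pcs = 295, n_group_pcs = 300),
    "3L3Ddirich" = list(spec = hierarchy_spec(3, 3, 1024,
                                              block_mode = "dirichlet",
                                              dirichlet_alpha = c(3, 3, 3)),
                        n_subjects = 100, n_timepoints = 300, tr = 2,
                        n_subject_pcs = 295, n_group_pcs = 300),
    "small" = list(spec = hierarchy_spec(3, 2, 128),
                   n_subjects = 8, n_timepoints = 120, tr = 2,
                   n_subject_pcs = 60, n_group_pcs = 64))
  cfg$name <- name
  cfg$gamma <- 0.4
  cfg$alpha_fwe <- 0.001
  cfg$orthogonalize <- TRUE
  cfg$reconstruct <- TRUE
  cfg$run_ica <- FALSE
  cfg$seed <- 1L
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run a full hPCA experiment
#'
#' Executes the whole pipeline: simulate the study, compress it with
#' two-stage PCA, fit the treelet hierarchy, filter levels (SET +
#' correlation test under Bonferroni FWE), optionally back-reconstruct all
#' significant levels and evaluate accuracy against the simulated ground
#' truth (and against a FastICA baseline when `run_ica = TRUE`). When
#' `out_dir` is given, writes a plain-text run directory: `config.json`,
#' `summary.json`, `level_report.csv`, `dendrogram_merges.csv` and (with
#' \pkg{ape} installed) `dendrogram.newick`.
#'
#' @param config configuration list from [hpca_preset()] (or a hand-built
#'   list with the same fields).
#' @param out_dir optional output directory (created if missing).
#' @param verbose print stage progress and timings?
#' @returns An object of class `"hpca_experiment"` with elements `study`,
#'   `compression`, `tree`, `filter`, `levels` (reconstructed maps),
#'   `matches`, `ica`, `summary` (machine-readable list) and `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) {
    if (verbose)
      message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0),
              sprintf(fmt, ...))
  }
  stage <- function(label, expr) {
    say("%s ...", label)
    tryCatch(expr, error = function(e)
      stop_(sprintf("stage '%s' failed: %s", label, conditionMessage(e))))
  }

  set.seed(check_count(config$seed %||% 1L, "seed", 0L))
  study <- stage("simulate", simulate_study(
    config$spec, n_subjects = config$n_subjects,
    n_timepoints = config$n_timepoints, tr = config$tr))
  compression <- stage("compress", compress_study(
    study, n_subject_pcs = config$n_subject_pcs,
    n_group_pcs = config$n_group_pcs))
  tree <- stage("treelet", hpca(compression$x))
  filt <- stage("filter", filter_levels(tree, gamma = config$gamma,
                                        alpha_fwe = config$alpha_fwe))
  say("base level %d (%d active variables), %d significant, %d unrelated",
      filt$base_level, filt$n_active, length(filt$significant_levels),
      length(filt$unrelated_levels))

  levels_out <- NULL
  matches <- NULL
  if (isTRUE(config$reconstruct)) {
    # the analysis set: every base-level basis variable (summaries of the
    # redundant prefix) plus every significant level above the base
    ids <- c(active_variables(tree, filt$base_level),
             tree$n_leaves + filt$significant_levels)
    levels_out <- stage("reconstruct", {
      lapply(ids, function(id)
        reconstruct_variable(tree, id, compression, study,
                             base_level = filt$base_level,
                             orthogonalize = isTRUE(config$orthogonalize)))
    })
    names(levels_out) <- ids
    matches <- stage("evaluate",
                     evaluate_levels(study, ids, levels_out, tree, compression))
  }
  ica <- NULL
  if (isTRUE(config$run_ica)) {
    # the ICA branch follows its own convention: the group PCA retains
    # exactly the ICA model order (the true component count)
    n_true <- nrow(study$sources$blocks)
    ica_compression <- stage("ica compression", compress_study(
      study, n_subject_pcs = config$n_subject_pcs, n_group_pcs = n_true))
    ica <- stage("ica baseline", run_ica_baseline(
      ica_compression, n_components = n_true, seed = config$seed))
    if (!is.null(matches)) {
      # subject-specific ICA maps and time series, matched per subject like
      # the hPCA reconstructions
      ica_rows <- stage("evaluate ica", rbind(
        match_table(study, ica_subject_maps(ica, ica_compression, study),
                    "spatial", method = "ica"),
        match_table(study, ica$subject_timeseries, "temporal", method = "ica")))
      matches <- rbind(matches, ica_rows)
    }
  }

  summary_list <- list(
    name = config$name %||% "custom",
    seed = config$seed,
    n_true_components = nrow(study$sources$blocks),
    n_levels = tree$n_levels,
    base_level = filt$base_level,
    n_active = filt$n_active,
    significant_levels = filt$significant_levels,
    unrelated_levels = filt$unrelated_levels,
    final_merge_r = tree$r[tree$n_levels])

  out <- structure(
    list(study = study, compression = compression, tree = tree,
         filter = filt, levels = levels_out, matches = matches, ica = ica,
         summary = summary_list, config = config),
    class = "hpca_experiment")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_json <- config
    cfg_json$spec <- unclass(config$spec)
    jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_filter_report(filt, file.path(out_dir, "level_report.csv"))
    export_dendrogram(tree, file.path(out_dir, "dendrogram_merges.csv"),
                      format = "merge")
    if (requireNamespace("ape", quietly = TRUE))
      export_dendrogram(tree, file.path(out_dir, "dendrogram.newick"),
                        format = "newick")
    if (!is.null(matches))
      utils::write.csv(matches, file.path(out_dir, "match_table.csv"),
                       row.names = FALSE)
    say("outputs written to %s", out_dir)
  }
  say("done")
  out
}

# accuracy of the reconstructed analysis set against per-subject truth,
# using the reconstruction convention of the run (orthogonalized by
# default) for both spatial maps and time series
evaluate_levels <- function(study, ids, levels_out, tree, compression) {
  if (!length(levels_out)) return(NULL)
  est_maps <- lapply(seq_len(study$n_subjects), function(i)
    do.call(rbind, lapply(levels_out, function(lm) lm$subject_maps[i, ])))
  est_ts <- lapply(seq_len(study$n_subjects), function(i)
    do.call(rbind, lapply(levels_out, function(lm) lm$subject_timeseries[i, ])))
  rbind(match_table(study, est_maps, "spatial", method = "hpca"),
        match_table(study, est_ts, "temporal", method = "hpca"))
}

#' @export
print.hpca_experiment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("hPCA experiment '%s' (seed %s)\n", s$name, s$seed))
  cat(sprintf("  %d true components; tree of %d levels\n",
              s$n_true_components, s$n_levels))
  cat(sprintf("  base level %d -> %d active variables\n",
              s$base_level, s$n_active))
  cat(sprintf("  significant: %s; unrelated: %s\n",
              range_label(s$significant_levels), range_label(s$unrelated_levels)))
  invisible(x)
}
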