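#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking at
#' `peak` seconds minus an undershoot peaking at `undershoot` seconds scaled
#' by `ratio`. Gamma shapes are chosen so the density modes sit at the
#' requested times (shape = peak/dispersion + 1, rate = 1/dispersion).
#'
#' @param t time in seconds (vector).
#' @param peak time-to-peak of the positive lobe, seconds.
#' @param undershoot time-to-peak of the undershoot lobe, seconds.
#' @param ratio undershoot amplitude relative to the peak.
#' @param dispersion gamma dispersion (scale) in seconds.
#' @returns HRF values at `t`.
#' @examples
#' h <- hrf_double_gamma(seq(0, 30, 0.5))
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6,
                             dispersion = 1) {
  stats::dgamma(t, shape = peak / dispersion + 1, rate = 1 / dispersion) -
    ratio * stats::dgamma(t, shape = undershoot / dispersion + 1,
                          rate = 1 / dispersion)
}

# one event train -> normalized BOLD-like time course
events_to_bold <- function(events, kernel) {
  n <- length(events)
  s <- stats::convolve(events, rev(kernel), type = "open")[seq_len(n)]
  rng <- diff(range(s))
  if (rng == 0) return(NULL)  # degenerate: caller decides
  s <- s - mean(s)
  s / rng
}

#' Simulate component neural-event time courses
#'
#' Each component gets an independent binary event train drawn Bernoulli(0.2)
#' per TR, convolved with a double-gamma haemodynamic response sampled at the
#' TR, then normalized to mean 0 and peak-to-peak range 1. A component whose
#' event train produces a constant (zero-range) signal is resampled once;
#' a second degenerate draw is an error.
#'
#' @param n_components number of component time courses.
#' @param n_timepoints number of time points (TRs).
#' @param tr repetition time in seconds.
#' @param event_prob per-TR event probability.
#' @param seed optional integer seed.
#' @param hrf_kernel optional HRF kernel sampled at the TR; defaults to
#'   [hrf_double_gamma()] over 0-32 s.
#' @returns `n_components` x `n_timepoints` matrix; the event trains are
#'   attached as the integer attribute `"events"`.
#' @examples
#' r <- simulate_component_timeseries(4, 100, tr = 2, seed = 1)
#' range(rowMeans(r))        # ~0
#' apply(r, 1, function(x) diff(range(x)))  # all 1
#' @export
simulate_component_timeseries <- function(n_components, n_timepoints, tr = 2,
                                          event_prob = 0.2, seed = NULL,
                                          hrf_kernel = NULL) {
  n_components <- check_count(n_components, "n_components", 1L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", 2L)
  tr <- check_number(tr, "tr", 0, open_lower = TRUE)
  event_prob <- check_number(event_prob, "event_prob", 0, 1,
                             open_lower = TRUE, open_upper = TRUE)
  if (!is.null(seed)) set.seed(check_count(seed, "seed", 0L))
  if (is.null(hrf_kernel)) hrf_kernel <- hrf_double_gamma(seq(0, 32, by = tr))
  out <- matrix(0, n_components, n_timepoints)
  ev <- matrix(0L, n_components, n_timepoints)
  for (p in seq_len(n_components)) {
    for (attempt in 1:2) {
      e <- stats::rbinom(n_timepoints, 1L, event_prob)
      s <- events_to_bold(e, hrf_kernel)
      if (!is.null(s)) break
      if (attempt == 2L)
        stop_(sprintf("component %d: degenerate (zero-range) time course after resampling", p))
    }
    out[p, ] <- s
    ev[p, ] <- e
  }
  attr(out, "events") <- ev
  out
}

#' Simulate one subject's voxel-by-time dataset
#'
#' Implements the linear mixture model `Znf = S D R`: subject spatial maps
#' `S` are the group maps plus i.i.d. Gaussian map noise, `D` scales each
#' component by a random amplitude, and `R` holds freshly drawn component
#' time courses (each subject has unique dynamics). Rician scanner noise
#' `sqrt(e1^2 + e2^2)` with `e1, e2 ~ N(0, sigma_n^2)` is then added to every
#' voxel and time point, where `sigma_n = sigma_s / CNR`, `sigma_s` is the
#' mean voxelwise temporal SD of the noise-free data, and the
#' contrast-to-noise ratio CNR is drawn uniformly per subject.
#'
#' @param sources ground-truth sources from [build_hierarchy_maps()].
#' @param n_timepoints number of time points.
#' @param tr repetition time, seconds.
#' @param seed optional integer seed.
#' @param cnr contrast-to-noise ratio; `NULL` (default) draws
#'   `U(cnr_range[1], cnr_range[2])`.
#' @param cnr_range range of the uniform CNR law.
#' @param map_noise_sd SD of the subject map noise added to the group weights.
#' @param amp_mean,amp_sd mean and SD of the Gaussian component amplitudes.
#' @param subject_id integer identifier stored with the dataset.
#' @param keep_noise_free keep the noise-free matrix `Znf` in the result?
#' @param keep_truth keep the subject's true maps/time courses/amplitudes?
#' @returns An object of class `"hpca_subject"`: list with `data` (V x N),
#'   `cnr`, `sigma_s`, `sigma_n`, `tr`, `subject_id`, optionally `noise_free`,
#'   and (if `keep_truth`) `truth = list(maps, timeseries, amplitudes)`.
#' @export
simulate_subject <- function(sources, n_timepoints = 300, tr = 2, seed = NULL,
                             cnr = NULL, cnr_range = c(0.65, 2),
                             map_noise_sd = sqrt(0.005),
                             amp_mean = 1, amp_sd = 0.3,
                             subject_id = 1L, keep_noise_free = FALSE,
                             keep_truth = TRUE) {
  if (!inherits(sources, "hpca_sources"))
    stop_("`sources` must come from build_hierarchy_maps()")
  if (!is.null(seed)) set.seed(check_count(seed, "seed", 0L))
  w <- sources$weights
  v <- nrow(w)
  p <- ncol(w)
  maps <- w + matrix(stats::rnorm(v * p, 0, map_noise_sd), v, p)
  amps <- stats::rnorm(p, amp_mean, amp_sd)
  r <- simulate_component_timeseries(p, n_timepoints, tr)
  znf <- maps %*% (amps * r)
  sigma_s <- mean(sqrt(rowMeans((znf - rowMeans(znf))^2)))
  if (is.null(cnr)) cnr <- stats::runif(1, cnr_range[1], cnr_range[2])
  cnr <- check_number(cnr, "cnr", 0, open_lower = TRUE)
  sigma_n <- sigma_s / cnr
  e1 <- matrix(stats::rnorm(v * n_timepoints, 0, sigma_n), v, n_timepoints)
  e2 <- matrix(stats::rnorm(v * n_timepoints, 0, sigma_n), v, n_timepoints)
  z <- znf + sqrt(e1^2 + e2^2)
  if (!all(is.finite(z))) {
    bad <- which(!is.finite(z), arr.ind = TRUE)
    stop_(sprintf("non-finite simulated values, first at voxel %d, timepoint %d",
                  bad[1, 1], bad[1, 2]))
  }
  out <- list(data = z, cnr = cnr, sigma_s = sigma_s, sigma_n = sigma_n,
              tr = tr, subject_id = as.integer(subject_id))
  if (keep_noise_free) out$noise_free <- znf
  if (keep_truth)
    out$truth <- list(maps = maps, timeseries = r, amplitudes = amps)
  structure(out, class = "hpca_subject")
}

#' @export
print.hpca_subject <- function(x, ...) {
  cat(sprintf("Simulated subject %d: %d voxels x %d timepoints (TR %gs), CNR %.2f\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr, x$cnr))
  invisible(x)
}

#' Simulate a multi-subject hierarchical fMRI-like study
#'
#' Draws the group hierarchy maps once, then simulates `n_subjects`
#' independent subjects with [simulate_subject()] (subject-specific map
#' noise, amplitudes, time courses, CNR and Rician noise).
#'
#' @param spec an [hierarchy_spec()] object.
#' @param n_subjects number of subjects.
#' @param n_timepoints time points per subject.
#' @param tr repetition time, seconds.
#' @param seed integer master seed; fully determines the study.
#' @param ... further arguments passed to [simulate_subject()].
#' @returns An object of class `"hpca_study"`: list with `subjects` (list of
#'   `"hpca_subject"`), `sources`, and the simulation parameters.
#' @examples
#' st <- simulate_study(hierarchy_spec(2, 2, 32), n_subjects = 3,
#'                      n_timepoints = 60, seed = 1)
#' @export
simulate_study <- function(spec, n_subjects = 100, n_timepoints = 300, tr = 2,
                           seed = NULL, ...) {
  n_subjects <- check_count(n_subjects, "n_subjects", 1L)
  if (!is.null(seed)) set.seed(check_count(seed, "seed", 0L))
  sources <- build_hierarchy_maps(spec)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects))
    subjects[[i]] <- simulate_subject(sources, n_timepoints = n_timepoints,
                                      tr = tr, subject_id = i, ...)
  structure(list(subjects = subjects, sources = sources, spec = spec,
                 n_subjects = n_subjects, n_timepoints = n_timepoints,
                 tr = tr, seed = seed),
            class = "hpca_study")
}

#' @export
print.hpca_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d subjects, %d voxels x %d timepoints (TR %gs)\n",
              x$n_subjects, x$spec$n_voxels, x$n_timepoints, x$tr))
  print(x$sources)
  invisible(x)
}

#' Group-averaged voxel correlation matrix
#'
#' Per-subject Pearson correlation matrices of the raw voxel time series,
#' averaged across subjects. For hierarchical simulations this displays the
#' nested-block structure of the ground truth.
#'
#' @param study an `"hpca_study"`, or a list of voxel-by-time matrices.
#' @returns Symmetric V x V matrix with unit diagonal.
#' @export
group_correlation <- function(study) {
  mats <- if (inherits(study, "hpca_study"))
    lapply(study$subjects, `[[`, "data")
  else if (inherits(study, "hpca_subject")) list(study$data)
  else if (is.list(study)) study
  else list(check_matrix(study, "study"))
  if (!length(mats)) stop_("no subjects supplied")
  v <- nrow(mats[[1]])
  acc <- matrix(0, v, v)
  for (i in seq_along(mats)) {
    z <- check_matrix(mats[[i]], sprintf("subject %d", i))
    if (nrow(z) != v) stop_("subjects differ in voxel count")
    sds <- apply(z, 1, stats::sd)
    if (any(sds == 0))
      stop_(sprintf("subject %d: zero-variance voxel %d has undefined correlations",
                    i, which(sds == 0)[1]))
    acc <- acc + stats::cor(t(z))
  }
  acc <- acc / length(mats)
  dimnames(acc) <- NULL
  acc
}
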