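#' Best-match accuracy of estimated components against ground truth
#'
#' For every true component vector, the estimate with the highest absolute
#' Pearson correlation is its (non-exclusive) best match: one estimate may
#' serve as best match for several true components, but each true component
#' has exactly one. Ties are broken by the lowest estimate index.
#'
#' @param true_set matrix of true component vectors in rows (spatial maps
#'   over voxels, or time series over time points).
#' @param est_set matrix of estimated vectors in rows, same column
#'   dimension.
#' @returns Data frame with one row per true component: `true_component`,
#'   `best_match` (estimate index), `r_abs`.
#' @export
best_match <- function(true_set, est_set) {
  true_set <- check_matrix(true_set, "true_set")
  est_set <- check_matrix(est_set, "est_set")
  if (ncol(true_set) != ncol(est_set))
    stop_("true and estimated vectors differ in dimension")
  drop_zero <- function(m, lab) {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("excluding %d zero-variance %s vector(s)",
                      sum(sds == 0), lab), call. = FALSE)
    }
    sds > 0
  }
  tkeep <- drop_zero(true_set, "true")
  ekeep <- drop_zero(est_set, "estimated")
  if (!any(tkeep) || !any(ekeep)) stop_("no usable vectors left to match")
  cc <- abs(stats::cor(t(true_set[tkeep, , drop = FALSE]),
                       t(est_set[ekeep, , drop = FALSE])))
  eidx <- which(ekeep)
  best <- apply(cc, 1L, which.max)           # first max = lowest index
  data.frame(true_component = which(tkeep),
             best_match = eidx[best],
             r_abs = cc[cbind(seq_len(nrow(cc)), best)])
}

#' Build a per-subject match table for a study
#'
#' Applies [best_match()] subject by subject in the spatial or temporal
#' domain and stacks the results into a long-format table suitable for
#' paired method comparisons and violin-style accuracy displays.
#'
#' @param study an `"hpca_study"` with per-subject truth.
#' @param estimates either a matrix shared across subjects (components in
#'   rows) or a list with one matrix per subject.
#' @param domain `"spatial"` (vectors over voxels) or `"temporal"` (vectors
#'   over time points).
#' @param method label stored in the table.
#' @returns Data frame: `subject`, `true_component`, `best_match`, `r_abs`,
#'   `domain`, `method`.
#' @export
match_table <- function(study, estimates, domain = c("spatial", "temporal"),
                        method = "hpca") {
  stopifnot(inherits(study, "hpca_study"))
  domain <- match.arg(domain)
  rows <- lapply(seq_len(study$n_subjects), function(i) {
    subj <- study$subjects[[i]]
    if (is.null(subj$truth))
      stop_("study subjects carry no ground truth (simulate with keep_truth = TRUE)")
    truth <- if (domain == "spatial") t(subj$truth$maps) else subj$truth$timeseries
    est <- if (is.list(estimates)) estimates[[i]] else estimates
    bm <- best_match(truth, est)
    bm$subject <- i
    bm
  })
  out <- do.call(rbind, rows)
  out$domain <- domain
  out$method <- method
  out[, c("subject", "true_component", "best_match", "r_abs", "domain", "method")]
}

#' Paired comparison of two methods' accuracy tables
#'
#' Aligns two match tables on their (subject, true component) keys and runs
#' a paired t-test on the difference in absolute best-match correlations
#' (`a - b`).
#'
#' @param table_a,table_b match tables from [match_table()] or
#'   [best_match()] (the latter must share identical `true_component` keys;
#'   a `subject` column is added as 1 when absent).
#' @returns List with `mean_a`, `mean_b`, `mean_diff`, `t`, `df`, `p_value`,
#'   `n`, and `long` (stacked long-format table for plotting).
#' @export
compare_methods <- function(table_a, table_b) {
  norm_tab <- function(tb) {
    if (is.null(tb$subject)) tb$subject <- 1L
    tb
  }
  a <- norm_tab(table_a)
  b <- norm_tab(table_b)
  key_a <- paste(a$subject, a$true_component)
  key_b <- paste(b$subject, b$true_component)
  if (length(key_a) != length(key_b) || !setequal(key_a, key_b) ||
      anyDuplicated(key_a) || anyDuplicated(key_b))
    stop_("tables do not share identical (subject, component) keys")
  b <- b[match(key_a, key_b), ]
  d <- a$r_abs - b$r_abs
  if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    tt <- list(statistic = c(t = if (mean(d) == 0) 0 else Inf * sign(mean(d))),
               parameter = c(df = length(d) - 1),
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(a$r_abs, b$r_abs, paired = TRUE)
  }
  long <- rbind(a, b)
  list(mean_a = mean(a$r_abs), mean_b = mean(b$r_abs), mean_diff = mean(d),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n = length(d), long = long)
}
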