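#' Bonferroni-corrected per-test significance level
#'
#' @param alpha_fwe family-wise error rate in (0, 1).
#' @param n_tests number of tests.
#' @returns `alpha_fwe / n_tests`.
#' @examples
#' bonferroni_alpha(0.001, 2046) # ~4.9e-7
#' @export
bonferroni_alpha <- function(alpha_fwe, n_tests) {
  alpha_fwe <- check_number(alpha_fwe, "alpha_fwe", 0, 1,
                            open_lower = TRUE, open_upper = TRUE)
  n_tests <- check_count(n_tests, "n_tests", 1L)
  alpha_fwe / n_tests
}

#' Smallest Eigenvalue Test for a redundant merger
#'
#' Tests `H0: lambda2 >= gamma` against `lambda2 < gamma` for the trailing
#' eigenvalue of a level's local PCA. Rejection means the merged pair shared
#' nearly all its variance (a redundant merger): the leading component
#' summarizes both inputs and the difference carries only noise. The
#' asymptotic variance of an eigenvalue estimate, `2 lambda^2 / (K - 1)`,
#' gives the z-statistic `z = (lambda2 - gamma) / (lambda2 sqrt(2/(K-1)))`
#' with `p = Phi(z)`; equivalently H0 is rejected when
#' `lambda2 < gamma - z_alpha lambda2 sqrt(2/(K-1))`.
#'
#' @param lambda2 trailing eigenvalue (in `[0, 1]` on the correlation scale).
#' @param gamma eigenvalue cutoff (> 0); 0.4 for the simulated noise model.
#' @param K number of observations (compressed, concatenated time points).
#' @param alpha per-test significance level.
#' @returns List with `lambda2`, `gamma`, `K`, `z`, `p_value`, `reject_H0`,
#'   and `floored` (`TRUE` when the p-value underflowed below 1e-300 and is
#'   reported as 0).
#' @examples
#' set_test(0.15, gamma = 0.4, K = 300, alpha = bonferroni_alpha(0.001, 2046))
#' @export
set_test <- function(lambda2, gamma = 0.4, K, alpha = 0.05) {
  lambda2 <- check_number(lambda2, "lambda2", 0)
  gamma <- check_number(gamma, "gamma", 0, open_lower = TRUE)
  K <- check_count(K, "K", 3L)
  alpha <- check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  se <- lambda2 * sqrt(2 / (K - 1))
  z <- if (lambda2 == 0) -Inf else (lambda2 - gamma) / se
  p <- stats::pnorm(z)
  floored <- is.finite(z) && p < 1e-300
  if (floored) p <- 0
  list(lambda2 = lambda2, gamma = gamma, K = K, z = z, p_value = p,
       reject_H0 = p < alpha, floored = floored)
}

#' One-tailed correlation test for an unrelated merger
#'
#' Tests `H0: rho <= 0` against `rho > 0` for a level's merge similarity
#' using the t-approximation `t = sqrt(K - 2) r / sqrt(1 - r^2)` with
#' `K - 2` degrees of freedom (upper tail). Non-significance flags the level
#' as merging unrelated (uncorrelated or anticorrelated) variables.
#'
#' @param r merge similarity in `[-1, 1]`.
#' @param K number of observations.
#' @param alpha per-test significance level.
#' @returns List with `r`, `t_stat`, `df`, `p_value`, `significant`.
#' @examples
#' corr_test(0.5, K = 102, alpha = 0.05)
#' @export
corr_test <- function(r, K, alpha = 0.05) {
  r <- check_number(r, "r", -1, 1)
  K <- check_count(K, "K", 3L)
  alpha <- check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  df <- K - 2L
  if (abs(r) == 1) {
    t_stat <- sign(r) * Inf
    p <- if (r > 0) 0 else 1
  } else {
    t_stat <- sqrt(df) * r / sqrt(1 - r^2)
    p <- stats::pt(t_stat, df, lower.tail = FALSE)
  }
  list(r = r, t_stat = t_stat, df = df, p_value = p, significant = p < alpha)
}

# vectorized SET p-values for a whole tree
set_pvalues <- function(lambda2, gamma, K) {
  se <- lambda2 * sqrt(2 / (K - 1))
  z <- ifelse(lambda2 == 0, -Inf, (lambda2 - gamma) / se)
  p <- stats::pnorm(z)
  ifelse(is.finite(z) & p < 1e-300, 0, p)
}

corr_pvalues <- function(r, K) {
  df <- K - 2L
  ifelse(abs(r) == 1, ifelse(r > 0, 0, 1),
         stats::pt(sqrt(df) * r / sqrt(pmax(1 - r^2, 0)), df, lower.tail = FALSE))
}

#' Select the base level of an hPCA hierarchy
#'
#' Applies the Smallest Eigenvalue Test to every level and returns the last
#' level of the maximal contiguous prefix `1..l` of rejections. The active
#' variables at that level (`V - l` of them) summarize all earlier redundant
#' mergers and form the analysis basis. Isolated rejections beyond the
#' prefix do not move the base level.
#'
#' @param tree an `"hpca"` fit.
#' @param gamma SET eigenvalue cutoff.
#' @param alpha per-test significance level (already corrected for multiple
#'   comparisons; see [bonferroni_alpha()]).
#' @returns Integer base level; 0 (with a warning) when no level rejects.
#' @export
select_base_level <- function(tree, gamma = 0.4, alpha) {
  stopifnot(inherits(tree, "hpca"))
  p <- set_pvalues(tree$lambda2, gamma, tree$n_obs)
  rej <- p < alpha
  if (!rej[1]) {
    warning("no redundant prefix: base level 0 (all-variable basis)", call. = FALSE)
    return(0L)
  }
  acc <- which(!rej)
  if (!length(acc)) return(length(rej))
  acc[1] - 1L
}

#' Statistical filtering of hPCA levels
#'
#' Runs both parametric tests on every level of the hierarchy under
#' Bonferroni family-wise error control over `2 (V - 1)` tests (a Smallest
#' Eigenvalue Test and a correlation test per level). Levels in the
#' contiguous SET-rejection prefix are redundant mergers summarized by the
#' base level; above the base level, levels whose merge similarity is not
#' significantly positive are flagged unrelated; the remaining SET-accepted,
#' correlation-significant levels are the significant set for
#' back-reconstruction.
#'
#' @param tree an `"hpca"` fit.
#' @param gamma SET eigenvalue cutoff.
#' @param alpha_fwe family-wise error rate (Bonferroni-corrected internally).
#' @returns An object of class `"hpca_filter"`: list with `table` (per-level
#'   data frame: `level`, `r`, `lambda2`, `p_set`, `p_corr`, `set_reject`,
#'   `corr_significant`), `base_level`, `n_active` (variables at base),
#'   `redundant_levels`, `unrelated_levels`, `significant_levels`,
#'   `alpha_fwe`, `alpha_per_test`, `n_tests`, `gamma`, `K`.
#' @examples
#' x <- matrix(rnorm(6 * 50), 6, 50)
#' x <- rbind(x, x[1, ] + rnorm(50, 0, 0.01)) # one redundant pair
#' filter_levels(hpca(x), gamma = 0.4, alpha_fwe = 0.05)
#' @export
filter_levels <- function(tree, gamma = 0.4, alpha_fwe = 0.001) {
  stopifnot(inherits(tree, "hpca"))
  nlev <- tree$n_levels
  n_tests <- 2L * nlev
  alpha <- bonferroni_alpha(alpha_fwe, n_tests)
  p_set <- set_pvalues(tree$lambda2, gamma, tree$n_obs)
  p_corr <- corr_pvalues(tree$r, tree$n_obs)
  set_reject <- p_set < alpha
  corr_sig <- p_corr < alpha
  base <- if (set_reject[1]) (which(!set_reject) - 1L)[1] %||% nlev else 0L
  if (is.na(base)) base <- nlev
  lev <- seq_len(nlev)
  above <- lev > base
  unrelated <- lev[above & !corr_sig]
  significant <- lev[above & corr_sig & !set_reject]
  tab <- data.frame(level = lev, r = tree$r, lambda2 = tree$lambda2,
                    p_set = p_set, p_corr = p_corr,
                    set_reject = set_reject, corr_significant = corr_sig)
  structure(
    list(table = tab, base_level = base,
         n_active = tree$n_leaves - base,
         redundant_levels = if (base > 0) 1L:base else integer(0),
         unrelated_levels = unrelated, significant_levels = significant,
         alpha_fwe = alpha_fwe, alpha_per_test = alpha, n_tests = n_tests,
         gamma = gamma, K = tree$n_obs),
    class = "hpca_filter")
}

#' @export
print.hpca_filter <- function(x, ...) {
  cat(sprintf("hPCA level filtering (gamma = %g, FWE alpha = %g over %d tests)\n",
              x$gamma, x$alpha_fwe, x$n_tests))
  cat(sprintf("  base level %d: %d active variables summarize levels %s\n",
              x$base_level, x$n_active,
              if (x$base_level > 0) sprintf("1-%d", x$base_level) else "(none)"))
  cat(sprintf("  significant levels: %s\n", range_label(x$significant_levels)))
  cat(sprintf("  unrelated levels:   %s\n", range_label(x$unrelated_levels)))
  invisible(x)
}

range_label <- function(v) {
  if (!length(v)) return("(none)")
  if (length(v) > 8L)
    sprintf("%d levels in [%d, %d]", length(v), min(v), max(v))
  else paste(v, collapse = ", ")
}

#' Write the per-level filtering report to CSV
#'
#' @param filter an `"hpca_filter"` object.
#' @param file output path.
#' @export
write_filter_report <- function(filter, file) {
  stopifnot(inherits(filter, "hpca_filter"))
  utils::write.csv(filter$table, file, row.names = FALSE)
  invisible(file)
}
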