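# internal argument checks -----------------------------------------------

stop_ <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_(sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_(sprintf("`%s` = %g is outside its admissible range", name, x))
  as.numeric(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_(sprintf("`%s` must be a numeric matrix", name))
  x
}

# population z-score of a vector (SD with divisor n)
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop_("cannot z-score a constant vector")
  (x - m) / s
}

# standardize matrix rows to zero mean, unit L2 norm scaled so that
# tcrossprod() of the result is the Pearson correlation matrix of the rows
row_standardize <- function(x) {
  x <- x - rowMeans(x)
  n2 <- sqrt(rowSums(x^2))
  bad <- which(n2 == 0)
  if (length(bad))
    stop_("zero-variance row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  x / n2
}

# Moore-Penrose pseudo-inverse via SVD, warning on poor conditioning
pinv <- function(x, tol = NULL, cond_warn = 1e8) {
  s <- svd(x)
  if (is.null(tol)) tol <- max(dim(x)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  if (max(s$d) / min(s$d[keep]) > cond_warn)
    warning(sprintf("matrix is poorly conditioned (kappa > %g); using pseudo-inverse",
                    cond_warn), call. = FALSE)
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
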