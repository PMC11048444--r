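#' Spatial FastICA baseline on compressed group data
#'
#' Fixed-point FastICA (symmetric decorrelation, logcosh contrast) applied
#' to the voxel-by-K compressed matrix, treating voxels as samples: the
#' model is `X = S A` with independent spatial maps in the columns of `S`.
#' Several random restarts are run and the run with the highest average
#' component-wise agreement (mean absolute correlation of matched
#' components) with the other runs is kept, a light-weight stand-in for
#' full bootstrap reliability clustering. Subject time series are obtained
#' by back-projecting the mixing rows through the compression inverses
#' (`R_i = A pinv(G_i) t(F_i)`).
#'
#' @param x V x K compressed matrix, or an `"hpca_compression"` (whose `x`
#'   is used, and whose inverses provide subject time series).
#' @param n_components number of independent components (<= K).
#' @param restarts number of random restarts (15 by default, mirroring the
#'   common bootstrap-replication count used for ICA reliability selection).
#' @param max_iter,tol fixed-point iteration controls.
#' @param seed integer seed making the estimate reproducible.
#' @returns An object of class `"hpca_ica"`: list with `maps` (V x n,
#'   z-scored spatial components), `mixing` (n x K), `subject_timeseries`
#'   (list of n x N matrices when a compression model was supplied),
#'   `converged`, `iterations`, `restart_used`.
#' @export
run_ica_baseline <- function(x, n_components, restarts = 15L, max_iter = 500L,
                             tol = 1e-8, seed = NULL) {
  compression <- NULL
  if (inherits(x, "hpca_compression")) {
    compression <- x
    x <- x$x
  }
  x <- check_matrix(x, "x")
  n <- check_count(n_components, "n_components", 1L)
  restarts <- check_count(restarts, "restarts", 1L)
  if (n > ncol(x)) stop_("`n_components` exceeds the data dimension")
  if (!is.null(seed)) set.seed(check_count(seed, "seed", 0L))

  xc <- sweep(x, 2L, colMeans(x))
  v <- nrow(xc)
  sv <- svd(xc, nu = n, nv = 0)
  if (sv$d[n] <= sv$d[1] * 1e-12)
    stop_("data rank below `n_components`; cannot whiten")
  zw <- sv$u * sqrt(v - 1)                 # whitened: cov(zw) = I

  runs <- vector("list", restarts)
  for (rr in seq_len(restarts)) {
    w0 <- matrix(stats::rnorm(n * n), n, n)
    runs[[rr]] <- fastica_core(zw, w0, max_iter, tol)
  }
  best <- pick_consensus_run(runs, restarts)
  w <- runs[[best]]$w
  s <- zw %*% t(w)                          # V x n independent maps
  s <- apply(s, 2L, zscore_pop)
  # mixing s.t. xc ~ s %*% a  (s columns ~ unit variance)
  a <- crossprod(s, xc) / (v)               # n x K (population scaling)
  out <- list(maps = s, mixing = a, converged = runs[[best]]$converged,
              iterations = runs[[best]]$iters, restart_used = best)
  if (!is.null(compression)) {
    m <- compression$dims$M
    out$subject_timeseries <- lapply(seq_len(m), function(i)
      a %*% backprojector(compression, i))
  }
  structure(out, class = "hpca_ica")
}

# symmetric fixed-point iterations with logcosh nonlinearity
fastica_core <- function(zw, w, max_iter, tol) {
  v <- nrow(zw)
  sym_decorrelate <- function(w) {
    e <- eigen(tcrossprod(w), symmetric = TRUE)
    e$vectors %*% ((1 / sqrt(pmax(e$values, 1e-300))) * t(e$vectors)) %*% w
  }
  w <- sym_decorrelate(w)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    wx <- zw %*% t(w)                       # V x n projections
    g <- tanh(wx)
    gp <- colMeans(1 - g^2)
    w_new <- crossprod(g, zw) / v - gp * w
    w_new <- sym_decorrelate(w_new)
    delta <- 1 - abs(diag(w_new %*% t(w)))
    w <- w_new
    if (max(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  list(w = w, converged = converged, iters = it)
}

# score each run by mean best-match |r| of its components against all other
# runs; return the index of the most reproducible run
pick_consensus_run <- function(runs, restarts) {
  if (restarts == 1L) return(1L)
  score <- numeric(restarts)
  for (i in seq_len(restarts)) {
    sims <- vapply(seq_len(restarts)[-i], function(j) {
      cc <- abs(stats::cor(t(runs[[i]]$w), t(runs[[j]]$w)))
      mean(apply(cc, 1L, max))
    }, numeric(1))
    score[i] <- mean(sims)
  }
  which.max(score)
}

#' Subject-specific ICA spatial maps (GICA-style linear inversion)
#'
#' Projects each subject's compressed data onto the ICA source space:
#' `S_i = Z_i F_i G_i pinv(A)`, i.e. the subject's version of the group
#' decomposition `X = S A`. Maps are z-scored across voxels.
#'
#' @param ica an `"hpca_ica"` fit.
#' @param compression the `"hpca_compression"` the ICA was run on.
#' @param subjects an `"hpca_study"` or list of voxel-by-time matrices.
#' @returns List of n_components x V matrices (components in rows), one per
#'   subject.
#' @export
ica_subject_maps <- function(ica, compression, subjects) {
  stopifnot(inherits(ica, "hpca_ica"), inherits(compression, "hpca_compression"))
  mats <- if (inherits(subjects, "hpca_study"))
    lapply(subjects$subjects, `[[`, "data") else subjects
  if (length(mats) != compression$dims$M)
    stop_("subject count does not match the compression model")
  a_pinv <- pinv(ica$mixing)
  lapply(seq_along(mats), function(i) {
    zc <- mats[[i]] - rowMeans(mats[[i]])
    zc <- sweep(zc, 2L, colMeans(zc))
    xi <- (zc %*% compression$f[[i]]) %*% compression$gi[[i]]
    si <- xi %*% a_pinv
    t(apply(si, 2L, zscore_pop))
  })
}

#' @export
print.hpca_ica <- function(x, ...) {
  cat(sprintf("FastICA baseline: %d components, %s after %d iteration(s) (restart %d)\n",
              ncol(x$maps), if (x$converged) "converged" else "NOT converged",
              x$iterations, x$restart_used))
  invisible(x)
}
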