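#' Subject-level PCA reduction of a voxel-by-time matrix
#'
#' Centers the data (each voxel's temporal mean, then each time point's mean
#' across voxels — voxels are the statistical samples in spatial PCA) and
#' projects onto the top `n_keep` right singular vectors. The basis sign is
#' fixed so each column's largest-magnitude loading is positive, making runs
#' reproducible to the bit.
#'
#' @param z V x N voxel-by-time matrix.
#' @param n_keep number of components `C` to retain (`C <= min(V, N)`).
#' @returns List with `scores` (V x C, the reduced data `Y = Z F`), `basis`
#'   (N x C orthonormal `F`), `d` (singular values), `row_means`, `col_means`
#'   (the removed centerings).
#' @seealso [compress_study()] for the full two-stage pipeline.
#' @export
subject_pca <- function(z, n_keep) {
  z <- check_matrix(z, "z")
  n_keep <- check_count(n_keep, "n_keep", 1L)
  if (n_keep > min(dim(z)))
    stop_(sprintf("rank-deficient request: n_keep = %d exceeds attainable rank %d",
                  n_keep, min(dim(z))))
  row_means <- rowMeans(z)
  zc <- z - row_means
  col_means <- colMeans(zc)
  zc <- sweep(zc, 2L, col_means)
  sv <- svd(zc, nu = 0, nv = n_keep)
  f <- fix_signs(sv$v[, seq_len(n_keep), drop = FALSE])
  list(scores = zc %*% f, basis = f, d = sv$d[seq_len(n_keep)],
       row_means = row_means, col_means = col_means)
}

# deterministic sign convention: largest-|loading| entry of each column > 0
fix_signs <- function(b) {
  flip <- apply(b, 2L, function(col) col[which.max(abs(col))] < 0)
  b[, flip] <- -b[, flip, drop = FALSE]
  b
}

#' Group-level PCA of temporally concatenated subject scores
#'
#' Reduces the concatenated matrix `Y = [Y_1, ..., Y_M]` (V x C*M) to `K`
#' columns. Columns of `Y` inherit zero voxel-sums from the subject
#' centering, so the decomposition acts on the spatial covariance directly.
#' Computed from the eigendecomposition of `Y Y^T` when voxels are the
#' smaller dimension (deterministic; no randomized solver).
#'
#' @param y V x (C*M) concatenated score matrix.
#' @param n_keep number of group components `K` to retain.
#' @param n_subjects number of subjects `M`; when given, the returned basis
#'   is also partitioned into per-subject blocks `Gi`.
#' @returns List with `x` (V x K compressed data), `g` ((C*M) x K group
#'   basis), `gi` (list of M C x K blocks, when `n_subjects` is given),
#'   `d` (singular values).
#' @export
group_pca <- function(y, n_keep, n_subjects = NULL) {
  y <- check_matrix(y, "y")
  n_keep <- check_count(n_keep, "n_keep", 1L)
  if (n_keep > min(dim(y)))
    stop_(sprintf("rank-deficient request: n_keep = %d exceeds attainable rank %d",
                  n_keep, min(dim(y))))
  y <- sweep(y, 2L, colMeans(y))
  if (nrow(y) <= ncol(y)) {
    ei <- eigen(tcrossprod(y), symmetric = TRUE)
    d <- sqrt(pmax(ei$values[seq_len(n_keep)], 0))
    u <- fix_signs(ei$vectors[, seq_len(n_keep), drop = FALSE])
    pos <- d > max(d) * .Machine$double.eps * nrow(y)
    if (!all(pos))
      warning("retained components beyond numerical rank; trailing columns are null directions",
              call. = FALSE)
    g <- crossprod(y, u)
    g[, pos] <- sweep(g[, pos, drop = FALSE], 2L, d[pos], "/")
  } else {
    sv <- svd(y, nu = 0, nv = n_keep)
    g <- fix_signs(sv$v[, seq_len(n_keep), drop = FALSE])
    d <- sv$d[seq_len(n_keep)]
  }
  x <- y %*% g
  out <- list(x = x, g = g, d = d)
  if (!is.null(n_subjects)) {
    n_subjects <- check_count(n_subjects, "n_subjects", 1L)
    if (nrow(g) %% n_subjects != 0)
      stop_("rows of the group basis are not divisible into equal subject blocks")
    cc <- nrow(g) %/% n_subjects
    out$gi <- lapply(seq_len(n_subjects), function(i)
      g[((i - 1L) * cc + 1L):(i * cc), , drop = FALSE])
  }
  out
}

#' Two-stage PCA compression of a multi-subject study
#'
#' Applies [subject_pca()] to every subject (retaining `n_subject_pcs`
#' components), concatenates the reduced data over the temporal dimension,
#' and applies [group_pca()] (retaining `n_group_pcs`). The compressed
#' matrix `X = Y G` is the input to [hpca()]; the stored bases allow
#' subject-specific back-reconstruction via [backproject_timeseries()].
#'
#' @param study an `"hpca_study"` or list of voxel-by-time matrices.
#' @param n_subject_pcs subject-level components `C`.
#' @param n_group_pcs group-level components `K`.
#' @returns An object of class `"hpca_compression"`: list with `x` (V x K),
#'   `f` (list of N x C subject bases), `gi` (list of C x K group-basis
#'   blocks), `g`, `d`, `dims` (`V`, `N`, `C`, `K`, `M`).
#' @examples
#' st <- simulate_study(hierarchy_spec(2, 2, 32), n_subjects = 3,
#'                      n_timepoints = 60, seed = 1)
#' cm <- compress_study(st, n_subject_pcs = 20, n_group_pcs = 24)
#' dim(cm$x) # 32 x 24
#' @export
compress_study <- function(study, n_subject_pcs, n_group_pcs) {
  mats <- if (inherits(study, "hpca_study"))
    lapply(study$subjects, `[[`, "data") else study
  if (!is.list(mats) || !length(mats)) stop_("`study` must hold at least one subject")
  m <- length(mats)
  v <- nrow(mats[[1]])
  n <- ncol(mats[[1]])
  cc <- check_count(n_subject_pcs, "n_subject_pcs", 1L)
  y <- matrix(0, v, cc * m)
  f <- vector("list", m)
  for (i in seq_len(m)) {
    sp <- subject_pca(mats[[i]], cc)
    f[[i]] <- sp$basis
    y[, ((i - 1L) * cc + 1L):(i * cc)] <- sp$scores
  }
  gp <- group_pca(y, n_group_pcs, n_subjects = m)
  structure(
    list(x = gp$x, f = f, g = gp$g, gi = gp$gi, d = gp$d,
         dims = list(V = v, N = n, C = cc, K = ncol(gp$x), M = m),
         backprojectors = new.env(parent = emptyenv())),
    class = "hpca_compression")
}

#' @export
print.hpca_compression <- function(x, ...) {
  d <- x$dims
  cat(sprintf("Two-stage PCA compression: %d subjects, %d voxels\n", d$M, d$V))
  cat(sprintf("  subject stage: %d -> %d, group stage: %d -> %d\n",
              d$N, d$C, d$C * d$M, d$K))
  invisible(x)
}

# K x N back-projection operator for subject i, memoized.
# The compression acts jointly through the tall orthonormal basis G, so its
# generalized inverse is taken of G as a whole: (G^+)_i = (G^T G)^{-1} G_i^T,
# the i-th column block of pinv(G) (equal to t(G_i) for orthonormal G).
# Inverting each nearly-square block G_i on its own would amplify its small
# singular values and bury the reconstruction in noise.
backprojector <- function(compression, i) {
  key <- as.character(i)
  env <- compression$backprojectors
  if (is.null(env[["gtg_inv"]])) {
    gtg <- crossprod(compression$g)
    e <- eigen(gtg, symmetric = TRUE)   # tolerant inverse: G may carry
    keep <- e$values > max(e$values) * 1e-12  # null directions at full order
    env[["gtg_inv"]] <- e$vectors[, keep, drop = FALSE] %*%
      ((1 / e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
  }
  if (is.null(env[[key]]))
    env[[key]] <- (env[["gtg_inv"]] %*% t(compression$gi[[i]])) %*%
      t(compression$f[[i]])
  env[[key]]
}

#' Back-project a group-level score vector into one subject's time space
#'
#' Reverses the two compression stages for subject `i`:
#' `h_i = h %*% Gi^+ %*% t(F_i)`, where `Gi^+` inverts the group
#' compression for the subject's block and `F_i` is the subject basis
#' (orthonormal, so its generalized inverse is the transpose).
#'
#' When an `"hpca_compression"` model is supplied, the subject blocks are
#' inverted jointly through the full orthonormal group basis `G` (the i-th
#' column block of `pinv(G)`, i.e. `t(G_i)` for orthonormal `G`), which is
#' the numerically stable inverse of the compression actually applied. When
#' a bare matrix `gi` is supplied, its own Moore-Penrose pseudo-inverse is
#' used (with a conditioning warning above kappa = 1e8).
#'
#' @param h length-K score vector (e.g. a treelet sum variable).
#' @param gi C x K group-basis block for the subject, or an
#'   `"hpca_compression"` object together with `subject`.
#' @param fi N x C subject basis (ignored when `gi` is a compression model).
#' @param subject subject index when `gi` is an `"hpca_compression"`.
#' @returns Length-N subject-specific time series.
#' @export
backproject_timeseries <- function(h, gi, fi = NULL, subject = NULL) {
  if (inherits(gi, "hpca_compression")) {
    i <- check_count(subject, "subject", 1L)
    b <- backprojector(gi, i)
    return(drop(rbind(h) %*% b))
  }
  gi <- check_matrix(gi, "gi")
  fi <- check_matrix(fi, "fi")
  if (length(h) != ncol(gi)) stop_("`h` length must equal ncol(gi)")
  drop(rbind(h) %*% pinv(gi) %*% t(fi))
}
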