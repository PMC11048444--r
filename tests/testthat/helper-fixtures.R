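# shared fixtures and independent reference implementations

# rows grouped into `n_blocks` blocks; rows within a block are noisy copies
# of one latent source, sources independent across blocks
make_block_data <- function(n_blocks, per_block, k, noise = 0.05, seed = 1) {
  set.seed(seed)
  src <- matrix(rnorm(n_blocks * k), n_blocks, k)
  x <- matrix(0, n_blocks * per_block, k)
  for (b in seq_len(n_blocks)) {
    for (j in seq_len(per_block)) {
      x[(b - 1) * per_block + j, ] <- src[b, ] + rnorm(k, 0, noise)
    }
  }
  list(x = x, sources = src)
}

# independent reference treelet: recomputes the full correlation matrix of
# the active set with stats::cor() at every level and takes the local PCA
# from an explicit 2x2 eigendecomposition
reference_treelet <- function(x) {
  v <- nrow(x)
  s <- t(scale(t(x)))  # rows standardized (sd denominator n-1; scale-free)
  active <- rep(TRUE, v)
  ids <- seq_len(v)
  merges <- matrix(0L, v - 1L, 2L)
  rs <- lam1 <- lam2 <- numeric(v - 1L)
  for (l in seq_len(v - 1L)) {
    cm <- suppressWarnings(stats::cor(t(s)))
    cm[!active, ] <- -Inf
    cm[, !active] <- -Inf
    cm[upper.tri(cm, diag = TRUE)] <- -Inf
    ix <- which.max(cm)
    a <- (ix - 1L) %/% v + 1L
    b <- ix - (a - 1L) * v
    r <- cm[b, a]
    e <- eigen(matrix(c(1, r, r, 1), 2), symmetric = TRUE)
    xs <- (s[a, ] + s[b, ]) / sqrt(2)   # kept variable: normalized sum
    merges[l, ] <- c(ids[a], ids[b])
    rs[l] <- r
    lam1[l] <- e$values[1L]
    lam2[l] <- e$values[2L]
    s[a, ] <- (xs - mean(xs)) / stats::sd(xs)
    active[b] <- FALSE
    ids[a] <- v + l
  }
  list(merges = merges, r = rs, lambda1 = lam1, lambda2 = lam2)
}

# four variables: two orthogonalized duplicate pairs (1,2) and (3,4)
make_duplicate_pairs <- function(k = 60, seed = 3) {
  set.seed(seed)
  a <- rnorm(k)
  b <- rnorm(k)
  b <- residuals(lm(b ~ a))  # orthogonal to a
  rbind(a, a, b, b)
}

# small noiseless two-block dataset from independent latent sources
make_two_block_noiseless <- function(per_block = 5, k = 60, seed = 4) {
  set.seed(seed)
  s1 <- rnorm(k)
  s2 <- rnorm(k)
  x <- rbind(
    t(sapply(seq_len(per_block), function(i) runif(1, 0.5, 2) * s1)),
    t(sapply(seq_len(per_block), function(i) runif(1, 0.5, 2) * s2)))
  x + matrix(rnorm(nrow(x) * k, 0, 1e-6), nrow(x), k)
}

tiny_study <- function(n_levels = 2, branching = 2, n_voxels = 32,
                       n_subjects = 3, n_timepoints = 60, seed = 11, ...) {
  simulate_study(hierarchy_spec(n_levels, branching, n_voxels),
                 n_subjects = n_subjects, n_timepoints = n_timepoints,
                 seed = seed, ...)
}
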