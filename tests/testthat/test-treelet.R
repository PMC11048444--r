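test_that("similarity is signed correlation with guarded inputs", {
  v <- rnorm(20)
  expect_equal(similarity(v, v), 1)
  expect_equal(similarity(v, -v), -1)
  expect_error(similarity(v, rep(1, 20)), "zero-variance")
  expect_error(similarity(v, rnorm(19)), "equal length")
})

test_that("local PCA matches the 2x2 eigendecomposition oracle", {
  set.seed(1)
  x <- rnorm(80)
  y <- 0.7 * x + rnorm(80)
  p <- local_pca2(x, y)
  r <- cor(x, y)
  e <- eigen(matrix(c(1, r, r, 1), 2), symmetric = TRUE)
  expect_equal(p$lambda1, e$values[1], tolerance = 1e-12)
  expect_equal(p$lambda2, e$values[2], tolerance = 1e-12)
  expect_equal(p$lambda1, 1 + abs(r), tolerance = 1e-12)
  expect_equal(p$lambda2, 1 - abs(r), tolerance = 1e-12)
  # scores equal the eigenvector combination of the standardized inputs
  xs <- scale(x)[, 1]; ys <- scale(y)[, 1]
  lead <- e$vectors[, 1]; if (lead[1] < 0) lead <- -lead
  expect_equal(p$sum_scores, lead[1] * xs + lead[2] * ys, tolerance = 1e-10)
  expect_gt(cor(p$sum_scores, x), 0)      # sign convention
  expect_lt(abs(cor(p$sum_scores, p$diff_scores)), 1e-10)
})

test_that("local PCA handles the degenerate and isotropic corners", {
  set.seed(2)
  x <- rnorm(50)
  same <- local_pca2(x, x)
  expect_equal(same$lambda1, 2)
  expect_equal(same$lambda2, 0)
  expect_equal(same$diff_scores, rep(0, 50), tolerance = 1e-12)
  y <- residuals(lm(rnorm(50) ~ x))       # exactly uncorrelated
  iso <- local_pca2(x, y)
  expect_equal(iso$lambda1, 1, tolerance = 1e-12)
  expect_equal(iso$lambda2, 1, tolerance = 1e-12)
  # exactly anticorrelated inputs: the sum variable collapses
  anti <- local_pca2(x, -x)
  expect_equal(anti$r, -1)
  expect_equal(anti$lambda1, 2)
  expect_equal(anti$sum_scores, rep(0, 50), tolerance = 1e-12)
  expect_true(anti$degenerate)
})

test_that("an exactly anticorrelated merge is recorded as degenerate", {
  set.seed(4)
  x <- rnorm(40)
  fit <- hpca(rbind(x, -x))
  expect_equal(fit$r[1], -1)
  expect_identical(fit$degenerate, 1L)
})

test_that("duplicate pairs merge first and their sums join last", {
  x <- make_duplicate_pairs()
  fit <- hpca(x)
  expect_equal(fit$n_levels, 3)
  expect_identical(fit$merges[1, ], c(1L, 2L))
  expect_identical(fit$merges[2, ], c(3L, 4L))
  expect_identical(fit$merges[3, ], c(5L, 6L))
  expect_equal(fit$r[1:2], c(1, 1), tolerance = 1e-10)
  expect_lt(abs(fit$r[3]), 0.3)
})

test_that("a two-variable fit produces the leading principal component", {
  set.seed(3)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  fit <- hpca(rbind(x, y))
  expect_equal(fit$n_levels, 1)
  p <- local_pca2(x, y)
  expect_gt(abs(cor(fit$sum_scores[1, ], p$sum_scores)), 1 - 1e-10)
})

test_that("active set shrinks by one per level", {
  d <- make_block_data(4, 4, 50, seed = 5)
  fit <- hpca(d$x)
  for (l in c(0, 1, 7, 15)) {
    expect_length(active_variables(fit, l), 16 - l)
  }
  expect_error(active_variables(fit, 16), "exceeds")
})

test_that("incremental similarity maintenance equals full recomputation", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(24 * 40), 24, 40)
    fit <- hpca(x)
    ref <- reference_treelet(x)
    expect_identical(fit$merges, ref$merges)
    expect_equal(fit$r, ref$r, tolerance = 1e-10)
    expect_equal(fit$lambda1, ref$lambda1, tolerance = 1e-10)
    expect_equal(fit$lambda2, ref$lambda2, tolerance = 1e-10)
  }
  # structured case: correlated blocks
  d <- make_block_data(4, 4, 60, noise = 0.3, seed = 9)
  fit <- hpca(d$x)
  ref <- reference_treelet(d$x)
  expect_identical(fit$merges, ref$merges)
  expect_equal(fit$r, ref$r, tolerance = 1e-10)
})

test_that("eigen-identities and score orthogonality hold at every node", {
  d <- make_block_data(3, 5, 45, noise = 0.2, seed = 6)
  fit <- hpca(d$x)
  expect_equal(fit$lambda1 + fit$lambda2, rep(2, fit$n_levels),
               tolerance = 1e-10)
  expect_equal(fit$lambda1, 1 + abs(fit$r), tolerance = 1e-10)
  for (l in seq_len(fit$n_levels)) {
    if (fit$lambda2[l] < 1e-8) next
    expect_lt(abs(cor(fit$sum_scores[l, ], fit$diff_scores[l, ])), 1e-8)
  }
})

test_that("noiseless two-block data merge within blocks before joining them", {
  x <- make_two_block_noiseless(per_block = 5, k = 60)
  fit <- hpca(x)
  sets <- hpca:::leaf_sets(fit)
  block <- function(ls) if (all(ls <= 5)) 1L else if (all(ls >= 6)) 2L else 0L
  within <- vapply(sets[1:(fit$n_levels - 1)], block, 0L)
  expect_true(all(within > 0))
  expect_identical(sort(sets[[fit$n_levels]]), 1:10)
})

test_that("degenerate inputs are rejected with the offending row", {
  x <- rbind(rnorm(20), rep(2, 20))
  expect_error(hpca(x), "zero-variance row")
})

test_that("the dendrogram converts to hclust and exports cleanly", {
  d <- make_block_data(3, 3, 40, seed = 7)
  fit <- hpca(d$x)
  hc <- as.hclust(fit)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, 1 - fit$r)
  expect_identical(sort(hc$order), 1:9)
  tab <- export_dendrogram(fit)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$height, 1 - fit$r)
  expect_equal(tab$size[nrow(tab)], 9L)
  nw <- export_dendrogram(fit, format = "newick")
  expect_match(nw, "^\\(")
})
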