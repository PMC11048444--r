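# four-leaf tree with two duplicate pairs: leaves 1,2 merge at level 1
# (sum id 5), leaves 3,4 at level 2 (sum id 6), sums join at level 3
dup_tree <- function() hpca(make_duplicate_pairs())

test_that("tree dependencies partition the basis by descent", {
  fit <- dup_tree()
  # against the leaf basis: a level-1 node depends on its two voxels only
  d1 <- tree_dependencies(fit, 1, base_level = 0)
  expect_identical(d1$dependent, c(1L, 2L))
  expect_identical(d1$independent, c(3L, 4L))
  # the root depends on everything: nothing to orthogonalize against
  droot <- tree_dependencies(fit, 3, base_level = 0)
  expect_identical(sort(droot$dependent), 1:4)
  expect_length(droot$independent, 0)
  # against the level-2 basis the root merges exactly the two basis sums
  d3 <- tree_dependencies(fit, 3, base_level = 2)
  expect_identical(sort(d3$dependent), c(5L, 6L))
  expect_length(d3$independent, 0)
  expect_error(tree_dependencies(fit, 2, base_level = 2), "must lie in")
})

test_that("orthogonalization leaves dependent-only series unchanged", {
  fit <- dup_tree()
  basis_ids <- active_variables(fit, 2)
  basis <- t(variable_scores(fit, basis_ids))
  h <- fit$sum_scores[3, ]
  deps <- tree_dependencies(fit, 3, base_level = 2)
  expect_identical(orthogonalize_scores(h, basis, deps, basis_ids), h)
})

test_that("orthogonalization residuals are orthogonal to the regressors", {
  set.seed(21)
  basis <- scale(matrix(rnorm(80 * 5), 80, 5), scale = FALSE)
  basis_ids <- 1:5
  deps <- list(dependent = 1:2, independent = 3:5)
  h <- rnorm(80)
  res <- orthogonalize_scores(h, basis, deps, basis_ids)
  for (j in 3:5) expect_lt(abs(cor(res, basis[, j])), 1e-10)
  # a vector inside the independent span is annihilated
  inside <- drop(basis[, 3:5] %*% c(1, -2, 0.5))
  expect_lt(max(abs(orthogonalize_scores(inside, basis, deps, basis_ids))),
            1e-10)
})

test_that("lossless reconstruction matches the uncompressed computation", {
  # 16 independent block sources: one block is a small fraction of the
  # volume, so the removed global spatial mean barely touches its maps
  x <- make_block_data(16, 4, 150, noise = 1e-3, seed = 8)$x
  cm <- suppressWarnings(compress_study(list(x), n_subject_pcs = 64,
                                        n_group_pcs = 64))
  fit <- hpca(cm$x)
  # the first merge joins two rows of the same block, and its
  # back-projected series reproduces the corresponding combination of the
  # raw centered data (inner products survive the lossless rotation; only
  # the Pearson mean term, O(K^-1/2), lives in compressed coordinates)
  zc <- x - rowMeans(x)
  zc <- sweep(zc, 2, colMeans(zc))
  pair <- fit$merges[1, ]
  expect_equal((pair[1] - 1) %/% 4, (pair[2] - 1) %/% 4)
  rl <- reconstruct_level(fit, 1, cm, list(x), orthogonalize = FALSE)
  expect_gt(cor(drop(rl$subject_timeseries), zc[pair[1], ] + zc[pair[2], ]),
            0.99)
  # seed-correlation map: high within the merged source's block, small
  # outside it
  leaves <- hpca:::leaf_sets(fit)[[1]]
  block <- (leaves[1] - 1) %/% 4
  members <- block * 4 + 1:4
  expect_gt(min(rl$raw_maps[1, members]), 0.9)
  expect_lt(max(abs(rl$raw_maps[1, setdiff(1:64, members)])), 0.45)
})

test_that("subject maps are z-scored and the group map is their mean", {
  st <- tiny_study(n_voxels = 24, n_subjects = 3, n_timepoints = 50, seed = 22)
  cm <- compress_study(st, n_subject_pcs = 20, n_group_pcs = 24)
  fit <- hpca(cm$x)
  rl <- reconstruct_level(fit, fit$n_levels - 2, cm, st,
                          base_level = 4, orthogonalize = TRUE)
  for (i in 1:3) {
    expect_equal(mean(rl$subject_maps[i, ]), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean(rl$subject_maps[i, ]^2)), 1, tolerance = 1e-10)
  }
  expect_equal(rl$group_map, colMeans(rl$subject_maps), tolerance = 1e-12)
})

test_that("basis variables orthogonalize against the rest of the basis", {
  st <- tiny_study(n_voxels = 32, n_subjects = 4, n_timepoints = 80, seed = 23)
  cm <- compress_study(st, n_subject_pcs = 30, n_group_pcs = 32)
  fit <- hpca(cm$x)
  fl <- filter_levels(fit, gamma = 0.4, alpha_fwe = 0.05)
  base <- max(fl$base_level, 1L)
  basis_ids <- active_variables(fit, base)
  id <- basis_ids[1]
  deps <- hpca:::variable_dependencies(fit, id, base)
  expect_identical(deps$dependent, id)
  expect_identical(deps$independent, setdiff(basis_ids, id))
  rv <- reconstruct_variable(fit, id, cm, st, base_level = base)
  expect_equal(dim(rv$subject_maps), c(4L, 32L))
})

test_that("orthogonalization typically sharpens within-support contrast", {
  st <- tiny_study(n_levels = 2, branching = 2, n_voxels = 64,
                   n_subjects = 8, n_timepoints = 150, seed = 24)
  cm <- compress_study(st, n_subject_pcs = 60, n_group_pcs = 60)
  fit <- hpca(cm$x)
  fl <- filter_levels(fit, gamma = 0.4, alpha_fwe = 0.001)
  contrast <- vapply(fl$significant_levels, function(lev) {
    support <- hpca:::leaf_sets(fit)[[lev]]
    orth <- reconstruct_level(fit, lev, cm, st, base_level = fl$base_level,
                              orthogonalize = TRUE)
    plain <- reconstruct_level(fit, lev, cm, st, orthogonalize = FALSE)
    c(max(abs(orth$group_map[support])), max(abs(plain$group_map[support])))
  }, numeric(2))
  # the typical significant level gains contrast; individual high levels
  # can lose shared variance instead (a known trait of the procedure)
  expect_gt(median(contrast[1, ]), median(contrast[2, ]))
})
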