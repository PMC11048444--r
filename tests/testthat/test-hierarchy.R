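test_that("component counts follow the branching geometry", {
  expect_identical(count_components(5, 2), 62L)
  expect_identical(count_components(3, 3), 39L)
  expect_identical(count_components(1, 2), 2L)
  expect_error(count_components(0, 2), "n_levels")
  expect_error(count_components(3, 1), "branching")
})

test_that("equal-mode hierarchy maps partition the voxel line at every level", {
  spec <- hierarchy_spec(5, 2, 1024)
  src <- build_hierarchy_maps(spec)
  expect_equal(nrow(src$blocks), 62)
  deep <- src$blocks[src$blocks$level == 5, ]
  expect_equal(nrow(deep), 32)
  expect_true(all(deep$size == 32))
  # every voxel lies in exactly one block per level (L supports in total)
  expect_true(all(rowSums(src$weights) == 5))
  for (l in 1:5) {
    lv <- src$blocks[src$blocks$level == l, ]
    expect_equal(sum(lv$size), 1024)
    cover <- unlist(mapply(seq, lv$start, lv$end, SIMPLIFY = FALSE))
    expect_identical(sort(cover), 1:1024)
  }
  # nesting: each deep block inside exactly one parent block
  parents <- src$blocks[src$blocks$level == 4, ]
  inside <- vapply(seq_len(nrow(deep)), function(i)
    sum(parents$start <= deep$start[i] & parents$end >= deep$end[i]), 0L)
  expect_true(all(inside == 1L))
})

test_that("component count matches the closed form for a grid of specs", {
  for (l in 1:3) for (d in 2:4) {
    spec <- hierarchy_spec(l, d, 256)
    expect_equal(nrow(build_hierarchy_maps(spec)$blocks),
                 count_components(l, d))
  }
})

test_that("dirichlet block sizes respect the minimum and nest correctly", {
  spec <- hierarchy_spec(3, 3, 1024, block_mode = "dirichlet",
                         dirichlet_alpha = c(3, 3, 3))
  src <- build_hierarchy_maps(spec, seed = 5)
  expect_equal(nrow(src$blocks), 39)
  expect_true(all(src$blocks$size >= 2))
  deep <- src$blocks[src$blocks$level == 3, ]
  expect_equal(sum(deep$size), 1024)
  expect_true(all(deep$size >= 2 & deep$size <= 505))
  expect_true(all(rowSums(src$weights) == 3))
})

test_that("infeasible hierarchies are rejected", {
  expect_error(hierarchy_spec(1, 2, 10, block_mode = "equal", min_block = 6),
               "infeasible")
  expect_error(hierarchy_spec(5, 2, 32), "infeasible")
})

test_that("component time courses are normalized and event-driven", {
  r <- simulate_component_timeseries(100, 300, tr = 2, seed = 8)
  expect_equal(rowMeans(r), rep(0, 100), tolerance = 1e-12)
  ptp <- apply(r, 1, function(x) diff(range(x)))
  expect_equal(ptp, rep(1, 100), tolerance = 1e-12)
  ev <- attr(r, "events")
  n <- length(ev)
  rate <- mean(ev)
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  # an all-zero event train has no defined normalization
  expect_null(hpca:::events_to_bold(rep(0, 50), hrf_double_gamma(seq(0, 32, 2))))
})

test_that("subject noise scales as sigma_s over CNR with Rician statistics", {
  src <- build_hierarchy_maps(hierarchy_spec(1, 2, 64), seed = 2)
  sub <- simulate_subject(src, n_timepoints = 200, seed = 9, cnr = 2,
                          keep_noise_free = TRUE)
  expect_equal(sub$sigma_n, sub$sigma_s / 2)
  # added Rician term is Rayleigh(sigma_n): mean sigma_n * sqrt(pi/2)
  rice <- sub$data - sub$noise_free
  expect_true(all(rice >= 0))
  n <- length(rice)
  se <- sqrt((2 - pi / 2) * sub$sigma_n^2 / n)
  expect_lt(abs(mean(rice) - sub$sigma_n * sqrt(pi / 2)), 4 * se)
})

test_that("with all noise sources off the data equal the mixing model", {
  src <- build_hierarchy_maps(hierarchy_spec(1, 2, 20), seed = 2)
  sub <- simulate_subject(src, n_timepoints = 80, seed = 10, cnr = 1e9,
                          map_noise_sd = 0, amp_sd = 0, keep_truth = TRUE)
  expect_equal(sub$data, src$weights %*% sub$truth$timeseries,
               tolerance = 1e-6)
})

test_that("group correlation averages subjects and flags degenerate voxels", {
  v <- rnorm(30)
  expect_equal(group_correlation(list(rbind(v, v))),
               matrix(1, 2, 2), tolerance = 1e-12)
  bad <- rbind(v, rep(1, 30))
  expect_error(group_correlation(list(bad)), "zero-variance voxel 2")
})

test_that("independent sources give near-zero between-block correlation", {
  x <- make_two_block_noiseless(per_block = 6, k = 400)
  g <- group_correlation(list(x))
  between <- g[1:6, 7:12]
  expect_lt(max(abs(between)), 4 / sqrt(400))
  expect_gt(min(g[1:6, 1:6]), 0.99)
})

test_that("simulated nested hierarchy yields nested block correlations", {
  st <- tiny_study(n_levels = 2, branching = 2, n_voxels = 64,
                   n_subjects = 6, n_timepoints = 120, seed = 21)
  g <- group_correlation(st)
  blocks <- st$sources$blocks
  deep <- blocks[blocks$level == 2, ]
  within_deep <- mean(vapply(seq_len(nrow(deep)), function(i) {
    idx <- deep$start[i]:deep$end[i]
    m <- g[idx, idx]
    mean(m[upper.tri(m)])
  }, 0))
  top <- blocks[blocks$level == 1, ]
  between_top <- mean(g[top$start[1]:top$end[1], top$start[2]:top$end[2]])
  expect_gt(within_deep, between_top)
  # within-ancestral-block means stay non-negative up to sampling error
  within_top <- mean(g[top$start[1]:top$end[1], top$start[1]:top$end[1]])
  expect_gt(within_top, -0.05)
})
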