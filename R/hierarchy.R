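#' Declare a nested block spatial hierarchy
#'
#' A hierarchy specification describes how a line of `n_voxels` voxels is
#' recursively partitioned: every block at level `l - 1` is split into
#' `branching` child blocks at level `l`, down to `n_levels` levels. One
#' network component is attached to every block at every level, so a voxel in
#' a deepest block carries the signal of all of its ancestors. Block sizes are
#' either as equal as integer arithmetic allows (`block_mode = "equal"`) or
#' drawn per branch from a Dirichlet distribution (`block_mode = "dirichlet"`).
#'
#' @param n_levels number of levels `L >= 1` of the hierarchy.
#' @param branching branching degree `D >= 2` at every split.
#' @param n_voxels total number of voxels `V`.
#' @param block_mode `"equal"` or `"dirichlet"` block-size law.
#' @param dirichlet_alpha Dirichlet concentration vector of length `branching`
#'   (only used for `block_mode = "dirichlet"`).
#' @param min_block smallest admissible block size, in voxels.
#' @returns An object of class `"hpca_hierarchy_spec"`.
#' @seealso [build_hierarchy_maps()], [simulate_study()]
#' @examples
#' hierarchy_spec(5, 2, 1024)
#' hierarchy_spec(3, 3, 1024, block_mode = "dirichlet")
#' @export
hierarchy_spec <- function(n_levels, branching, n_voxels,
                           block_mode = c("equal", "dirichlet"),
                           dirichlet_alpha = NULL, min_block = 2L) {
  n_levels <- check_count(n_levels, "n_levels", 1L)
  branching <- check_count(branching, "branching", 2L)
  n_voxels <- check_count(n_voxels, "n_voxels", 2L)
  min_block <- check_count(min_block, "min_block", 2L)
  block_mode <- match.arg(block_mode)
  if (block_mode == "dirichlet") {
    dirichlet_alpha <- dirichlet_alpha %||% rep(3, branching)
    if (length(dirichlet_alpha) != branching || any(dirichlet_alpha <= 0))
      stop_("`dirichlet_alpha` must be a positive vector of length `branching`")
  }
  if (n_voxels < min_block * branching^n_levels)
    stop_(sprintf(
      "infeasible hierarchy: %d voxels cannot give all %d deepest blocks >= %d voxels",
      n_voxels, branching^n_levels, min_block))
  structure(
    list(n_levels = n_levels, branching = branching, n_voxels = n_voxels,
         block_mode = block_mode, dirichlet_alpha = dirichlet_alpha,
         min_block = min_block),
    class = "hpca_hierarchy_spec")
}

#' @export
print.hpca_hierarchy_spec <- function(x, ...) {
  cat(sprintf("Nested block hierarchy: %d level(s), %d-way branching, %d voxels (%s blocks)\n",
              x$n_levels, x$branching, x$n_voxels, x$block_mode))
  cat(sprintf("  %d components in total\n", count_components(x$n_levels, x$branching)))
  invisible(x)
}

#' Number of components in a nested block hierarchy
#'
#' With branching degree `D` over `L` levels there are `D^l` blocks at level
#' `l`, one component per block, hence `sum(D^(1:L))` components in total
#' (e.g. 2-way branching over five levels gives 62, 3-way over three gives 39).
#'
#' @param n_levels number of levels `L >= 1`.
#' @param branching branching degree `D >= 2`.
#' @returns Integer component count.
#' @examples
#' count_components(5, 2) # 62
#' count_components(3, 3) # 39
#' @export
count_components <- function(n_levels, branching) {
  n_levels <- check_count(n_levels, "n_levels", 1L)
  branching <- check_count(branching, "branching", 2L)
  as.integer(sum(branching^(seq_len(n_levels))))
}

# split n voxels into D child sizes; dirichlet mode uses largest-remainder
# apportionment and resamples the branch while any child < min_block
split_block <- function(n, spec) {
  d <- spec$branching
  if (spec$block_mode == "equal")
    return(diff(round(seq(0, n, length.out = d + 1))))
  for (attempt in seq_len(1000L)) {
    g <- stats::rgamma(d, shape = spec$dirichlet_alpha, rate = 1)
    p <- g / sum(g)
    raw <- p * n
    sizes <- floor(raw)
    short <- n - sum(sizes)
    if (short > 0) {
      ord <- order(raw - sizes, decreasing = TRUE)
      sizes[ord[seq_len(short)]] <- sizes[ord[seq_len(short)]] + 1L
    }
    if (all(sizes >= spec$min_block)) return(as.integer(sizes))
  }
  stop_(sprintf(
    "infeasible split: could not divide %d voxels into %d blocks of >= %d voxels",
    n, d, spec$min_block))
}

#' Build the ground-truth component supports of a hierarchy
#'
#' Recursively partitions the voxel line according to a hierarchy
#' specification and attaches one component to every block of every level.
#' Component spatial weights are 1 on the block and 0 elsewhere, so each
#' voxel at depth `L` lies in the support of exactly `L` components, one per
#' ancestor level.
#'
#' @param spec an [hierarchy_spec()] object.
#' @param seed optional integer seed (only consumed by the Dirichlet
#'   block-size draws).
#' @returns An object of class `"hpca_sources"` with elements
#'   \describe{
#'     \item{weights}{`n_voxels` x `n_components` spatial weight matrix (the
#'       group maps, components in columns).}
#'     \item{blocks}{data frame with one row per component: `component`,
#'       `level`, `index` (block index within its level), `start`, `end`,
#'       `size` (voxel support, 1-based inclusive).}
#'     \item{spec}{the input specification.}
#'   }
#' @examples
#' src <- build_hierarchy_maps(hierarchy_spec(3, 2, 64))
#' dim(src$weights) # 64 x 14
#' @export
build_hierarchy_maps <- function(spec, seed = NULL) {
  if (!inherits(spec, "hpca_hierarchy_spec"))
    stop_("`spec` must be created with hierarchy_spec()")
  if (!is.null(seed)) set.seed(check_count(seed, "seed", 0L))
  v <- spec$n_voxels
  p <- count_components(spec$n_levels, spec$branching)
  w <- matrix(0, v, p)
  blocks <- vector("list", p)
  comp <- 0L
  frontier <- list(c(1L, v))
  for (l in seq_len(spec$n_levels)) {
    nxt <- vector("list", length(frontier) * spec$branching)
    k <- 0L
    for (b in frontier) {
      sizes <- split_block(b[2] - b[1] + 1L, spec)
      at <- b[1]
      for (d in seq_len(spec$branching)) {
        comp <- comp + 1L
        k <- k + 1L
        idx <- at:(at + sizes[d] - 1L)
        w[idx, comp] <- 1
        blocks[[comp]] <- data.frame(component = comp, level = l, index = k,
                                     start = at, end = at + sizes[d] - 1L,
                                     size = sizes[d])
        nxt[[k]] <- c(at, at + sizes[d] - 1L)
        at <- at + sizes[d]
      }
    }
    frontier <- nxt
  }
  structure(list(weights = w, blocks = do.call(rbind, blocks), spec = spec),
            class = "hpca_sources")
}

#' @export
print.hpca_sources <- function(x, ...) {
  deep <- x$blocks[x$blocks$level == x$spec$n_levels, ]
  cat(sprintf("Ground-truth hierarchy sources: %d components over %d voxels\n",
              nrow(x$blocks), x$spec$n_voxels))
  cat(sprintf("  deepest level: %d blocks, sizes %d-%d voxels\n",
              nrow(deep), min(deep$size), max(deep$size)))
  invisible(x)
}
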