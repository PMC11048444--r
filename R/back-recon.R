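#' Dendrogram dependencies of a level relative to the base-level basis
#'
#' The analysis basis is the set of active variables at the base level.
#' A level's sum variable is tree-dependent on exactly those basis variables
#' that are its dendrogram descendants (their leaf sets intersect its leaf
#' set); it is tree-independent of the rest. The root is dependent on the
#' whole basis, so its independent set is empty.
#'
#' @param tree an `"hpca"` fit.
#' @param level level index, `base_level < level <= n_levels`.
#' @param base_level the SET-selected base level (see [select_base_level()]).
#' @returns List with `dependent` and `independent` variable id vectors
#'   (a partition of the base-level active set) and `level`.
#' @export
tree_dependencies <- function(tree, level, base_level) {
  stopifnot(inherits(tree, "hpca"))
  level <- check_count(level, "level", 1L)
  base_level <- check_count(base_level, "base_level", 0L)
  if (level <= base_level || level > tree$n_levels)
    stop_(sprintf("`level` must lie in (%d, %d]", base_level, tree$n_levels))
  basis <- active_variables(tree, base_level)
  sets <- leaf_sets(tree)
  v <- tree$n_leaves
  node_leaves <- sets[[level]]
  dep <- vapply(basis, function(id) {
    lv <- if (id <= v) id else sets[[id - v]]
    any(lv %in% node_leaves)
  }, logical(1))
  list(level = level, dependent = basis[dep], independent = basis[!dep])
}

#' Tree-independent orthogonalization of a level's score vector
#'
#' Regresses the level's sum-variable scores on the tree-independent subset
#' of the base-level basis and returns the residual, removing latent
#' statistical dependence on parts of the hierarchy the level does not
#' descend from (a dendrogram-constrained analogue of partial correlation).
#' When the independent set is empty (e.g. the tree root) the scores are
#' returned unchanged.
#'
#' @param h length-K score vector.
#' @param basis K x B matrix whose columns are the base-level basis score
#'   vectors, ordered as the basis ids.
#' @param deps a dependency partition from [tree_dependencies()]; columns of
#'   `basis` must correspond to `c(deps$dependent, deps$independent)` order
#'   given by `basis_ids`.
#' @param basis_ids variable ids labelling the columns of `basis`.
#' @returns Length-K residual vector.
#' @export
orthogonalize_scores <- function(h, basis, deps, basis_ids) {
  basis <- check_matrix(basis, "basis")
  if (length(h) != nrow(basis)) stop_("`h` length must match nrow(basis)")
  keep <- basis_ids %in% deps$independent
  if (!any(keep)) return(h)
  x <- basis[, keep, drop = FALSE]
  drop(stats::lm.fit(x, h)$residuals)
}

# dependency partition for any variable id: a basis member depends only on
# itself; a sum variable above the base level depends on its descendants
variable_dependencies <- function(tree, id, base_level) {
  basis <- active_variables(tree, base_level)
  if (id %in% basis)
    return(list(level = NA_integer_, dependent = id,
                independent = setdiff(basis, id)))
  v <- tree$n_leaves
  if (id <= v || id - v <= base_level)
    stop_("variable is neither a basis member nor a level above the base")
  tree_dependencies(tree, id - v, base_level)
}

#' Back-reconstruct subject time series and spatial maps for a level
#'
#' For the selected level's sum variable `h` (optionally tree-independent
#' orthogonalized in compressed space), computes every subject's
#' back-projected time series `h_i = h pinv(G_i) t(F_i)` and their
#' seed-correlation spatial maps: the Pearson correlation of `h_i` with each
#' voxel's raw time series, z-scored across voxels (population SD). The
#' group map is the mean of the subject maps.
#'
#' @param tree an `"hpca"` fit of the compressed data.
#' @param level level whose sum variable is reconstructed.
#' @param compression the `"hpca_compression"` used to build the tree input.
#' @param subjects the uncompressed data: an `"hpca_study"` or list of
#'   voxel-by-time matrices.
#' @param base_level SET base level defining the orthogonalization basis
#'   (required when `orthogonalize = TRUE`).
#' @param orthogonalize apply tree-independent orthogonalization first?
#' @returns An object of class `"hpca_level_maps"`: list with `level`,
#'   `orthogonalized`, `subject_timeseries` (M x N), `subject_maps` (M x V,
#'   z-scored), `raw_maps` (M x V correlations before z-scoring),
#'   `group_map` (length V), `excluded_subjects`.
#' @export
reconstruct_level <- function(tree, level, compression, subjects,
                              base_level = NULL, orthogonalize = TRUE) {
  level <- check_count(level, "level", 1L)
  if (level > tree$n_levels) stop_("`level` exceeds the number of levels")
  out <- reconstruct_variable(tree, tree$n_leaves + level, compression,
                              subjects, base_level = base_level,
                              orthogonalize = orthogonalize)
  out$level <- level
  out
}

#' Back-reconstruct any tree variable (leaf, basis member or level sum)
#'
#' Generalization of [reconstruct_level()] to arbitrary variable
#' identifiers, in particular the active variables of the base level (each
#' tree-independent of every other basis member, so orthogonalization
#' regresses out the rest of the basis).
#'
#' @inheritParams reconstruct_level
#' @param id variable identifier (leaf `1..V` or sum `V + level`).
#' @returns See [reconstruct_level()]; `level` is `id - V` for sum
#'   variables and `NA` for leaves.
#' @export
reconstruct_variable <- function(tree, id, compression, subjects,
                                 base_level = NULL, orthogonalize = TRUE) {
  stopifnot(inherits(tree, "hpca"), inherits(compression, "hpca_compression"))
  id <- check_count(id, "id", 1L)
  if (id > tree$n_leaves + tree$n_levels) stop_("unknown variable id")
  mats <- if (inherits(subjects, "hpca_study"))
    lapply(subjects$subjects, `[[`, "data") else subjects
  m <- length(mats)
  if (m != compression$dims$M)
    stop_("subject count does not match the compression model")
  h <- drop(variable_scores(tree, id))
  if (orthogonalize) {
    if (is.null(base_level)) stop_("`base_level` is required for orthogonalization")
    deps <- variable_dependencies(tree, id, base_level)
    basis_ids <- active_variables(tree, base_level)
    basis <- t(variable_scores(tree, basis_ids))
    h <- orthogonalize_scores(h, basis, deps, basis_ids)
  }
  v <- compression$dims$V
  n <- compression$dims$N
  ts <- matrix(0, m, n)
  maps <- raw <- matrix(NA_real_, m, v)
  excluded <- integer(0)
  for (i in seq_len(m)) {
    hi <- drop(rbind(h) %*% backprojector(compression, i))
    ts[i, ] <- hi
    if (stats::sd(hi) == 0) {
      excluded <- c(excluded, i)
      next
    }
    r <- drop(stats::cor(t(mats[[i]]), hi))
    raw[i, ] <- r
    maps[i, ] <- zscore_pop(r)
  }
  if (length(excluded))
    warning(sprintf("%d subject(s) with zero-variance reconstructed series excluded from the group map: %s",
                    length(excluded), paste(excluded, collapse = ", ")),
            call. = FALSE)
  keep <- setdiff(seq_len(m), excluded)
  level <- if (id > tree$n_leaves) id - tree$n_leaves else NA_integer_
  structure(
    list(level = level, id = id, orthogonalized = orthogonalize,
         subject_timeseries = ts, subject_maps = maps, raw_maps = raw,
         group_map = colMeans(maps[keep, , drop = FALSE]),
         excluded_subjects = excluded),
    class = "hpca_level_maps")
}

#' @export
print.hpca_level_maps <- function(x, ...) {
  what <- if (is.na(x$level)) sprintf("variable %d", x$id)
          else sprintf("level %d", x$level)
  cat(sprintf("Back-reconstructed %s (%s): %d subjects, %d voxels\n",
              what, if (x$orthogonalized) "orthogonalized" else "plain",
              nrow(x$subject_maps), ncol(x$subject_maps)))
  cat(sprintf("  group map |z| max: %.2f\n", max(abs(x$group_map))))
  invisible(x)
}
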