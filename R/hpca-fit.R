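#' Signed-correlation similarity between two score vectors
#'
#' The treelet merge criterion: plain Pearson correlation, signed (not its
#' absolute value), so anticorrelated variables are dissimilar.
#'
#' @param x,y numeric vectors of equal length (>= 3) with nonzero variance.
#' @returns Correlation in `[-1, 1]`.
#' @export
similarity <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_("`x` and `y` must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_("similarity is undefined for zero-variance input")
  stats::cor(x, y)
}

#' Local PCA of a pair of variables
#'
#' Standardizes both inputs and takes the principal components of their
#' 2 x 2 correlation matrix: the "sum" variable `(x + y)/sqrt(2)` and the
#' "difference" variable `(x - y)/sqrt(2)` (on standardized inputs), always
#' uncorrelated, with the eigenvalue pair `lambda1 = 1 + |r|`,
#' `lambda2 = 1 - |r|`. For a positively correlated pair the sum is the
#' leading component; for an anticorrelated pair it is the minor one (such
#' mergers are exactly the ones the correlation test later flags as
#' unrelated), and at `r = -1` it degenerates to zero variance.
#'
#' @param x,y numeric score vectors.
#' @returns List with `sum_scores`, `diff_scores` (principal-component
#'   scores of the standardized pair), `lambda1`, `lambda2`, `r` (the merge
#'   similarity), and `degenerate` (`TRUE` when the sum variable has no
#'   variance, which happens exactly at `r = -1`).
#' @examples
#' p <- local_pca2(sin(1:50), sin(1:50) + rnorm(50, 0, 0.1))
#' p$lambda1 + p$lambda2 # 2
#' @export
local_pca2 <- function(x, y) {
  r <- similarity(x, y)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  s <- (xs + ys) / sqrt(2)
  d <- (xs - ys) / sqrt(2)
  list(sum_scores = s, diff_scores = d,
       lambda1 = 1 + abs(r), lambda2 = 1 - abs(r), r = r,
       degenerate = stats::sd(s) < sqrt(.Machine$double.eps))
}

#' Fit a treelet hierarchical principal component analysis
#'
#' Builds the full merge hierarchy over the rows of `x` (variables, e.g.
#' voxels; columns are observations, e.g. compressed time points). At each
#' level the pair of active variables with maximal signed correlation is
#' merged by a two-variable local PCA; the "sum" variable
#' (re-standardized) replaces the pair in the active set and the
#' "difference" variable is set aside. For positively correlated pairs —
#' every merger a later significance filter keeps — the sum is the leading
#' principal component. After `V - 1` levels a single root remains. The similarity matrix is maintained incrementally:
#' only the new variable's row is recomputed after each merge. Ties at the
#' arg max are broken by the lexicographically smallest index pair.
#'
#' Variable identifiers: leaves are `1..V`; the sum variable created at
#' level `l` is `V + l`.
#'
#' @param x numeric matrix, variables in rows, observations in columns
#'   (at least 3 observations; no zero-variance row).
#' @param n_levels number of merge levels, or `"full"` (default, `V - 1`).
#' @returns An object of class `"hpca"`: list with
#'   \describe{
#'     \item{merges}{`(V-1)` x 2 matrix of merged variable identifiers
#'       (first column is the variable the sum loads positively on).}
#'     \item{r}{merge similarity at each level.}
#'     \item{lambda1, lambda2}{eigenvalue pair of each local PCA.}
#'     \item{sum_scores, diff_scores}{levels x K score matrices.}
#'     \item{leaf_scores}{standardized input rows (V x K).}
#'     \item{degenerate}{levels with a zero-variance sum variable (excluded
#'       from further merging).}
#'     \item{n_leaves, n_obs}{problem dimensions.}
#'   }
#' @references Lee, Nadler and Wasserman (2008), Ann. Appl. Stat. 2(2),
#'   435-471 (treelets).
#' @examples
#' x <- matrix(rnorm(8 * 40), 8, 40)
#' fit <- hpca(x)
#' fit
#' @export
hpca <- function(x, n_levels = "full") {
  x <- check_matrix(x, "x")
  v <- nrow(x)
  k <- ncol(x)
  if (v < 2L) stop_("need at least two variables (rows)")
  if (k < 3L) stop_("need at least three observations (columns)")
  nlev <- if (identical(n_levels, "full")) v - 1L
          else min(v - 1L, check_count(n_levels, "n_levels", 1L))

  s <- row_standardize(x)          # rows: mean 0, unit norm; tcrossprod = cor
  ids <- seq_len(v)                # active-slot -> variable id
  alive <- rep(TRUE, v)
  # lower-triangular similarity; inactive entries -Inf. Column-major
  # which.max then realizes lexicographic (smallest-first) tie-breaking.
  cm <- tcrossprod(s)
  cm[upper.tri(cm, diag = TRUE)] <- -Inf

  merges <- matrix(0L, nlev, 2L)
  rvec <- lamb2 <- numeric(nlev)
  sums <- diffs <- matrix(0, nlev, k)
  degen <- logical(nlev)

  for (l in seq_len(nlev)) {
    ix <- which.max(cm)
    if (!is.finite(cm[ix]))
      stop_("no mergeable pair left: all remaining variables are degenerate")
    a <- ((ix - 1L) %/% v) + 1L    # column = smaller slot
    b <- ix - (a - 1L) * v         # row = larger slot
    r <- cm[b, a]
    xa <- s[a, ]
    xb <- s[b, ]
    xs <- xa + xb
    xd <- xa - xb
    # standardized inputs have unit norm: the PC scores of the pair are
    # (xa +/- xb)/sqrt(2) with norms sqrt(1 +/- r); the sum is kept as the
    # active variable (it is the leading PC whenever r >= 0)
    merges[l, ] <- c(ids[a], ids[b])
    rvec[l] <- r
    lamb2[l] <- 1 - abs(r)
    sums[l, ] <- xs / sqrt(2)
    diffs[l, ] <- xd / sqrt(2)

    alive[b] <- FALSE
    cm[b, ] <- -Inf
    cm[, b] <- -Inf
    ids[a] <- v + l

    nrm <- sqrt(sum(xs^2))
    if (nrm < sqrt(.Machine$double.eps)) {
      # exact anticorrelation: record the merge, flag the sum variable and
      # drop it from further similarity maximization
      degen[l] <- TRUE
      alive[a] <- FALSE
      cm[a, ] <- -Inf
      cm[, a] <- -Inf
      next
    }
    xs <- xs - mean(xs)
    xs <- xs / sqrt(sum(xs^2))     # re-standardize before reinsertion
    s[a, ] <- xs
    cr <- as.vector(s %*% xs)
    cr[!alive] <- -Inf
    if (a > 1L) cm[a, seq_len(a - 1L)] <- cr[seq_len(a - 1L)]
    if (a < v) cm[(a + 1L):v, a] <- cr[(a + 1L):v]
  }

  structure(
    list(merges = merges, r = rvec, lambda1 = 1 + abs(rvec), lambda2 = lamb2,
         sum_scores = sums, diff_scores = diffs, leaf_scores = s0_leaves(x),
         degenerate = which(degen), n_leaves = v, n_obs = k,
         n_levels = nlev),
    class = "hpca")
}

# standardized copies of the original rows (merging overwrote slots in s)
s0_leaves <- function(x) row_standardize(x)

#' Active variable identifiers after a given level
#'
#' Replays the merge sequence: the active set starts as the `V` leaves and at
#' each level loses the merged pair and gains the new sum variable, so its
#' size after level `l` is `V - l`.
#'
#' @param tree an `"hpca"` fit.
#' @param level level index in `0..n_levels` (0 = nothing merged).
#' @returns Integer vector of active variable ids, ascending.
#' @export
active_variables <- function(tree, level) {
  stopifnot(inherits(tree, "hpca"))
  level <- check_count(level, "level", 0L)
  if (level > tree$n_levels) stop_("`level` exceeds the number of levels")
  act <- rep(TRUE, tree$n_leaves + level)
  if (level > 0) for (l in seq_len(level)) {
    act[tree$merges[l, ]] <- FALSE
  }
  ids <- which(act)
  ids[ids <= tree$n_leaves + level]
}

#' Score vectors of arbitrary tree variables
#'
#' @param tree an `"hpca"` fit.
#' @param ids variable identifiers (leaves `1..V`, sums `V + level`).
#' @returns Matrix with one row per id: standardized leaf scores for leaves,
#'   sum-variable scores for internal nodes.
#' @export
variable_scores <- function(tree, ids) {
  stopifnot(inherits(tree, "hpca"))
  v <- tree$n_leaves
  out <- matrix(0, length(ids), tree$n_obs)
  for (i in seq_along(ids)) {
    id <- ids[i]
    out[i, ] <- if (id <= v) tree$leaf_scores[id, ]
                else tree$sum_scores[id - v, ]
  }
  rownames(out) <- ids
  out
}

# list: for every internal node (level), the sorted leaf ids under it
leaf_sets <- function(tree) {
  v <- tree$n_leaves
  sets <- vector("list", tree$n_levels)
  get <- function(id) if (id <= v) id else sets[[id - v]]
  for (l in seq_len(tree$n_levels))
    sets[[l]] <- sort(c(get(tree$merges[l, 1L]), get(tree$merges[l, 2L])))
  sets
}

#' @export
print.hpca <- function(x, ...) {
  cat(sprintf("Treelet hPCA: %d variables, %d observations, %d level(s)\n",
              x$n_leaves, x$n_obs, x$n_levels))
  cat(sprintf("  merge similarity range: [%.3f, %.3f]\n",
              min(x$r), max(x$r)))
  if (length(x$degenerate))
    cat(sprintf("  %d degenerate merge(s)\n", length(x$degenerate)))
  invisible(x)
}

#' Summarize an hPCA fit, with optional level filtering
#'
#' @param object an `"hpca"` fit.
#' @param gamma,alpha_fwe when both supplied, runs [filter_levels()] and
#'   reports the base level and significant/unrelated levels.
#' @param ... unused.
#' @export
summary.hpca <- function(object, gamma = NULL, alpha_fwe = NULL, ...) {
  out <- list(fit = object)
  if (!is.null(gamma) && !is.null(alpha_fwe))
    out$filter <- filter_levels(object, gamma = gamma, alpha_fwe = alpha_fwe)
  class(out) <- "summary.hpca"
  out
}

#' @export
print.summary.hpca <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$filter)) print(x$filter)
  invisible(x)
}

#' Convert an hPCA fit to an hclust tree
#'
#' Heights are `1 - r` (one minus the merge similarity). Treelet merge
#' heights are not guaranteed monotone; plotting still works but crossing
#' branches may occur.
#'
#' @param x an `"hpca"` fit spanning all `V - 1` levels.
#' @param ... unused.
#' @returns An object of class `"hclust"`.
#' @export
as.hclust.hpca <- function(x, ...) {
  if (x$n_levels != x$n_leaves - 1L)
    stop_("only a full hierarchy (V - 1 levels) converts to hclust")
  v <- x$n_leaves
  merge <- matrix(0L, v - 1L, 2L)
  for (l in seq_len(v - 1L)) {
    id <- x$merges[l, ]
    merge[l, ] <- ifelse(id <= v, -id, id - v)
  }
  structure(list(merge = merge, height = 1 - x$r, order = hclust_order(merge, v),
                 labels = as.character(seq_len(v)), method = "treelet",
                 call = match.call(), dist.method = "1 - signed correlation"),
            class = "hclust")
}

# leaf ordering by left-to-right traversal from the root merge
hclust_order <- function(merge, v) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(v - 1L)
}

#' Plot the hPCA dendrogram
#'
#' @param x an `"hpca"` fit (full hierarchy).
#' @param ... passed to [stats::plot.hclust()] via `plot`.
#' @export
plot.hpca <- function(x, ...) {
  plot(stats::as.hclust(x), ...)
  invisible(x)
}

#' Export the merge table or a Newick dendrogram
#'
#' @param tree an `"hpca"` fit.
#' @param file optional path; when given and `format = "newick"`, requires
#'   the \pkg{ape} package.
#' @param format `"merge"` (4-column data frame: children, height `1 - r`,
#'   cluster size) or `"newick"`.
#' @returns The merge data frame, or (for `"newick"`) the Newick string,
#'   invisibly when written to `file`.
#' @export
export_dendrogram <- function(tree, file = NULL, format = c("merge", "newick")) {
  stopifnot(inherits(tree, "hpca"))
  format <- match.arg(format)
  sizes <- vapply(leaf_sets(tree), length, 1L)
  tab <- data.frame(child_a = tree$merges[, 1L], child_b = tree$merges[, 2L],
                    height = 1 - tree$r, size = sizes)
  if (format == "merge") {
    if (!is.null(file)) {
      utils::write.csv(tab, file, row.names = FALSE)
      return(invisible(tab))
    }
    return(tab)
  }
  if (!requireNamespace("ape", quietly = TRUE))
    stop_("Newick export requires the 'ape' package")
  phy <- ape::as.phylo(stats::as.hclust(tree))
  if (!is.null(file)) {
    ape::write.tree(phy, file = file)
    return(invisible(ape::write.tree(phy)))
  }
  ape::write.tree(phy)
}
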