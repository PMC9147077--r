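# Hierarchical clustering of quantitative variables by the first-principal-
# component homogeneity criterion: the homogeneity of a cluster is the sum
# of squared Pearson correlations between its variables and the cluster's
# first principal component, which equals the largest eigenvalue of the
# cluster's correlation matrix.

#' Homogeneity of a block of quantitative variables
#'
#' `H = sum_j r^2(x_j, y)`, where `y` is the block's first principal
#' component; for standardized quantitative variables this equals the
#' largest eigenvalue of the block's Pearson correlation matrix, so
#' `1 <= H <= p`. A single variable has `H = 1`; `p` copies of one variable
#' have `H = p`; a two-variable block has the closed form `H = 1 + |rho|`.
#'
#' @param X a samples-by-variables numeric matrix (at least one column,
#'   each with nonzero variance).
#' @return the homogeneity (largest correlation eigenvalue).
#' @examples
#' x <- rnorm(30)
#' homogeneity(cbind(x, x, x))  # 3
#' @export
homogeneity <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) .stopf("need at least one variable")
  v <- apply(X, 2, stats::var)
  if (any(v < .Machine$double.eps))
    .stopf("degenerate variable(s) with zero variance: column %s",
           paste(which(v < .Machine$double.eps), collapse = ", "))
  if (ncol(X) == 1L) return(1)
  eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values[1]
}

#' Cluster variables by homogeneity loss
#'
#' Agglomerative clustering of the columns of `X`: starting from
#' singletons, each step merges the pair of clusters (A, B) minimizing the
#' homogeneity loss `d(A, B) = H(A) + H(B) - H(A union B)`, which is
#' non-negative, and records `d` as the merge height. Ties (within 1e-10)
#' are broken by lexicographic order of the clusters' smallest variable
#' names, so the tree is invariant to column order up to that rule.
#'
#' @param X a samples-by-variables matrix (>= 2 columns); columns are
#'   standardized internally.
#' @return a [ClusterTree].
#' @seealso [cutVarTree()], [homogeneity()]
#' @examples
#' set.seed(1)
#' a <- rnorm(40); b <- rnorm(40)
#' X <- cbind(a1 = a, a2 = a + rnorm(40, 0, 0.1),
#'            b1 = b, b2 = b + rnorm(40, 0, 0.1))
#' tree <- hclustVariables(X)
#' clusterGroups(cutVarTree(tree, 2))
#' @export
hclustVariables <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2L) .stopf("need at least 2 variables")
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  colnames(X) <- labels
  v <- apply(X, 2, stats::var)
  if (any(v < .Machine$double.eps))
    .stopf("degenerate variable(s) with zero variance: %s",
           paste(labels[v < .Machine$double.eps], collapse = ", "))
  Xs <- scale(X)

  members <- as.list(seq_len(p))     # column indices per active cluster
  ids <- -seq_len(p)                 # hclust convention: negatives = leaves
  H <- rep(1, p)
  minlab <- labels                   # tie-break key per cluster
  merges <- matrix(0L, p - 1L, 2L)
  heights <- numeric(p - 1L)

  H_union <- function(a, b) homogeneity(Xs[, c(members[[a]], members[[b]]),
                                            drop = FALSE])
  for (step in seq_len(p - 1L)) {
    n_act <- length(members)
    best <- NULL
    for (a in seq_len(n_act - 1L)) for (b in (a + 1L):n_act) {
      d <- H[a] + H[b] - H_union(a, b)
      cand_key <- sort(c(minlab[a], minlab[b]))
      better <- is.null(best) || d < best$d - 1e-10 ||
        (d < best$d + 1e-10 &&
           (cand_key[1] < best$key[1] ||
              (cand_key[1] == best$key[1] && cand_key[2] < best$key[2])))
      if (better) best <- list(a = a, b = b, d = d, key = cand_key)
    }
    a <- best$a; b <- best$b
    merges[step, ] <- c(ids[a], ids[b])
    heights[step] <- max(best$d, 0)
    members[[a]] <- c(members[[a]], members[[b]])
    H[a] <- H[a] + H[b] - best$d
    minlab[a] <- min(minlab[a], minlab[b])
    ids[a] <- step
    members[[b]] <- NULL
    H <- H[-b]; minlab <- minlab[-b]; ids <- ids[-b]
  }
  new("ClusterTree", merges = merges, heights = heights, labels = labels,
      data = Xs)
}

#' Suggest a group count from the merge heights
#'
#' Secondary, automatic rule for choosing `k`: the cut just before the
#' merge with the largest relative increase in homogeneity loss over the
#' previous merge. Intended as a sanity check on a hand-picked `k`, not a
#' replacement for it.
#'
#' @param tree a [ClusterTree].
#' @param k_max largest group count considered.
#' @return the suggested number of groups.
#' @export
suggestK <- function(tree, k_max = length(tree@labels) - 1L) {
  stopifnot(is(tree, "ClusterTree"))
  h <- pmax(tree@heights, 1e-12)
  n <- length(tree@labels)
  jumps <- h[-1] / h[-length(h)]          # jump entering merge m + 1
  ks <- n - seq_along(jumps)              # cutting before that merge
  ok <- ks <= k_max
  ks[ok][which.max(jumps[ok])]
}

#' Cut a variable-clustering tree into k groups
#'
#' Returns the partition obtained by undoing the last `k - 1` merges.
#' Groups are numbered 1..k by the order of their first variable in the
#' original column order, and each group's homogeneity is reported.
#'
#' @param tree a [ClusterTree].
#' @param k number of groups, `1 <= k <=` number of variables.
#' @return a [ClusterAssignment].
#' @export
cutVarTree <- function(tree, k) {
  stopifnot(is(tree, "ClusterTree"))
  n <- length(tree@labels)
  k <- as.integer(k)
  if (k < 1L || k > n) .stopf("k must lie in 1..%d", n)
  groups <- as.list(seq_len(n))
  alive <- rep(TRUE, n)
  merged <- vector("list", n - 1L)
  for (step in seq_len(n - k)) {
    left <- tree@merges[step, 1]; right <- tree@merges[step, 2]
    get_members <- function(id) if (id < 0) id * -1L else merged[[id]]$m
    m <- c(get_members(left), get_members(right))
    if (left < 0) alive[-left] <- FALSE else merged[[left]]$alive <- FALSE
    if (right < 0) alive[-right] <- FALSE else merged[[right]]$alive <- FALSE
    merged[[step]] <- list(m = m, alive = TRUE)
  }
  clusters <- c(lapply(which(alive), identity),
                lapply(Filter(function(x) !is.null(x) && x$alive, merged),
                       function(x) x$m))
  clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  assignment <- integer(n)
  for (g in seq_along(clusters)) assignment[clusters[[g]]] <- g
  names(assignment) <- tree@labels
  hom <- vapply(clusters, function(m)
    homogeneity(tree@data[, m, drop = FALSE]), numeric(1))
  new("ClusterAssignment", assignment = assignment, k = k, homogeneity = hom)
}
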