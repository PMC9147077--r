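# The headline procedure: bootstrap distributions of the first regularized
# canonical correlation per gene cluster against the vigor-trait block, a
# per-timepoint consistency check, and the letter-based ranking of groups.

#' Pair the expression and trait blocks sample-by-sample
#'
#' Builds the two aligned analysis blocks: `X` holds the log2RQ rows of the
#' imbibition samples at the selected timepoints; `Y` holds, for each such
#' sample, its lot's row of the vigor-trait matrix (lot-level traits are
#' broadcast to every matching expression sample). Columns of both blocks
#' are standardized. With `pairing = "replicate"` a replicate-level trait
#' table is consulted instead and trait replicate `i` is matched to
#' expression replicate `i` (falling back to the lot mean where a trait has
#' no replicate `i`).
#'
#' @param expr an [ExpressionMatrix].
#' @param traits a [TraitMatrix] covering every (cultivar, lot) present in
#'   the selected samples.
#' @param times imbibition timepoints (h) to include.
#' @param pairing `"broadcast"` (default) or `"replicate"`.
#' @param trait_replicates a [TraitReplicateTable], required for
#'   `pairing = "replicate"`.
#' @return a list with the standardized matrices `X` (samples x genes) and
#'   `Y` (samples x traits) and `samples`, the row alignment.
#' @examples
#' design <- designConfig(rng_seed = 1)
#' effect <- effectConfig(design)
#' expr <- relativeExpression(generateCqTable(design, effect))
#' tm <- assembleTraitMatrix(generateTraitReplicates(design, effect))
#' blocks <- pairedBlocks(expr, tm)
#' dim(blocks$X); dim(blocks$Y)
#' @export
pairedBlocks <- function(expr, traits, times = c(6, 10),
                         pairing = c("broadcast", "replicate"),
                         trait_replicates = NULL) {
  stopifnot(is(expr, "ExpressionMatrix"), is(traits, "TraitMatrix"))
  pairing <- match.arg(pairing)
  info <- sampleInfo(expr)
  sel <- info$time_h %in% times
  if (!any(sel)) .stopf("no expression samples at timepoint(s) %s",
                        paste(times, collapse = ", "))
  info <- info[sel, , drop = FALSE]
  X <- t(log2rq(expr)[, sel, drop = FALSE])

  key <- paste(info$cultivar, info$lot)
  trait_key <- paste(traits@keys$cultivar, traits@keys$lot)
  row_idx <- match(key, trait_key)
  if (anyNA(row_idx))
    .stopf("lot(s) missing from the trait matrix: %s",
           paste(unique(key[is.na(row_idx)]), collapse = "; "))
  Y <- traits@values[row_idx, , drop = FALSE]

  if (pairing == "replicate") {
    if (is.null(trait_replicates))
      .stopf("pairing = 'replicate' needs a trait_replicates table")
    tr <- trait_replicates@records
    for (j in colnames(Y)) {
      sub <- tr[tr$trait == j, ]
      if (!nrow(sub)) next
      m <- match(paste(info$cultivar, info$lot, info$rep),
                 paste(sub$cultivar, sub$lot, sub$replicate))
      Y[!is.na(m), j] <- sub$value[m[!is.na(m)]]
    }
  }

  X <- scale(X)
  Y <- scale(Y)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    .stopf("zero-variance column after pairing; check the selected samples")
  rownames(X) <- rownames(Y) <- NULL
  list(X = X, Y = Y, samples = info)
}

#' Bootstrap the first canonical correlation of a gene group
#'
#' Draws `B` bootstrap resamples of the aligned sample rows -- jointly from
#' `(X, Y)`, preserving the expression-trait coupling -- and records the
#' first regularized canonical correlation of each refit. Resamples in
#' which any column becomes constant are redrawn (and counted), so the
#' distribution always holds exactly `B` values.
#'
#' @param X samples-by-genes block (one gene cluster, or the full panel).
#' @param Y samples-by-traits block, row-aligned with `X`.
#' @param B number of resamples (default 10000).
#' @param lambda_x,lambda_y ridge constants for every fit.
#' @param seed RNG seed; the same seed reproduces the vector exactly.
#' @param group,genes identifiers stored with the result.
#' @param squared record the first squared canonical correlation (the
#'   eigenvalue itself) instead of its square root.
#' @param indices optional `B x n` integer matrix of resample rows,
#'   overriding the RNG (intended for tests and exact reproduction).
#' @return a [BootstrapRho].
#' @examples
#' design <- designConfig(rng_seed = 1)
#' effect <- effectConfig(design)
#' expr <- relativeExpression(generateCqTable(design, effect))
#' tm <- assembleTraitMatrix(generateTraitReplicates(design, effect))
#' blk <- pairedBlocks(expr, tm)
#' bootstrapRho1(blk$X, blk$Y, B = 50, seed = 1)
#' @export
bootstrapRho1 <- function(X, Y, B = 10000L, lambda_x = 0.1, lambda_y = 0.1,
                          seed = NULL, group = "all",
                          genes = colnames(X), squared = FALSE,
                          indices = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  B <- as.integer(B)
  if (B <= 0L) .stopf("B must be a positive integer")
  n <- nrow(X)
  if (nrow(Y) != n) .stopf("X and Y must have the same sample rows")
  if (!is.null(indices)) {
    indices <- matrix(as.integer(indices), nrow = B)
    if (ncol(indices) != n) .stopf("indices must be a B x n matrix")
  }
  run <- function() {
    rho <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- if (!is.null(indices)) indices[b, ] else
          sample.int(n, n, replace = TRUE)
        core <- .rccaCore(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                          lambda_x, lambda_y, standardize = TRUE,
                          want_weights = FALSE)
        if (!is.null(core) && !inherits(core, "singular")) break
        if (!is.null(indices))
          .stopf("supplied resample %d is degenerate (constant column)", b)
        redraws <- redraws + 1L
        if (redraws > 100L * B)
          .stopf("too many degenerate resamples; blocks look constant")
      }
      rho[b] <- if (squared) core$rho[1]^2 else core$rho[1]
    }
    list(rho = rho, redraws = redraws)
  }
  out <- .withSeed(seed, run())
  new("BootstrapRho", group = as.character(group),
      genes = as.character(if (is.null(genes)) character() else genes),
      rho1 = out$rho, B = B,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      lambda_x = lambda_x, lambda_y = lambda_y, n = as.integer(n),
      redraws = out$redraws)
}

#' Per-timepoint consistency of the expression-vigor association
#'
#' Runs the bootstrap of the first regularized canonical correlation with
#' the full gene block at each imbibition timepoint separately and checks
#' that both mean correlations exceed a threshold (default 0.7). Passing
#' indicates that the association between expression and vigor looks the
#' same at the two germination times, justifying pooling them downstream.
#' The verdict is symmetric in the timepoints.
#'
#' @param expr an [ExpressionMatrix] containing samples at every requested
#'   timepoint.
#' @param traits a [TraitMatrix].
#' @param times the timepoints to compare (default 6 h and 10 h).
#' @param B,lambda_x,lambda_y,seed bootstrap settings, see
#'   [bootstrapRho1()].
#' @param threshold mean-correlation bound for the pass verdict.
#' @return a list with `means` (named by timepoint), `pass`, `threshold`
#'   and `dists`, the per-timepoint [BootstrapRho] objects.
#' @export
timeConsistency <- function(expr, traits, times = c(6, 10), B = 10000L,
                            lambda_x = 0.1, lambda_y = 0.1, seed = NULL,
                            threshold = 0.7) {
  info <- sampleInfo(expr)
  missing <- setdiff(times, unique(info$time_h))
  if (length(missing))
    .stopf("expression matrix has no samples at timepoint(s): %s h",
           paste(missing, collapse = ", "))
  dists <- lapply(seq_along(times), function(i) {
    blk <- pairedBlocks(expr, traits, times = times[i])
    bootstrapRho1(blk$X, blk$Y, B = B, lambda_x = lambda_x,
                  lambda_y = lambda_y,
                  seed = if (is.null(seed)) NULL else seed + i,
                  group = paste0("t", times[i], "h"))
  })
  means <- vapply(dists, function(d) mean(d@rho1), numeric(1))
  names(means) <- paste0(times, "h")
  list(means = means, pass = all(means > threshold), threshold = threshold,
       dists = dists)
}

#' Rank gene groups by their bootstrap association with vigor
#'
#' Pools the bootstrap first-canonical-correlation values of all groups,
#' runs a one-way ANOVA with Tukey HSD compact letters ([tukeyLetters()]),
#' and ranks groups by mean. All groups must carry the same number of
#' resamples. Note the recorded caveat: treating bootstrap resamples as
#' independent observations makes the letters descriptive, not inferential.
#'
#' @param dists a list of [BootstrapRho] objects (>= 2), one per group,
#'   with equal `B`.
#' @param alpha significance level for the letter display.
#' @return a [GroupRanking].
#' @export
rankGroups <- function(dists, alpha = 0.05) {
  if (length(dists) < 2L) .stopf("need at least 2 groups to rank")
  stopifnot(all(vapply(dists, is, logical(1), "BootstrapRho")))
  Bs <- vapply(dists, function(d) d@B, integer(1))
  if (length(unique(Bs)) != 1L)
    .stopf("resample counts differ across groups: %s",
           paste(Bs, collapse = ", "))
  grp <- vapply(dists, function(d) d@group, character(1))
  if (anyDuplicated(grp)) .stopf("duplicated group identifiers")
  values <- unlist(lapply(dists, function(d) d@rho1))
  groups <- rep(grp, each = Bs[1])
  lett <- tukeyLetters(values, groups, alpha = alpha)
  means <- vapply(dists, function(d) mean(d@rho1), numeric(1))
  sds <- vapply(dists, function(d) sd(d@rho1), numeric(1))
  tab <- data.frame(group = grp, mean_rho1 = means, sd_rho1 = sds,
                    letters = unname(lett[grp]),
                    rank = rank(-means, ties.method = "first"))
  top <- tab$group[tab$rank == 1L]
  new("GroupRanking", table = tab, top_group = top,
      top_genes = dists[[which(grp == top)]]@genes, alpha = alpha,
      note = paste("Tukey letters treat bootstrap resamples as independent",
                   "observations; they are descriptive, not inferential."))
}
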