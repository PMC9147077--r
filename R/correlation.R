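# Gene-gene Spearman correlation and the thresholded co-expression network.

#' Spearman correlation matrix over genes
#'
#' Rank correlation (average ranks for ties) between all target-gene pairs
#' over the pooled imbibition samples, with pairwise-complete handling of
#' missing cells and two-sided p-values from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))`. Because Spearman correlation is
#' invariant to monotone transforms, RQ and log2RQ give identical matrices.
#'
#' @param expr an [ExpressionMatrix], or a samples-by-genes numeric matrix.
#' @param times imbibition timepoints (h) to pool when `expr` is an
#'   [ExpressionMatrix]; defaults to all timepoints > 0.
#' @return a [CorrMatrix].
#' @examples
#' design <- designConfig(rng_seed = 1)
#' expr <- relativeExpression(generateCqTable(design, effectConfig(design)))
#' cm <- spearmanMatrix(expr)
#' cm
#' @export
spearmanMatrix <- function(expr, times = NULL) {
  if (is(expr, "ExpressionMatrix")) {
    info <- sampleInfo(expr)
    if (is.null(times)) times <- setdiff(unique(info$time_h), 0)
    X <- t(log2rq(expr)[, info$time_h %in% times, drop = FALSE])
  } else {
    X <- as.matrix(expr)
  }
  genes <- colnames(X)
  if (is.null(genes)) genes <- paste0("V", seq_len(ncol(X)))
  const <- apply(X, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && max(x) - min(x) < .Machine$double.eps
  })
  if (any(const))
    .warnf("constant column(s), correlations undefined: %s",
           paste(genes[const], collapse = ", "))
  n_eff <- crossprod(!is.na(X))
  if (any(n_eff[upper.tri(n_eff)] < 3))
    .warnf("some gene pairs have fewer than 3 complete samples")
  r <- suppressWarnings(cor(X, method = "spearman",
                            use = "pairwise.complete.obs"))
  tstat <- r * sqrt(pmax(n_eff - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = pmax(n_eff - 2, 1))
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(r) <- 1
  diag(p) <- NA_real_
  dimnames(r) <- dimnames(p) <- dimnames(n_eff) <- list(genes, genes)
  new("CorrMatrix", genes = genes, r = r, p = p,
      n_eff = matrix(as.numeric(n_eff), nrow(n_eff),
                     dimnames = dimnames(n_eff)))
}

#' Threshold a correlation matrix into an edge list
#'
#' Keeps undirected gene pairs with `r > r_min` (signed by default -- the
#' display convention for "high and positive" co-expression networks; set
#' `absolute = TRUE` to threshold `|r|`) and `p <= alpha`. Self-edges are
#' never reported. Lowering `r_min` can only add edges.
#'
#' @param corr a [CorrMatrix].
#' @param r_min correlation threshold (default 0.70).
#' @param alpha significance threshold on the pair's p-value.
#' @param absolute threshold `|r|` instead of `r`.
#' @return a `data.frame` with columns `gene1`, `gene2`, `r`, `p`, ordered
#'   by decreasing `r`.
#' @export
thresholdEdges <- function(corr, r_min = 0.70, alpha = 0.05,
                           absolute = FALSE) {
  stopifnot(is(corr, "CorrMatrix"))
  r <- corr@r; p <- corr@p
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]; pv <- p[ut]
  keep <- !is.na(rv) & !is.na(pv) &
    (if (absolute) abs(rv) else rv) > r_min & pv <= alpha
  out <- data.frame(gene1 = corr@genes[ut[keep, 1]],
                    gene2 = corr@genes[ut[keep, 2]],
                    r = rv[keep], p = pv[keep])
  out[order(-out$r), , drop = FALSE]
}
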