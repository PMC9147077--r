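# Relative quantification by 2^-ddCt with multi-reference normalization,
# and the pair-wise fixed-reallocation randomization test for expression
# ratios.

.sampleKey <- function(df) paste(df$cultivar, df$lot, df$time_h, df$rep, sep = "\r")

#' Mean reference-gene Cq of a sample
#'
#' Combines the reference genes of one sample by the arithmetic mean of
#' their Cq values, which at amplification efficiency 2 corresponds to the
#' geometric mean of the linear quantities.
#'
#' @param table a [CqTable].
#' @param cultivar,lot,time_h,rep the sample key.
#' @return the mean reference Cq (cycles).
#' @examples
#' tab <- CqTable(data.frame(cultivar = "cv1", lot = "lot1", time_h = 0,
#'                           rep = 1, gene = c("REF1", "REF2"),
#'                           role = "reference", cq = c(19, 21)))
#' referenceCq(tab, "cv1", "lot1", 0, 1)  # 20
#' @export
referenceCq <- function(table, cultivar, lot, time_h, rep) {
  stopifnot(is(table, "CqTable"))
  df <- table@records
  sel <- df$role == "reference" & df$cultivar == cultivar & df$lot == lot &
    df$time_h == time_h & df$rep == rep & !is.na(df$cq)
  if (!any(sel))
    .stopf("no reference Cq measured for sample (%s, %s, %s h, rep %s)",
           cultivar, lot, time_h, rep)
  mean(df$cq[sel])
}

# Per-sample mean reference Cq for a whole table; errors on samples with
# no usable reference reaction.
.referenceCqBySample <- function(df) {
  refs <- df[df$role == "reference" & !is.na(df$cq), ]
  all_keys <- unique(.sampleKey(df))
  ref_mean <- tapply(refs$cq, .sampleKey(refs), mean)
  miss <- setdiff(all_keys, names(ref_mean))
  if (length(miss))
    .stopf("no reference Cq measured for sample(s): %s",
           paste(gsub("\r", "/", miss), collapse = "; "))
  ref_mean
}

#' Relative expression by the 2^-ddCt method
#'
#' For every target gene and sample, `dCt = Cq_target - mean reference Cq`;
#' `ddCt = dCt - mean dCt of the control group`; `RQ = 2^-ddCt`. The
#' control group defaults to the dry seeds (first timepoint) of lot 1 of
#' the same cultivar; `control = "own_lot"` instead normalizes each lot to
#' its own dry seeds. Amplification efficiency is fixed at 2 and missing Cq
#' values propagate to `NA` cells -- they are never imputed.
#'
#' @param table a [CqTable] containing control replicates for every
#'   cultivar and every target gene.
#' @param control `"lot1"` (dry seeds of lot 1 per cultivar) or
#'   `"own_lot"` (dry seeds of each lot).
#' @param control_time timepoint (h) of the control group.
#' @return an [ExpressionMatrix] (genes x samples) with assays `RQ` and
#'   `log2RQ` and the control definition in `metadata()`.
#' @examples
#' design <- designConfig(rng_seed = 1)
#' expr <- relativeExpression(generateCqTable(design, effectConfig(design)))
#' expr
#' @export
relativeExpression <- function(table, control = c("lot1", "own_lot"),
                               control_time = NULL) {
  stopifnot(is(table, "CqTable"))
  control <- match.arg(control)
  df <- table@records
  if (!nrow(df)) .stopf("empty Cq table")
  if (is.null(control_time)) control_time <- min(df$time_h)
  ref_mean <- .referenceCqBySample(df)

  tg <- df[df$role == "target", ]
  tg$dct <- tg$cq - unname(ref_mean[.sampleKey(tg)])

  lot1 <- sort(unique(df$lot))[1]
  is_ctrl <- tg$time_h == control_time &
    (if (control == "lot1") tg$lot == lot1 else TRUE)
  ctrl <- tg[is_ctrl & !is.na(tg$dct), ]
  ctrl_key <- if (control == "lot1") paste(ctrl$cultivar, ctrl$gene)
              else paste(ctrl$cultivar, ctrl$lot, ctrl$gene)
  ctrl_mean <- tapply(ctrl$dct, ctrl_key, mean)

  want_key <- if (control == "lot1") paste(tg$cultivar, tg$gene)
              else paste(tg$cultivar, tg$lot, tg$gene)
  miss <- unique(tg$gene[!(want_key %in% names(ctrl_mean))])
  if (length(miss))
    .stopf("gene(s) absent from the control group: %s",
           paste(miss, collapse = ", "))
  tg$ddct <- tg$dct - unname(ctrl_mean[want_key])

  genes <- sort(unique(tg$gene))
  samples <- unique(tg[c("cultivar", "lot", "time_h", "rep")])
  samples <- samples[order(samples$cultivar, samples$lot, samples$time_h,
                           samples$rep), ]
  rownames(samples) <- NULL
  sid <- .sampleKey(samples)
  log2rq_m <- matrix(NA_real_, length(genes), nrow(samples),
                     dimnames = list(genes, paste0("S", seq_len(nrow(samples)))))
  idx <- cbind(match(tg$gene, genes), match(.sampleKey(tg), sid))
  log2rq_m[idx] <- -tg$ddct
  rq_m <- 2^log2rq_m

  se <- SummarizedExperiment(
    assays = list(RQ = rq_m, log2RQ = log2rq_m),
    colData = DataFrame(samples))
  md <- list(control = control, control_time = control_time,
             control_lot = if (control == "lot1") lot1 else "own",
             method = "2^-ddCt, efficiency 2, reference Cq arithmetic mean")
  metadata(se) <- md
  new("ExpressionMatrix", se)
}

#' Pair-wise fixed-reallocation randomization test
#'
#' Tests whether the expression ratio between two groups differs from 1.
#' Each replicate is a (target Cq, reference Cq) pair that is reallocated
#' between the groups as a unit; the statistic is the absolute log2
#' expression ratio `|mean(dCt_control) - mean(dCt_treated)|`. When the
#' number of distinct group reallocations is at most `n_perm` all of them
#' are enumerated and the exact proportion of reallocations with a
#' statistic at least as large as the observed one is returned; otherwise
#' `n_perm` random reallocations are drawn and
#' `p = (1 + #greater) / (1 + n_perm)`.
#'
#' @param control_cq,treated_cq two-column numeric matrices or data frames
#'   (target Cq, reference Cq), one row per replicate; at least two
#'   replicates per group.
#' @param n_perm maximum number of reallocations before switching from
#'   exhaustive enumeration to Monte Carlo sampling.
#' @param seed optional RNG seed for the Monte Carlo branch.
#' @return a list with elements `p.value`, `statistic` (the absolute log2
#'   ratio), `exhaustive`, and `n_realloc` (reallocations evaluated).
#' @examples
#' ctl <- cbind(c(24.1, 24.3, 24.0), c(20.0, 20.1, 19.9))
#' trt <- cbind(c(22.9, 23.1, 23.0), c(20.1, 20.0, 20.0))
#' randomizationTest(ctl, trt)$p.value
#' @export
randomizationTest <- function(control_cq, treated_cq, n_perm = 2000L,
                              seed = NULL) {
  as_pairs <- function(x, what) {
    x <- as.matrix(x)
    if (ncol(x) != 2L)
      .stopf("%s must have two columns (target Cq, reference Cq)", what)
    storage.mode(x) <- "double"
    x
  }
  ctl <- as_pairs(control_cq, "control_cq")
  trt <- as_pairs(treated_cq, "treated_cq")
  if (nrow(ctl) < 2L || nrow(trt) < 2L)
    .stopf("need at least 2 replicates per group")
  d_c <- ctl[, 1] - ctl[, 2]
  d_t <- trt[, 1] - trt[, 2]
  pooled <- c(d_c, d_t)
  n1 <- length(d_c); n <- length(pooled)
  obs <- abs(mean(d_c) - mean(d_t))
  if (max(pooled) - min(pooled) < 1e-12) {
    .warnf("degenerate groups: all replicate dCt values identical; p = 1")
    return(list(p.value = 1, statistic = obs, exhaustive = TRUE,
                n_realloc = 1L))
  }
  tot <- sum(pooled)
  stat_of <- function(idx_mat) {
    # idx_mat: n1 x m matrix of group-1 member indices
    s1 <- colSums(matrix(pooled[idx_mat], nrow = n1))
    abs(s1 / n1 - (tot - s1) / (n - n1))
  }
  n_comb <- choose(n, n1)
  eps <- 1e-12
  if (n_comb <= n_perm) {
    idx <- combn(n, n1)
    stats <- stat_of(idx)
    p <- mean(stats >= obs - eps)
    list(p.value = p, statistic = obs, exhaustive = TRUE,
         n_realloc = as.integer(n_comb))
  } else {
    stats <- .withSeed(seed, {
      idx <- replicate(n_perm, sample.int(n, n1))
      stat_of(idx)
    })
    p <- (1 + sum(stats >= obs - eps)) / (1 + n_perm)
    list(p.value = p, statistic = obs, exhaustive = FALSE,
         n_realloc = as.integer(n_perm))
  }
}
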