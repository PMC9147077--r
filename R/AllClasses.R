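#' @import methods
#' @importFrom stats aov TukeyHSD cor pt sd quantile rnorm runif rbinom
#'   setNames aggregate complete.cases
#' @importFrom utils combn read.csv write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# ---------------------------------------------------------------------------
# Study design and effect configuration
# ---------------------------------------------------------------------------

#' @title Study design configuration
#'
#' @description
#' `DesignConfig` describes the layout of a germination *sensu stricto*
#' study: which cultivars and lots are sampled, the imbibition timepoints,
#' how many qPCR replicates are run per sample, the size of the target and
#' reference gene panels, which vigor traits are phenotyped and the
#' germination test conditions. It is consumed by the synthetic-data
#' generators and carries the RNG seed that makes them reproducible.
#'
#' @slot cultivars cultivar labels.
#' @slot lots_per_cultivar number of seed lots per cultivar.
#' @slot qpcr_reps biological replicates per (cultivar, lot, timepoint).
#' @slot timepoints_h imbibition timepoints in hours, strictly increasing;
#'   the first is the dry-seed control (0 h).
#' @slot n_target_genes,n_reference_genes size of the gene panels.
#' @slot trait_names unique names of the phenotyped vigor traits.
#' @slot trait_reps replicates per trait and lot.
#' @slot germination_conditions labels of the germination test conditions.
#' @slot germ_reps replicates per germination condition.
#' @slot seeds_per_rep seeds sown per germination replicate.
#' @slot rng_seed integer seed for the generators.
#'
#' @seealso [designConfig()]
#' @export
setClass("DesignConfig", slots = c(
  cultivars = "character",
  lots_per_cultivar = "integer",
  qpcr_reps = "integer",
  timepoints_h = "numeric",
  n_target_genes = "integer",
  n_reference_genes = "integer",
  trait_names = "character",
  trait_reps = "integer",
  germination_conditions = "character",
  germ_reps = "integer",
  seeds_per_rep = "integer",
  rng_seed = "integer"
))

setValidity("DesignConfig", function(object) {
  msg <- character()
  counts <- c(
    lots_per_cultivar = object@lots_per_cultivar,
    qpcr_reps = object@qpcr_reps,
    n_target_genes = object@n_target_genes,
    n_reference_genes = object@n_reference_genes,
    trait_reps = object@trait_reps,
    germ_reps = object@germ_reps,
    seeds_per_rep = object@seeds_per_rep
  )
  if (length(object@cultivars) < 1L) msg <- c(msg, "need at least one cultivar")
  bad <- counts < 1L | is.na(counts)
  if (any(bad))
    msg <- c(msg, paste0("counts must be >= 1: ",
                         paste(names(counts)[bad], collapse = ", ")))
  if (length(object@timepoints_h) < 1L ||
      any(diff(object@timepoints_h) <= 0))
    msg <- c(msg, "timepoints_h must be strictly increasing")
  if (anyDuplicated(object@trait_names))
    msg <- c(msg, "trait_names must be unique")
  if (length(msg)) msg else TRUE
})

#' @title Latent-effect configuration for the synthetic-data generators
#'
#' @description
#' `EffectConfig` parameterizes the statistical structure planted into
#' synthetic data: a latent lot-level vigor factor `v`, the subset of target
#' genes whose imbibition-phase expression loads on `v`, block-structured
#' co-expression among genes, and how each vigor trait and the germination
#' speed respond to `v`. All expression effects are on the log2 (Cq) scale.
#'
#' @slot planted_gene_set target genes whose expression at t > 0 increases
#'   with `loading * v`.
#' @slot loading cycles of Cq decrease per unit of latent vigor for planted
#'   genes at imbibition timepoints.
#' @slot vigor_by_lot named numeric, `"<cultivar>.<lot>"` -> latent vigor
#'   value (standardized units).
#' @slot cq_baseline mean quantification cycle of the panel.
#' @slot cq_noise_sd technical + biological Cq noise (cycles), > 0.
#' @slot block_factor_sd sd of the shared per-sample log2 factor within each
#'   co-expression block (drives within-block correlation).
#' @slot gene_blocks named list, block id -> gene ids; a partition of the
#'   target panel.
#' @slot time_trend_log2 named numeric, timepoint (h, as character) ->
#'   shared log2 up-regulation relative to the dry seed.
#' @slot trait_means,trait_sign,trait_magnitude named numeric per trait:
#'   baseline mean, direction of the vigor effect (+1 higher-with-vigor,
#'   -1 lower-with-vigor) and its magnitude in trait units per unit `v`.
#' @slot trait_noise_sd replicate noise, in units of `trait_magnitude`, > 0.
#' @slot t50_base_h named numeric, condition -> t50 (h) at `v = 0`.
#' @slot t50_vigor_slope log-scale decrease of t50 per unit `v`.
#' @slot hill_shape Hill exponent of the generating germination curve.
#' @slot gmax_pct final germination percentage.
#'
#' @seealso [effectConfig()]
#' @export
setClass("EffectConfig", slots = c(
  planted_gene_set = "character",
  loading = "numeric",
  vigor_by_lot = "numeric",
  cq_baseline = "numeric",
  cq_noise_sd = "numeric",
  block_factor_sd = "numeric",
  gene_blocks = "list",
  time_trend_log2 = "numeric",
  trait_means = "numeric",
  trait_sign = "numeric",
  trait_magnitude = "numeric",
  trait_noise_sd = "numeric",
  t50_base_h = "numeric",
  t50_vigor_slope = "numeric",
  hill_shape = "numeric",
  gmax_pct = "numeric"
))

setValidity("EffectConfig", function(object) {
  msg <- character()
  if (!is.finite(object@loading)) msg <- c(msg, "loading must be finite")
  if (!(object@cq_noise_sd > 0)) msg <- c(msg, "cq_noise_sd must be > 0")
  if (!(object@trait_noise_sd > 0)) msg <- c(msg, "trait_noise_sd must be > 0")
  if (object@block_factor_sd < 0) msg <- c(msg, "block_factor_sd must be >= 0")
  if (is.null(names(object@vigor_by_lot)))
    msg <- c(msg, "vigor_by_lot must be named '<cultivar>.<lot>'")
  if (!all(object@trait_sign %in% c(-1, 1)))
    msg <- c(msg, "trait_sign values must be -1 or +1")
  if (any(object@t50_base_h <= 0)) msg <- c(msg, "t50_base_h must be > 0")
  if (!(object@hill_shape > 0)) msg <- c(msg, "hill_shape must be > 0")
  if (!(object@gmax_pct > 0 && object@gmax_pct <= 100))
    msg <- c(msg, "gmax_pct must be in (0, 100]")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Long-format measurement tables
# ---------------------------------------------------------------------------

#' Replicate-level qPCR quantification-cycle records
#'
#' Long-format Cq records keyed by (cultivar, lot, time_h, rep, gene), with
#' each gene flagged as `target` or `reference`. Missing reactions are
#' stored as `NA` Cq values, never dropped silently.
#'
#' @slot records a `data.frame` with columns `cultivar`, `lot`, `time_h`,
#'   `rep`, `gene`, `role`, `cq`.
#' @seealso [CqTable()], [relativeExpression()]
#' @export
setClass("CqTable", slots = c(records = "data.frame"))

.cq_cols <- c("cultivar", "lot", "time_h", "rep", "gene", "role", "cq")

setValidity("CqTable", function(object) {
  df <- object@records
  msg <- character()
  if (!all(.cq_cols %in% names(df)))
    return(paste0("records must have columns: ", paste(.cq_cols, collapse = ", ")))
  if (nrow(df)) {
    if (!all(df$role %in% c("target", "reference")))
      msg <- c(msg, "role must be 'target' or 'reference'")
    bad <- !is.na(df$cq) & (!is.finite(df$cq) | df$cq <= 0)
    if (any(bad)) msg <- c(msg, "cq values must be finite and > 0 (or NA)")
    key <- paste(df$cultivar, df$lot, df$time_h, df$rep, df$gene)
    if (anyDuplicated(key))
      msg <- c(msg, "each (sample, gene) may appear at most once")
  }
  if (length(msg)) msg else TRUE
})

#' Cumulative germination time-course records
#'
#' Long-format observation records of germination tests: for each course
#' (identified by `condition`, `replicate` and optional `cultivar`/`lot`
#' columns), the cumulative number of seeds with root protrusion at each
#' observation time.
#'
#' @slot records a `data.frame` with columns `condition`, `replicate`,
#'   `time_h`, `cumulative`, `total` (plus optional `cultivar`, `lot`).
#' @seealso [GerminationCourses()], [fitHill()], [t50Table()]
#' @export
setClass("GerminationCourses", slots = c(records = "data.frame"))

.germ_cols <- c("condition", "replicate", "time_h", "cumulative", "total")

.courseKey <- function(df) {
  extra <- intersect(c("cultivar", "lot"), names(df))
  do.call(paste, c(df[c(extra, "condition", "replicate")], sep = "\r"))
}

setValidity("GerminationCourses", function(object) {
  df <- object@records
  if (!all(.germ_cols %in% names(df)))
    return(paste0("records must have columns: ", paste(.germ_cols, collapse = ", ")))
  msg <- character()
  if (nrow(df)) {
    if (any(df$time_h <= 0)) msg <- c(msg, "observation times must be > 0")
    if (any(df$cumulative < 0 | df$cumulative > df$total))
      msg <- c(msg, "cumulative counts must lie in [0, total]")
    for (key in unique(.courseKey(df))) {
      sub <- df[.courseKey(df) == key, ]
      sub <- sub[order(sub$time_h), ]
      if (any(diff(sub$time_h) <= 0)) {
        msg <- c(msg, "observation times must be strictly increasing per course")
        break
      }
      if (any(diff(sub$cumulative) < 0)) {
        msg <- c(msg, "cumulative counts must be non-decreasing per course")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Replicate-level vigor-trait records
#'
#' @slot records a `data.frame` with columns `cultivar`, `lot`, `trait`,
#'   `replicate`, `value` and optionally `units`. Percentage traits (names
#'   ending in `_pct`) are bounded to \[0, 100\].
#' @seealso [TraitReplicateTable()], [assembleTraitMatrix()]
#' @export
setClass("TraitReplicateTable", slots = c(records = "data.frame"))

.trait_cols <- c("cultivar", "lot", "trait", "replicate", "value")

setValidity("TraitReplicateTable", function(object) {
  df <- object@records
  if (!all(.trait_cols %in% names(df)))
    return(paste0("records must have columns: ", paste(.trait_cols, collapse = ", ")))
  msg <- character()
  if (nrow(df)) {
    pct <- grepl("_pct$", df$trait)
    if (any(pct & (df$value < 0 | df$value > 100), na.rm = TRUE))
      msg <- c(msg, "percentage traits must lie in [0, 100]")
    if (any(grepl("^ec_", df$trait) & df$value < 0, na.rm = TRUE))
      msg <- c(msg, "conductivities must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Derived containers
# ---------------------------------------------------------------------------

#' Relative-expression matrix (2^-ddCt)
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with target genes as rows and samples as columns, carrying two assays:
#' `RQ` (fold change relative to the dry-seed control group) and `log2RQ`.
#' Sample metadata (`cultivar`, `lot`, `time_h`, `rep`) lives in
#' `colData()`; the control-group definition is recorded in `metadata()`.
#' By construction the mean `log2RQ` over control replicates is 0 for every
#' gene.
#'
#' @seealso [relativeExpression()], [rq()], [log2rq()], [sampleInfo()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!all(c("RQ", "log2RQ") %in% names(assays(object))))
    msg <- c(msg, "assays 'RQ' and 'log2RQ' are required")
  need <- c("cultivar", "lot", "time_h", "rep")
  if (!all(need %in% names(colData(object))))
    msg <- c(msg, paste0("colData must contain: ", paste(need, collapse = ", ")))
  if (all(c("RQ", "log2RQ") %in% names(assays(object)))) {
    rqv <- assay(object, "RQ")
    if (any(rqv <= 0, na.rm = TRUE)) msg <- c(msg, "RQ values must be > 0")
    if (max(abs(log2(rqv) - assay(object, "log2RQ")), na.rm = TRUE) > 1e-8)
      msg <- c(msg, "log2RQ must equal log2(RQ)")
  }
  if (length(msg)) msg else TRUE
})

#' Lot-level vigor-trait matrix
#'
#' One row per (cultivar, lot), one column per trait; every column carries
#' an orientation flag saying whether larger values mean more vigor
#' (`"higher"`) or less (`"lower"`, e.g. electrical conductivity, MDA, t50).
#'
#' @slot values numeric matrix, rows = lots, columns = traits.
#' @slot keys `data.frame` with columns `cultivar`, `lot`, one row per
#'   matrix row.
#' @slot orientation named character, per-column `"higher"`/`"lower"`.
#' @seealso [assembleTraitMatrix()], [traitValues()], [traitOrientation()]
#' @export
setClass("TraitMatrix", slots = c(
  values = "matrix", keys = "data.frame", orientation = "character"
))

setValidity("TraitMatrix", function(object) {
  msg <- character()
  if (nrow(object@keys) != nrow(object@values))
    msg <- c(msg, "keys must have one row per matrix row")
  if (anyDuplicated(paste(object@keys$cultivar, object@keys$lot)))
    msg <- c(msg, "duplicated (cultivar, lot) rows")
  cn <- colnames(object@values)
  if (is.null(cn) || !all(cn %in% names(object@orientation)))
    msg <- c(msg, "orientation must be set for every column")
  if (!all(object@orientation %in% c("higher", "lower")))
    msg <- c(msg, "orientation values must be 'higher' or 'lower'")
  if (length(msg)) msg else TRUE
})

#' Hill fit of a cumulative germination course
#'
#' Parameters of the least-squares fit of
#' `G(t) = gmax * t^shape / (t50^shape + t^shape)` to a cumulative
#' germination percentage curve. `G(t50) = gmax / 2` by construction.
#'
#' @slot gmax final germination percentage, in (0, 100].
#' @slot t50 time to 50% of `gmax`, hours.
#' @slot shape Hill exponent (> 0; `NA` when the fallback was used).
#' @slot rss residual sum of squares (percentage points squared).
#' @slot converged `TRUE` for a converged nonlinear fit, `FALSE` when the
#'   interpolation fallback supplied `t50`.
#' @slot n_obs number of observation times used.
#' @seealso [fitHill()]
#' @export
setClass("HillFit", slots = c(
  gmax = "numeric", t50 = "numeric", shape = "numeric",
  rss = "numeric", converged = "logical", n_obs = "integer"
))

setValidity("HillFit", function(object) {
  msg <- character()
  if (object@converged) {
    if (!(object@gmax > 0 && object@gmax <= 100))
      msg <- c(msg, "gmax must be in (0, 100]")
    if (!(object@t50 > 0)) msg <- c(msg, "t50 must be > 0")
    if (!is.na(object@shape) && !(object@shape > 0))
      msg <- c(msg, "shape must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Spearman correlation matrix over genes
#'
#' @slot genes ordered gene ids.
#' @slot r symmetric matrix of Spearman coefficients (diagonal 1).
#' @slot p two-sided p-values from the t approximation.
#' @slot n_eff pairwise-complete sample counts.
#' @seealso [spearmanMatrix()], [thresholdEdges()]
#' @export
setClass("CorrMatrix", slots = c(
  genes = "character", r = "matrix", p = "matrix", n_eff = "matrix"
))

setValidity("CorrMatrix", function(object) {
  msg <- character()
  r <- object@r
  if (!isTRUE(all.equal(unname(diag(r)), rep(1, nrow(r)))))
    msg <- c(msg, "diagonal of r must be 1")
  if (max(abs(r - t(r)), na.rm = TRUE) > 1e-12) msg <- c(msg, "r must be symmetric")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) msg <- c(msg, "|r| must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Variable-clustering merge history
#'
#' Agglomerative clustering of quantitative variables under the
#' first-principal-component homogeneity criterion. Each merge joins the
#' pair of clusters whose union loses the least homogeneity; the loss is
#' recorded as the merge height.
#'
#' @slot merges integer matrix in [stats::hclust()] convention (negative
#'   entries are leaves, positive entries earlier merges).
#' @slot heights homogeneity loss `d >= 0` at each merge.
#' @slot labels variable (gene) names.
#' @slot data the standardized sample-by-variable matrix that was clustered
#'   (kept so cuts can report per-group homogeneity).
#' @seealso [hclustVariables()], [cutVarTree()], [homogeneity()]
#' @export
setClass("ClusterTree", slots = c(
  merges = "matrix", heights = "numeric", labels = "character", data = "matrix"
))

setValidity("ClusterTree", function(object) {
  n <- length(object@labels)
  msg <- character()
  if (nrow(object@merges) != n - 1L || length(object@heights) != n - 1L)
    msg <- c(msg, "a tree on n leaves must record n - 1 merges")
  if (any(object@heights < -1e-9)) msg <- c(msg, "merge losses must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Gene-to-group assignment from a tree cut
#'
#' @slot assignment named integer, gene -> group id in 1..k.
#' @slot k number of groups.
#' @slot homogeneity per-group homogeneity H (largest eigenvalue of the
#'   group's correlation matrix).
#' @seealso [cutVarTree()]
#' @export
setClass("ClusterAssignment", slots = c(
  assignment = "integer", k = "integer", homogeneity = "numeric"
))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  tab <- tabulate(object@assignment, nbins = object@k)
  if (any(tab == 0L)) msg <- c(msg, "groups must be non-empty")
  if (!all(object@assignment %in% seq_len(object@k)))
    msg <- c(msg, "assignment values must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' Regularized canonical correlation fit
#'
#' @slot lambda_x,lambda_y ridge constants added to the within-block
#'   covariance matrices.
#' @slot rho canonical correlations, sorted descending, clipped to \[0, 1\].
#' @slot x_weights,y_weights canonical coefficient matrices (one column per
#'   canonical pair).
#' @slot n number of samples used.
#' @slot standardized whether columns were scaled to unit variance before
#'   penalization.
#' @seealso [rccaFit()]
#' @export
setClass("RccaResult", slots = c(
  lambda_x = "numeric", lambda_y = "numeric", rho = "numeric",
  x_weights = "matrix", y_weights = "matrix", n = "integer",
  standardized = "logical"
))

setValidity("RccaResult", function(object) {
  msg <- character()
  if (any(object@rho < -1e-12 | object@rho > 1 + 1e-12))
    msg <- c(msg, "canonical correlations must lie in [0, 1]")
  if (is.unsorted(rev(object@rho), strictly = FALSE))
    msg <- c(msg, "rho must be sorted descending")
  if (!all(is.finite(object@x_weights)) || !all(is.finite(object@y_weights)))
    msg <- c(msg, "weight vectors must be finite")
  if (length(msg)) msg else TRUE
})

#' Bootstrap distribution of the first canonical correlation
#'
#' For one gene group: the B-vector of first regularized canonical
#' correlations obtained by jointly resampling aligned (expression, trait)
#' sample rows with replacement.
#'
#' @slot group group identifier.
#' @slot genes member genes of the group.
#' @slot rho1 the B first canonical correlations, each in \[0, 1\].
#' @slot B number of resamples.
#' @slot seed RNG seed used (NA when none was set).
#' @slot lambda_x,lambda_y ridge constants used in every fit.
#' @slot n sample rows resampled.
#' @slot redraws number of degenerate resamples (constant column) that were
#'   redrawn.
#' @seealso [bootstrapRho1()], [rankGroups()]
#' @export
setClass("BootstrapRho", slots = c(
  group = "character", genes = "character", rho1 = "numeric", B = "integer",
  seed = "integer", lambda_x = "numeric", lambda_y = "numeric",
  n = "integer", redraws = "integer"
))

setValidity("BootstrapRho", function(object) {
  msg <- character()
  if (length(object@rho1) != object@B)
    msg <- c(msg, "length(rho1) must equal B")
  if (any(object@rho1 < -1e-12 | object@rho1 > 1 + 1e-12))
    msg <- c(msg, "rho1 values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Letter-based ranking of gene groups
#'
#' @slot table `data.frame` with one row per group: `group`, `mean_rho1`,
#'   `sd_rho1`, `letters`, `rank`.
#' @slot top_group group with the largest mean bootstrap rho1.
#' @slot top_genes member genes of the top group.
#' @slot alpha significance level of the letter display.
#' @slot note caveat on interpreting Tukey letters computed over bootstrap
#'   resamples.
#' @seealso [rankGroups()]
#' @export
setClass("GroupRanking", slots = c(
  table = "data.frame", top_group = "character", top_genes = "character",
  alpha = "numeric", note = "character"
))

setValidity("GroupRanking", function(object) {
  tab <- object@table
  msg <- character()
  if (!setequal(tab$rank, seq_len(nrow(tab))))
    msg <- c(msg, "ranks must be a permutation of 1..n_groups")
  if (tab$group[tab$rank == 1L] != object@top_group)
    msg <- c(msg, "top_group must have rank 1")
  if (length(msg)) msg else TRUE
})
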