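# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' Extract the underlying long-format records
#'
#' @param x a [CqTable], [GerminationCourses] or [TraitReplicateTable]
#'   object.
#' @return a `data.frame` of replicate-level records.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "CqTable", function(x) x@records)

#' @rdname records
#' @export
setMethod("records", "GerminationCourses", function(x) x@records)

#' @rdname records
#' @export
setMethod("records", "TraitReplicateTable", function(x) x@records)

#' Relative-quantification assays and sample metadata
#'
#' `rq()` and `log2rq()` return the genes-by-samples assay matrices of an
#' [ExpressionMatrix]; `sampleInfo()` returns the sample annotation
#' (cultivar, lot, imbibition time, replicate) as a plain `data.frame`.
#'
#' @param x an [ExpressionMatrix].
#' @return a numeric matrix (`rq`, `log2rq`) or a `data.frame`
#'   (`sampleInfo`).
#' @export
setGeneric("rq", function(x) standardGeneric("rq"))

#' @rdname rq
#' @export
setMethod("rq", "ExpressionMatrix", function(x) assay(x, "RQ"))

#' @rdname rq
#' @export
setGeneric("log2rq", function(x) standardGeneric("log2rq"))

#' @rdname rq
#' @export
setMethod("log2rq", "ExpressionMatrix", function(x) assay(x, "log2RQ"))

#' @rdname rq
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname rq
#' @export
setMethod("sampleInfo", "ExpressionMatrix", function(x)
  as.data.frame(colData(x)))

#' Trait-matrix values, keys and orientation
#'
#' @param x a [TraitMatrix].
#' @return `traitValues()` the lots-by-traits matrix; `traitKeys()` the
#'   (cultivar, lot) row annotation; `traitOrientation()` the named
#'   `"higher"`/`"lower"` flag per trait.
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' @rdname traitValues
#' @export
setMethod("traitValues", "TraitMatrix", function(x) x@values)

#' @rdname traitValues
#' @export
setGeneric("traitKeys", function(x) standardGeneric("traitKeys"))

#' @rdname traitValues
#' @export
setMethod("traitKeys", "TraitMatrix", function(x) x@keys)

#' @rdname traitValues
#' @export
setGeneric("traitOrientation", function(x) standardGeneric("traitOrientation"))

#' @rdname traitValues
#' @export
setMethod("traitOrientation", "TraitMatrix", function(x) x@orientation)

#' Cluster membership of a tree cut
#'
#' @param x a [ClusterAssignment].
#' @return named integer vector, gene -> group id.
#' @export
setGeneric("clusterGroups", function(x) standardGeneric("clusterGroups"))

#' @rdname clusterGroups
#' @export
setMethod("clusterGroups", "ClusterAssignment", function(x) x@assignment)

#' Canonical correlations of a fit
#'
#' @param x an [RccaResult].
#' @return numeric vector of canonical correlations, largest first.
#' @export
setGeneric("canonicalCorrelations",
           function(x) standardGeneric("canonicalCorrelations"))

#' @rdname canonicalCorrelations
#' @export
setMethod("canonicalCorrelations", "RccaResult", function(x) x@rho)

#' Bootstrap first-canonical-correlation draws
#'
#' @param x a [BootstrapRho].
#' @return numeric vector of length `B`.
#' @export
setGeneric("rho1", function(x) standardGeneric("rho1"))

#' @rdname rho1
#' @export
setMethod("rho1", "BootstrapRho", function(x) x@rho1)

#' Ranking table of a group comparison
#'
#' @param x a [GroupRanking].
#' @return `data.frame` with mean rho1, letters and rank per group.
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname rankingTable
#' @export
setMethod("rankingTable", "GroupRanking", function(x) x@table)

# -- show methods -----------------------------------------------------------

setMethod("show", "DesignConfig", function(object) {
  cat("DesignConfig:",
      length(object@cultivars), "cultivar(s) x",
      object@lots_per_cultivar, "lot(s),",
      object@qpcr_reps, "qPCR rep(s), timepoints",
      paste(object@timepoints_h, collapse = "/"), "h\n")
  cat(" ", object@n_target_genes, "target +",
      object@n_reference_genes, "reference genes;",
      length(object@trait_names), "traits;",
      length(object@germination_conditions), "germination conditions;",
      "seed", object@rng_seed, "\n")
})

setMethod("show", "CqTable", function(object) {
  df <- object@records
  cat("CqTable:", nrow(df), "records,",
      length(unique(df$gene[df$role == "target"])), "target gene(s),",
      length(unique(df$gene[df$role == "reference"])), "reference gene(s),",
      sum(is.na(df$cq)), "missing Cq\n")
})

setMethod("show", "GerminationCourses", function(object) {
  df <- object@records
  cat("GerminationCourses:", length(unique(.courseKey(df))), "course(s),",
      nrow(df), "observations\n")
})

setMethod("show", "TraitReplicateTable", function(object) {
  df <- object@records
  cat("TraitReplicateTable:", nrow(df), "records,",
      length(unique(df$trait)), "trait(s),",
      length(unique(paste(df$cultivar, df$lot))), "lot(s)\n")
})

setMethod("show", "TraitMatrix", function(object) {
  cat("TraitMatrix:", nrow(object@values), "lot(s) x",
      ncol(object@values), "trait(s)\n")
  lower <- names(object@orientation)[object@orientation == "lower"]
  if (length(lower))
    cat("  lower-is-more-vigor:", paste(lower, collapse = ", "), "\n")
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf("HillFit: gmax = %.2f%%, t50 = %.2f h, shape = %s, rss = %.3g (%s)\n",
              object@gmax, object@t50,
              ifelse(is.na(object@shape), "NA", sprintf("%.2f", object@shape)),
              object@rss,
              if (object@converged) "converged" else "interpolation fallback"))
})

setMethod("show", "CorrMatrix", function(object) {
  cat("CorrMatrix:", length(object@genes), "genes, Spearman r in [",
      sprintf("%.2f", min(object@r[upper.tri(object@r)], na.rm = TRUE)), ",",
      sprintf("%.2f", max(object@r[upper.tri(object@r)], na.rm = TRUE)), "]\n")
})

setMethod("show", "ClusterTree", function(object) {
  cat("ClusterTree:", length(object@labels), "variables,",
      nrow(object@merges), "merges, total homogeneity loss",
      sprintf("%.3f", sum(object@heights)), "\n")
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment: k =", object@k, "groups of sizes",
      paste(tabulate(object@assignment, object@k), collapse = "/"), "\n")
})

setMethod("show", "RccaResult", function(object) {
  cat(sprintf("RccaResult: n = %d, lambda = (%.3g, %.3g), rho1 = %.4f\n",
              object@n, object@lambda_x, object@lambda_y, object@rho[1]))
})

setMethod("show", "BootstrapRho", function(object) {
  cat(sprintf("BootstrapRho[%s]: B = %d, mean rho1 = %.4f (sd %.4f), %d redraw(s)\n",
              object@group, object@B, mean(object@rho1), sd(object@rho1),
              object@redraws))
})

setMethod("show", "GroupRanking", function(object) {
  cat("GroupRanking (alpha =", object@alpha, "):\n")
  print(object@table[order(object@table$rank),
                     c("group", "mean_rho1", "letters", "rank")],
        row.names = FALSE)
  cat("  top group:", object@top_group, "->",
      paste(object@top_genes, collapse = ", "), "\n")
})
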