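# End-to-end orchestration: simulate or read inputs, then quantify, fit
# kinetics, assemble traits, correlate, cluster and rank -- writing every
# intermediate artifact plus a provenance manifest.

.defaultParams <- function() {
  list(n_perm = 2000L, B = 10000L, lambda_x = 0.1, lambda_y = 0.1,
       k = 5L, r_min = 0.70, alpha = 0.05, rho_threshold = 0.7,
       times = c(6, 10), seed = 1L)
}

#' Run the full expression-to-vigor pipeline
#'
#' Executes the analysis chain on either simulated or on-disk inputs:
#' relative quantification of the Cq table, Hill-curve t50 extraction,
#' assembly of the lot-level trait matrix, the Spearman co-expression
#' network, variable clustering into `k` groups, the per-timepoint
#' consistency check, per-group bootstraps of the first regularized
#' canonical correlation, and the letter-based group ranking. When
#' `outdir` is given, every intermediate artifact is written as CSV/JSON
#' together with a `manifest.json` recording parameters, seeds and input
#' file hashes.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Exactly one of `config$simulate` (a list of [designConfig()] /
#'   [effectConfig()] arguments; may be empty for the defaults) or
#'   `config$inputs` (paths `cq`, `germination`, `traits`) must be
#'   present. Hyperparameters (`B`, `lambda_x`, `lambda_y`, `k`, `r_min`,
#'   `alpha`, `rho_threshold`, `times`, `seed`) override the defaults.
#' @param outdir optional output directory, created if needed.
#' @return (invisibly) a list bundle with every intermediate object:
#'   `expr`, `t50`, `trait_matrix`, `corr`, `edges`, `tree`, `clusters`,
#'   `consistency`, `bootstrap` (per-group [BootstrapRho]), `ranking` and
#'   `manifest`.
#' @examples
#' \donttest{
#' res <- runPipeline(list(simulate = list(), B = 200, seed = 1))
#' rankingTable(res$ranking)
#' }
#' @export
runPipeline <- function(config = list(simulate = list()), outdir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  has_sim <- !is.null(config$simulate)
  has_real <- !is.null(config$inputs)
  if (has_sim == has_real)
    .stopf("config must contain exactly one of 'simulate' or 'inputs'")
  params <- .defaultParams()
  for (nm in intersect(names(config), names(params)))
    params[[nm]] <- config[[nm]]
  if (params$k < 1 || params$B < 1 || params$r_min < -1 || params$alpha <= 0 ||
      params$alpha >= 1 || params$lambda_x < 0 || params$lambda_y < 0)
    .stopf("hyperparameter out of range")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline aborted at stage '%s': %s", name, conditionMessage(e)))
  }
  input_hashes <- list()

  if (has_sim) {
    sim_args <- config$simulate
    design <- do.call(designConfig,
                      c(sim_args$design,
                        if (is.null(sim_args$design$rng_seed))
                          list(rng_seed = params$seed)))
    effect <- do.call(effectConfig, c(list(design = design), sim_args$effect))
    cq <- stage("simulate", generateCqTable(design, effect))
    germ <- stage("simulate", generateGerminationCourses(design, effect))
    traits_tab <- stage("simulate", generateTraitReplicates(design, effect))
  } else {
    paths <- config$inputs
    for (nm in c("cq", "germination", "traits"))
      if (is.null(paths[[nm]]))
        .stopf("pipeline aborted at stage '%s': input file not configured", nm)
    cq <- stage("qpcr", readCqTable(paths$cq))
    germ <- stage("t50", readGerminationCourses(paths$germination))
    traits_tab <- stage("traits", readTraitReplicates(paths$traits))
    input_hashes <- lapply(paths, function(p) unname(tools::md5sum(p)))
  }

  expr <- stage("qpcr", relativeExpression(cq))
  t50 <- stage("t50", t50Table(germ))
  has_lots <- all(c("cultivar", "lot") %in% names(t50$t50))
  tm <- stage("traits",
              assembleTraitMatrix(traits_tab, t50 = if (has_lots) t50))
  corr <- stage("corr", spearmanMatrix(expr, times = params$times))
  edges <- stage("corr", thresholdEdges(corr, r_min = params$r_min,
                                        alpha = params$alpha))
  blocks <- stage("cluster", pairedBlocks(expr, tm, times = params$times))
  tree <- stage("cluster", hclustVariables(blocks$X))
  clusters <- stage("cluster", cutVarTree(tree, params$k))
  consistency <- stage("associate",
                       timeConsistency(expr, tm, times = params$times,
                                       B = params$B,
                                       lambda_x = params$lambda_x,
                                       lambda_y = params$lambda_y,
                                       seed = params$seed + 7L,
                                       threshold = params$rho_threshold))
  boots <- stage("associate", {
    lapply(seq_len(params$k), function(g) {
      genes_g <- names(clusterGroups(clusters))[clusterGroups(clusters) == g]
      bootstrapRho1(blocks$X[, genes_g, drop = FALSE], blocks$Y,
                    B = params$B, lambda_x = params$lambda_x,
                    lambda_y = params$lambda_y,
                    seed = params$seed + 100L + g,
                    group = paste0("group", g), genes = genes_g)
    })
  })
  ranking <- stage("associate", rankGroups(boots, alpha = params$alpha))

  manifest <- list(
    package = "vigorlink",
    version = as.character(utils::packageVersion("vigorlink")),
    mode = if (has_sim) "simulate" else "real",
    parameters = params,
    pairing = "broadcast",
    input_hashes = input_hashes,
    groups = split(names(clusterGroups(clusters)), clusterGroups(clusters)),
    consistency_means = as.list(consistency$means),
    consistency_pass = consistency$pass,
    top_group = ranking@top_group,
    top_genes = ranking@top_genes,
    note = ranking@note)

  bundle <- list(cq = cq, germination = germ, trait_replicates = traits_tab,
                 expr = expr, t50 = t50, trait_matrix = tm, corr = corr,
                 edges = edges, tree = tree, clusters = clusters,
                 consistency = consistency, bootstrap = boots,
                 ranking = ranking, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(outdir, f)
    writeCqTable(cq, out("cq.csv"))
    writeGerminationCourses(germ, out("germ.csv"))
    writeTraitReplicates(traits_tab, out("traits.csv"))
    writeExpressionMatrix(expr, out("rq.csv"))
    write.csv(t50$t50, out("t50.csv"), row.names = FALSE)
    writeTraitMatrix(tm, out("trait_matrix.csv"))
    write.csv(edges, out("edges.csv"), row.names = FALSE)
    write.csv(data.frame(gene = names(clusterGroups(clusters)),
                         group = unname(clusterGroups(clusters))),
              out("groups.csv"), row.names = FALSE)
    write.csv(data.frame(merge_a = tree@merges[, 1],
                         merge_b = tree@merges[, 2],
                         height = tree@heights),
              out("merge_history.csv"), row.names = FALSE)
    ranking_json <- c(manifest,
                      list(ranking = ranking@table,
                           bootstrap_summaries = lapply(boots, function(b)
                             list(group = b@group, genes = b@genes,
                                  mean = mean(b@rho1), sd = sd(b@rho1),
                                  quantiles = as.list(quantile(b@rho1,
                                    c(0.025, 0.25, 0.5, 0.75, 0.975))),
                                  redraws = b@redraws))))
    jsonlite::write_json(ranking_json, out("ranking.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
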