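# Synthetic-data generators. These emulate the statistical structure the
# downstream analysis assumes -- a latent lot-level vigor factor linking a
# planted subset of genes to the vigor traits and to germination speed --
# not any particular laboratory's measurements.

.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.vigorOf <- function(effect, cultivar, lot) {
  key <- .lotKey(cultivar, lot)
  miss <- setdiff(unique(key), names(effect@vigor_by_lot))
  if (length(miss))
    .stopf("vigor_by_lot has no entry for: %s", paste(miss, collapse = ", "))
  unname(effect@vigor_by_lot[key])
}

.sampleGrid <- function(design, reps) {
  grid <- expand.grid(rep = seq_len(reps),
                      time_h = design@timepoints_h,
                      lot = lotLabels(design),
                      cultivar = design@cultivars,
                      stringsAsFactors = FALSE)
  grid[c("cultivar", "lot", "time_h", "rep")]
}

#' Generate a synthetic qPCR Cq table
#'
#' Draws one Cq record per (sample, gene). Reference genes fluctuate around
#' their own baselines independently of vigor. For target genes the Cq is
#' `baseline - log2(expression) + noise`, where log2 expression is 0 in the
#' dry seed (the control level) and at imbibition timepoints is the sum of a
#' shared up-regulation trend, a per-sample co-expression block factor, and
#' -- for planted genes only -- `loading * v` with `v` the latent vigor of
#' the sample's lot. A planted gene with loading 1 in a `v = +1` lot
#' therefore amplifies exactly one cycle earlier (at 6 h) than in a `v = 0`
#' lot, in the no-noise limit.
#'
#' Per-gene baselines and trend multipliers, block factors and noise are all
#' drawn from `design@rng_seed`, so the same configuration reproduces the
#' same table.
#'
#' @param design a [DesignConfig].
#' @param effect an [EffectConfig]; its `planted_gene_set` and `gene_blocks`
#'   must be subsets of the design's target panel.
#' @return a [CqTable].
#' @examples
#' design <- designConfig(rng_seed = 1)
#' cq <- generateCqTable(design, effectConfig(design))
#' cq
#' @export
generateCqTable <- function(design, effect) {
  stopifnot(is(design, "DesignConfig"), is(effect, "EffectConfig"))
  genes <- targetGenes(design)
  refs <- referenceGenes(design)
  if (!all(effect@planted_gene_set %in% genes))
    .stopf("planted genes not in the target panel: %s",
           paste(setdiff(effect@planted_gene_set, genes), collapse = ", "))
  block_genes <- unlist(effect@gene_blocks, use.names = FALSE)
  if (!all(block_genes %in% genes))
    .stopf("gene_blocks contain unknown genes: %s",
           paste(setdiff(block_genes, genes), collapse = ", "))
  tp_pos <- design@timepoints_h[design@timepoints_h > 0]
  if (!all(as.character(tp_pos) %in% names(effect@time_trend_log2)))
    .stopf("time_trend_log2 missing timepoint(s): %s",
           paste(setdiff(as.character(tp_pos), names(effect@time_trend_log2)),
                 collapse = ", "))

  samples <- .sampleGrid(design, design@qpcr_reps)
  n_s <- nrow(samples)
  n_t <- length(genes)
  n_b <- length(effect@gene_blocks)
  v <- .vigorOf(effect, samples$cultivar, samples$lot)
  imbibed <- samples$time_h > 0

  # block id per gene (0 = not in any block)
  block_of <- integer(n_t)
  for (b in seq_len(n_b))
    block_of[match(effect@gene_blocks[[b]], genes)] <- b

  .withSeed(design@rng_seed + 101L, {
    baseline_g <- effect@cq_baseline + rnorm(n_t, 0, 1.5)
    trend_mult <- runif(n_t, 0.6, 1.4)
    baseline_r <- effect@cq_baseline - 3 + rnorm(length(refs), 0, 1)
    u <- matrix(rnorm(n_s * n_b, 0, effect@block_factor_sd), n_s, n_b)

    trend <- ifelse(imbibed, effect@time_trend_log2[as.character(samples$time_h)], 0)
    expr <- outer(trend, trend_mult)                      # shared up-regulation
    if (n_b > 0)
      expr <- expr + u[, pmax(block_of, 1L), drop = FALSE] *
        rep(as.numeric(block_of > 0L), each = n_s)        # co-expression blocks
    planted <- genes %in% effect@planted_gene_set
    expr <- expr + outer(effect@loading * v * imbibed, as.numeric(planted))

    cq_target <- matrix(baseline_g, n_s, n_t, byrow = TRUE) - expr +
      matrix(rnorm(n_s * n_t, 0, effect@cq_noise_sd), n_s, n_t)
    cq_ref <- matrix(baseline_r, n_s, length(refs), byrow = TRUE) +
      matrix(rnorm(n_s * length(refs), 0, effect@cq_noise_sd), n_s, length(refs))

    long_t <- data.frame(samples[rep(seq_len(n_s), n_t), ],
                         gene = rep(genes, each = n_s),
                         role = "target", cq = as.vector(cq_target),
                         row.names = NULL)
    long_r <- data.frame(samples[rep(seq_len(n_s), length(refs)), ],
                         gene = rep(refs, each = n_s),
                         role = "reference", cq = as.vector(cq_ref),
                         row.names = NULL)
    out <- rbind(long_t, long_r)
    out <- out[order(out$cultivar, out$lot, out$time_h, out$rep,
                     out$role, out$gene), ]
    rownames(out) <- NULL
    CqTable(out)
  })
}

#' Generate synthetic germination time courses
#'
#' For every (cultivar, lot, condition, replicate), each sown seed
#' germinates with probability `gmax_pct / 100` at a time drawn from a Hill
#' distribution with exponent `hill_shape` and median
#' `t50_base_h[condition] * exp(-t50_vigor_slope * v)` -- higher-vigor lots
#' germinate earlier, harsher conditions later. Cumulative counts are then
#' read off a 6 h observation grid, so they are non-decreasing and bounded
#' by the number of seeds by construction.
#'
#' @inheritParams generateCqTable
#' @return a [GerminationCourses] table with `cultivar` and `lot` columns.
#' @examples
#' design <- designConfig(rng_seed = 1)
#' germ <- generateGerminationCourses(design, effectConfig(design))
#' germ
#' @export
generateGerminationCourses <- function(design, effect) {
  stopifnot(is(design, "DesignConfig"), is(effect, "EffectConfig"))
  conds <- design@germination_conditions
  h <- effect@hill_shape
  .withSeed(design@rng_seed + 303L, {
    rows <- list()
    for (cv in design@cultivars) for (lt in lotLabels(design)) {
      vl <- .vigorOf(effect, cv, lt)
      for (cond in conds) {
        base <- effect@t50_base_h[[cond]]
        t50_true <- base * exp(-effect@t50_vigor_slope * vl)
        obs <- seq(6, ceiling(3.5 * base / 6) * 6, by = 6)
        for (r in seq_len(design@germ_reps)) {
          n <- design@seeds_per_rep
          m <- rbinom(1L, n, effect@gmax_pct / 100)
          tg <- if (m > 0) {
            u <- runif(m)
            t50_true * (u / (1 - u))^(1 / h)
          } else numeric()
          cum <- vapply(obs, function(t) sum(tg <= t), integer(1))
          rows[[length(rows) + 1L]] <- data.frame(
            cultivar = cv, lot = lt, condition = cond, replicate = r,
            time_h = obs, cumulative = cum, total = n)
        }
      }
    }
    GerminationCourses(do.call(rbind, rows))
  })
}

#' Generate synthetic vigor-trait replicates
#'
#' Each replicate value is
#' `trait_mean + magnitude * (sign * v + noise)`, with `v` the latent vigor
#' of the lot and `noise ~ N(0, trait_noise_sd)`. The default signs make
#' electrical conductivity and MDA higher in low-vigor lots and survival
#' and growth traits higher in high-vigor lots. Percentages are truncated
#' to \[0, 100\].
#'
#' @inheritParams generateCqTable
#' @return a [TraitReplicateTable].
#' @examples
#' design <- designConfig(rng_seed = 1)
#' traits <- generateTraitReplicates(design, effectConfig(design))
#' traits
#' @export
generateTraitReplicates <- function(design, effect) {
  stopifnot(is(design, "DesignConfig"), is(effect, "EffectConfig"))
  unknown <- setdiff(design@trait_names, names(effect@trait_magnitude))
  if (length(unknown))
    .stopf("traits without a loading entry: %s", paste(unknown, collapse = ", "))
  grid <- expand.grid(replicate = seq_len(design@trait_reps),
                      trait = design@trait_names,
                      lot = lotLabels(design),
                      cultivar = design@cultivars,
                      stringsAsFactors = FALSE)
  grid <- grid[c("cultivar", "lot", "trait", "replicate")]
  v <- .vigorOf(effect, grid$cultivar, grid$lot)
  mu <- effect@trait_means[grid$trait]
  sgn <- effect@trait_sign[grid$trait]
  mag <- effect@trait_magnitude[grid$trait]
  .withSeed(design@rng_seed + 202L, {
    eps <- rnorm(nrow(grid), 0, effect@trait_noise_sd)
    value <- unname(mu + mag * (sgn * v + eps))
    pct <- grepl("_pct$", grid$trait)
    value[pct] <- pmin(pmax(value[pct], 0), 100)
    grid$value <- value
    grid$units <- .traitUnits(grid$trait)
    rownames(grid) <- NULL
    TraitReplicateTable(grid)
  })
}

.traitUnits <- function(trait) {
  out <- rep("", length(trait))
  out[grepl("_pct$", trait)] <- "%"
  out[grepl("_cm$", trait)] <- "cm"
  out[grepl("_mg$", trait)] <- "mg"
  out[grepl("_mm$", trait)] <- "mm"
  out[grepl("uS_cm_g", trait)] <- "uS.cm-1.g-1"
  out[grepl("nmol_g", trait)] <- "nmol.g-1"
  out
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing the three input tables of one simulated
#' study from a single configuration.
#'
#' @inheritParams generateCqTable
#' @return a list with elements `cq`, `germination`, `traits` and the two
#'   configurations.
#' @export
simulateVigorStudy <- function(design = designConfig(),
                               effect = effectConfig(design)) {
  list(cq = generateCqTable(design, effect),
       germination = generateGerminationCourses(design, effect),
       traits = generateTraitReplicates(design, effect),
       design = design, effect = effect)
}
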