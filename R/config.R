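#' Construct a study design configuration
#'
#' Defaults mirror a two-cultivar, two-lot soybean germination *sensu
#' stricto* study: embryonic axes sampled dry and at 6 h and 10 h of
#' imbibition in three biological replicates, a panel of 20 growth-related
#' target genes plus two reference genes, nine phenotyped vigor traits and
#' germination tests at 25 degC, 15 degC, 10 degC and 25 degC in
#' 100 mmol/L NaCl (four replicates of 25 seeds, scored every 6 h).
#'
#' @param cultivars cultivar labels.
#' @param lots_per_cultivar lots per cultivar.
#' @param qpcr_reps biological qPCR replicates per sample.
#' @param timepoints_h imbibition timepoints (h), strictly increasing; the
#'   first is the dry-seed control.
#' @param n_target_genes,n_reference_genes gene panel sizes.
#' @param trait_names phenotyped trait names (unique).
#' @param trait_reps replicates per trait and lot.
#' @param germination_conditions germination test condition labels.
#' @param germ_reps replicates per condition.
#' @param seeds_per_rep seeds per germination replicate.
#' @param rng_seed integer seed driving all generators.
#' @return a [DesignConfig] object.
#' @examples
#' design <- designConfig(rng_seed = 1)
#' design
#' @export
designConfig <- function(cultivars = c("cv1", "cv2"),
                         lots_per_cultivar = 2L,
                         qpcr_reps = 3L,
                         timepoints_h = c(0, 6, 10),
                         n_target_genes = 20L,
                         n_reference_genes = 2L,
                         trait_names = c("normal_seedlings_pct",
                                         "emergence_pct",
                                         "seedling_length_cm",
                                         "seedling_dry_mass_mg",
                                         "aass_pct",
                                         "ec_uS_cm_g",
                                         "mda_nmol_g",
                                         "axis_length_6h_mm",
                                         "axis_length_10h_mm"),
                         trait_reps = 8L,
                         germination_conditions = c("25C", "15C", "10C",
                                                    "25C_NaCl100"),
                         germ_reps = 4L,
                         seeds_per_rep = 25L,
                         rng_seed = 1L) {
  new("DesignConfig",
      cultivars = as.character(cultivars),
      lots_per_cultivar = as.integer(lots_per_cultivar),
      qpcr_reps = as.integer(qpcr_reps),
      timepoints_h = as.numeric(timepoints_h),
      n_target_genes = as.integer(n_target_genes),
      n_reference_genes = as.integer(n_reference_genes),
      trait_names = as.character(trait_names),
      trait_reps = as.integer(trait_reps),
      germination_conditions = as.character(germination_conditions),
      germ_reps = as.integer(germ_reps),
      seeds_per_rep = as.integer(seeds_per_rep),
      rng_seed = as.integer(rng_seed))
}

#' Gene and lot labels implied by a design
#'
#' @param design a [DesignConfig].
#' @return character vectors of ids.
#' @export
targetGenes <- function(design) sprintf("G%02d", seq_len(design@n_target_genes))

#' @rdname targetGenes
#' @export
referenceGenes <- function(design) sprintf("REF%d", seq_len(design@n_reference_genes))

#' @rdname targetGenes
#' @export
lotLabels <- function(design) sprintf("lot%d", seq_len(design@lots_per_cultivar))

.lotKey <- function(cultivar, lot) paste(cultivar, lot, sep = ".")

# Partition `genes` into `n_blocks` contiguous blocks after reserving the
# planted set as block 1.
.defaultGeneBlocks <- function(genes, planted, n_blocks = 5L) {
  rest <- setdiff(genes, planted)
  if (length(rest) == 0L) return(list(block1 = planted))
  k <- max(1L, n_blocks - 1L)
  sizes <- rep(length(rest) %/% k, k) + (seq_len(k) <= length(rest) %% k)
  idx <- rep(seq_len(k), sizes)
  blocks <- c(list(planted), split(rest, idx))
  names(blocks) <- paste0("block", seq_along(blocks))
  blocks
}

#' Construct a latent-effect configuration
#'
#' Defines the associations planted into synthetic data. The latent vigor
#' factor `v` is fixed per (cultivar, lot) — vigor is a lot-level property —
#' and by default ranks lot 1 above lot 2 within each cultivar and the
#' first cultivar above the second. A planted subset of target genes (six
#' by default) is up-regulated during imbibition in proportion to
#' `loading * v`; all other genes are independent of `v`. Target genes are
#' additionally organised into co-expression blocks sharing a per-sample
#' latent factor, so that variable clustering has a recoverable structure.
#' Vigor traits respond to `v` with a per-trait sign and magnitude:
#' electrical conductivity and MDA decrease with vigor, survival and growth
#' traits increase, and germination t50 shortens.
#'
#' @param design the [DesignConfig] the effects refer to.
#' @param planted_gene_set target genes associated with vigor.
#' @param loading Cq cycles of up-regulation per unit of `v` at t > 0.
#' @param vigor_by_lot named numeric `"<cultivar>.<lot>"` -> `v`.
#' @param cq_baseline mean Cq of the panel (cycles).
#' @param cq_noise_sd replicate Cq noise (cycles), > 0.
#' @param block_factor_sd sd of the shared within-block log2 factor.
#' @param gene_blocks named list partitioning the target genes into
#'   co-expression blocks; block 1 defaults to the planted set.
#' @param time_trend_log2 named shared log2 up-regulation per imbibition
#'   timepoint (relative to the dry seed).
#' @param trait_means,trait_sign,trait_magnitude named numerics per trait.
#' @param trait_noise_sd replicate noise in units of `trait_magnitude`.
#' @param t50_base_h named numeric, condition -> t50 (h) at `v = 0`.
#' @param t50_vigor_slope log-scale shortening of t50 per unit `v`.
#' @param hill_shape,gmax_pct generating germination curve parameters.
#' @return an [EffectConfig] object.
#' @examples
#' design <- designConfig(rng_seed = 1)
#' effect <- effectConfig(design)
#' effect@planted_gene_set
#' @export
effectConfig <- function(design,
                         planted_gene_set = targetGenes(design)[1:6],
                         loading = 0.9,
                         vigor_by_lot = NULL,
                         cq_baseline = 24,
                         cq_noise_sd = 0.25,
                         block_factor_sd = 0.5,
                         gene_blocks = NULL,
                         time_trend_log2 = NULL,
                         trait_means = NULL,
                         trait_sign = NULL,
                         trait_magnitude = NULL,
                         trait_noise_sd = 0.3,
                         t50_base_h = c("25C" = 36, "15C" = 60, "10C" = 96,
                                        "25C_NaCl100" = 48),
                         t50_vigor_slope = 0.15,
                         hill_shape = 6,
                         gmax_pct = 95) {
  stopifnot(is(design, "DesignConfig"))
  genes <- targetGenes(design)
  if (!all(planted_gene_set %in% genes))
    .stopf("planted genes not in the target panel: %s",
           paste(setdiff(planted_gene_set, genes), collapse = ", "))
  if (is.null(vigor_by_lot)) {
    # lot 1 more vigorous than lot 2; first cultivar more vigorous overall
    lots <- lotLabels(design)
    grid <- expand.grid(lot = lots, cultivar = design@cultivars,
                        stringsAsFactors = FALSE)
    base <- c(1, -0.5, 0.5, -1)
    v <- rep_len(base, nrow(grid))
    vigor_by_lot <- setNames(v, .lotKey(grid$cultivar, grid$lot))
  }
  if (is.null(gene_blocks))
    gene_blocks <- .defaultGeneBlocks(genes, planted_gene_set)
  if (is.null(time_trend_log2)) {
    tp <- design@timepoints_h[design@timepoints_h > 0]
    # shared imbibition up-regulation, growing mildly with time
    time_trend_log2 <- setNames(1 + 0.3 * (seq_along(tp) - 1), as.character(tp))
  }
  defaults <- data.frame(
    trait = c("normal_seedlings_pct", "emergence_pct", "seedling_length_cm",
              "seedling_dry_mass_mg", "aass_pct", "ec_uS_cm_g", "mda_nmol_g",
              "axis_length_6h_mm", "axis_length_10h_mm"),
    mean = c(92, 88, 25, 120, 75, 60, 8, 8.5, 10),
    sign = c(1, 1, 1, 1, 1, -1, -1, 1, 1),
    magnitude = c(1.5, 1.5, 1, 5, 8, 8, 1.5, 0.4, 0.6))
  fill <- function(x, col, generic) {
    if (!is.null(x)) return(x)
    out <- setNames(defaults[[col]], defaults$trait)[design@trait_names]
    out[is.na(out)] <- generic
    setNames(out, design@trait_names)
  }
  trait_means <- fill(trait_means, "mean", 50)
  trait_sign <- fill(trait_sign, "sign", 1)
  trait_magnitude <- fill(trait_magnitude, "magnitude", 1)
  missing <- setdiff(design@trait_names, names(trait_magnitude))
  if (length(missing))
    .stopf("traits without a loading entry: %s", paste(missing, collapse = ", "))
  unknown <- setdiff(names(trait_magnitude), design@trait_names)
  if (length(unknown))
    .stopf("unknown trait name(s) in loading map: %s",
           paste(unknown, collapse = ", "))
  if (!all(design@germination_conditions %in% names(t50_base_h)))
    .stopf("t50_base_h missing condition(s): %s",
           paste(setdiff(design@germination_conditions, names(t50_base_h)),
                 collapse = ", "))
  new("EffectConfig",
      planted_gene_set = as.character(planted_gene_set),
      loading = as.numeric(loading),
      vigor_by_lot = vigor_by_lot,
      cq_baseline = as.numeric(cq_baseline),
      cq_noise_sd = as.numeric(cq_noise_sd),
      block_factor_sd = as.numeric(block_factor_sd),
      gene_blocks = gene_blocks,
      time_trend_log2 = time_trend_log2,
      trait_means = trait_means,
      trait_sign = trait_sign,
      trait_magnitude = trait_magnitude,
      trait_noise_sd = as.numeric(trait_noise_sd),
      t50_base_h = t50_base_h[design@germination_conditions],
      t50_vigor_slope = as.numeric(t50_vigor_slope),
      hill_shape = as.numeric(hill_shape),
      gmax_pct = as.numeric(gmax_pct))
}

# ---------------------------------------------------------------------------
# Table constructors
# ---------------------------------------------------------------------------

#' Construct measurement tables from data frames
#'
#' Validating constructors for the three long-format input tables. All
#' invariants (uniqueness of keys, ranges, monotone germination counts) are
#' enforced at construction.
#'
#' @param records a `data.frame` with the dialect's columns (see the class
#'   documentation).
#' @return the corresponding S4 table object.
#' @seealso [CqTable-class], [GerminationCourses-class],
#'   [TraitReplicateTable-class]
#' @export
CqTable <- function(records) {
  records <- as.data.frame(records)
  records$cq <- as.numeric(records$cq)
  new("CqTable", records = records)
}

#' @rdname CqTable
#' @export
GerminationCourses <- function(records) {
  new("GerminationCourses", records = as.data.frame(records))
}

#' @rdname CqTable
#' @export
TraitReplicateTable <- function(records) {
  new("TraitReplicateTable", records = as.data.frame(records))
}
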