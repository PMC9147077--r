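# Vigor-trait computations: derived biochemical quantities, assembly of the
# lot-level trait matrix, and Tukey compact-letter group comparisons.

#' Seed water content on a wet basis
#'
#' `100 * (fresh - dry) / fresh`, the moisture percentage convention of
#' seed-testing rules.
#'
#' @param fresh_mass,dry_mass masses in the same unit (g); `fresh_mass >=
#'   dry_mass > 0`. Vectorized.
#' @return moisture percentage.
#' @examples
#' waterContentWetBasis(10, 8.68)  # 13.2
#' @export
waterContentWetBasis <- function(fresh_mass, dry_mass) {
  if (any(dry_mass <= 0)) .stopf("dry mass must be > 0")
  if (any(dry_mass > fresh_mass))
    .stopf("dry mass exceeds fresh mass: check measurement order")
  100 * (fresh_mass - dry_mass) / fresh_mass
}

#' Malondialdehyde estimate from TBA-adduct absorbances
#'
#' Beer-Lambert conversion of the thiobarbituric-acid assay: the
#' nonspecific absorbance at 600 nm is subtracted from the reading at
#' 532 nm, converted to a concentration with the extinction coefficient of
#' the TBA-MDA adduct, and scaled by the extract volume per gram of fresh
#' tissue. Negative corrected absorbances are clipped to zero with a
#' warning.
#'
#' @param a532 absorbance at 532 nm (>= 0).
#' @param a600 nonspecific absorbance at 600 nm.
#' @param volume_mL extract volume in mL.
#' @param mass_g fresh tissue mass in g (> 0).
#' @param epsilon_mM_cm extinction coefficient in mM^-1 cm^-1 (default 155,
#'   the TBA-MDA adduct).
#' @param path_cm optical path length in cm.
#' @return MDA estimate in nmol per g fresh weight.
#' @examples
#' mdaEstimate(0.155, 0, volume_mL = 1, mass_g = 0.1)  # 10 nmol/g
#' @export
mdaEstimate <- function(a532, a600 = 0, volume_mL, mass_g,
                        epsilon_mM_cm = 155, path_cm = 1) {
  if (any(mass_g <= 0)) .stopf("tissue mass must be > 0")
  if (any(a532 < 0)) .stopf("a532 must be >= 0")
  corrected <- a532 - a600
  if (any(corrected < 0)) {
    .warnf("negative corrected absorbance clipped to 0")
    corrected <- pmax(corrected, 0)
  }
  # corrected / (eps * path) is mM = nmol/uL; * 1000 gives nmol/mL
  conc_nmol_mL <- corrected / (epsilon_mM_cm * path_cm) * 1000
  conc_nmol_mL * volume_mL / mass_g
}

#' Normalize a conductivity-meter reading by sample mass
#'
#' @param reading_uS_cm meter reading in uS/cm.
#' @param mass_g seed sample mass in g.
#' @return conductivity in uS cm^-1 g^-1.
#' @export
conductivityPerGram <- function(reading_uS_cm, mass_g) {
  if (any(mass_g <= 0)) .stopf("sample mass must be > 0")
  reading_uS_cm / mass_g
}

.defaultOrientation <- function(trait_names) {
  lower <- grepl("^(ec_|mda_|t50_)", trait_names)
  setNames(ifelse(lower, "lower", "higher"), trait_names)
}

#' Assemble the lot-level vigor-trait matrix
#'
#' Averages trait replicates to one value per (cultivar, lot) and trait,
#' optionally appends per-condition germination t50 means (columns
#' `t50_<condition>_h`), and attaches an orientation flag per column.
#' Electrical conductivity, MDA and t50 are lower-is-more-vigor by default;
#' everything else higher-is-more-vigor. Columns are ordered
#' alphabetically (t50 columns after the assay traits), so the matrix is
#' independent of the record order of the inputs.
#'
#' @param replicates a [TraitReplicateTable].
#' @param t50 optional: the result of [t50Table()] run on courses carrying
#'   `cultivar`/`lot` columns, or its `$t50` data frame.
#' @param orientation optional named character overriding the default
#'   `"higher"`/`"lower"` flags.
#' @return a [TraitMatrix].
#' @examples
#' design <- designConfig(rng_seed = 1)
#' reps <- generateTraitReplicates(design, effectConfig(design))
#' assembleTraitMatrix(reps)
#' @export
assembleTraitMatrix <- function(replicates, t50 = NULL, orientation = NULL) {
  stopifnot(is(replicates, "TraitReplicateTable"))
  df <- replicates@records
  if (!nrow(df)) .stopf("empty trait replicate table")
  traits <- sort(unique(df$trait))
  lots <- unique(df[c("cultivar", "lot")])
  lots <- lots[order(lots$cultivar, lots$lot), ]
  rownames(lots) <- NULL
  lot_key <- paste(lots$cultivar, lots$lot, sep = "\r")
  means <- tapply(df$value, list(paste(df$cultivar, df$lot, sep = "\r"),
                                 factor(df$trait, levels = traits)), mean)
  means <- means[lot_key, , drop = FALSE]
  gaps <- which(is.na(means), arr.ind = TRUE)
  if (nrow(gaps))
    .stopf("missing trait/lot combinations: %s",
           paste(unique(paste0(gsub("\r", "/", rownames(means)[gaps[, 1]]),
                               ":", colnames(means)[gaps[, 2]])),
                 collapse = ", "))
  values <- unname(means)
  colnames(values) <- traits

  if (!is.null(t50)) {
    tt <- if (is.list(t50) && !is.data.frame(t50)) t50$t50 else t50
    need <- c("cultivar", "lot", "condition", "t50_h")
    if (!all(need %in% names(tt)))
      .stopf("t50 table must carry columns: %s", paste(need, collapse = ", "))
    conds <- sort(unique(tt$condition))
    t50_means <- tapply(tt$t50_h,
                        list(paste(tt$cultivar, tt$lot, sep = "\r"),
                             factor(tt$condition, levels = conds)), mean)
    t50_means <- t50_means[lot_key, , drop = FALSE]
    if (any(is.na(t50_means)))
      .stopf("t50 values missing for some (cultivar, lot, condition)")
    cn <- paste0("t50_", conds, "_h")
    t50_means <- unname(t50_means)
    colnames(t50_means) <- cn
    values <- cbind(values, t50_means)
  }

  orient <- .defaultOrientation(colnames(values))
  if (!is.null(orientation)) orient[names(orientation)] <- orientation
  rownames(values) <- paste(lots$cultivar, lots$lot, sep = ".")
  new("TraitMatrix", values = values, keys = lots, orientation = orient)
}

#' Tukey HSD compact letter display
#'
#' One-way ANOVA followed by Tukey's honestly-significant-difference test
#' on all group pairs; letters are assigned by the insert-and-absorb
#' algorithm so that two groups share a letter if and only if they are not
#' significantly different at `alpha`. Group order (first appearance in
#' `groups`) decides letter naming, and the letter partition itself is
#' invariant to input order.
#'
#' @param values numeric response.
#' @param groups group labels, same length as `values`; at least two
#'   groups with at least two replicates each.
#' @param alpha significance level.
#' @return named character vector of letter strings, one per group, in
#'   first-appearance order.
#' @examples
#' tukeyLetters(c(1.1, 0.9, 1.0, 5.2, 4.8, 5.0), rep(c("a", "b"), each = 3))
#' @export
tukeyLetters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  if (nlevels(groups) < 2L) .stopf("need at least 2 groups")
  if (any(table(groups) < 2L)) .stopf("need at least 2 replicates per group")
  lev <- levels(groups)
  k <- length(lev)
  wivar <- tapply(values, groups, stats::var)
  if (all(wivar < .Machine$double.eps)) {
    .warnf("zero within-group variance in all groups; letters are all distinct")
    return(setNames(letters[seq_len(k)], lev))
  }
  fit <- aov(values ~ groups, data = data.frame(values, groups))
  hsd <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pair_names <- strsplit(rownames(hsd), "-", fixed = TRUE)
  sig <- hsd[, "p adj"] <= alpha

  # insert-and-absorb: start with one letter column holding every group,
  # split any column that joins a significantly different pair, then drop
  # columns contained in another.
  cols <- list(seq_len(k))
  for (pidx in which(sig)) {
    i <- match(pair_names[[pidx]][1], lev)
    j <- match(pair_names[[pidx]][2], lev)
    hit <- vapply(cols, function(s) all(c(i, j) %in% s), logical(1))
    for (ci in which(hit)) {
      s <- cols[[ci]]
      cols[[ci]] <- setdiff(s, i)
      cols[[length(cols) + 1L]] <- setdiff(s, j)
    }
    keep <- !vapply(seq_along(cols), function(a)
      any(vapply(seq_along(cols), function(b)
        a != b && all(cols[[a]] %in% cols[[b]]) &&
          (length(cols[[a]]) < length(cols[[b]]) || a > b), logical(1))),
      logical(1))
    cols <- cols[keep]
  }
  cols <- cols[order(vapply(cols, min, integer(1)))]
  out <- vapply(seq_len(k), function(g)
    paste0(letters[which(vapply(cols, function(s) g %in% s, logical(1)))],
           collapse = ""), character(1))
  setNames(out, lev)
}
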