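test_that("water content follows the wet-basis formula", {
  expect_equal(waterContentWetBasis(10, 10), 0)
  expect_equal(waterContentWetBasis(10, 8.68), 13.2)
  # scale invariance
  expect_equal(waterContentWetBasis(2 * 10, 2 * 8.68),
               waterContentWetBasis(10, 8.68))
  expect_error(waterContentWetBasis(8, 10), "measurement order")
  expect_error(waterContentWetBasis(10, 0), "> 0")
})

test_that("the MDA estimate follows Beer-Lambert arithmetic", {
  expect_equal(mdaEstimate(0.3, 0.3, volume_mL = 1, mass_g = 0.1), 0)
  expect_equal(mdaEstimate(0.155, 0, volume_mL = 1, mass_g = 0.1), 10)
  expect_equal(mdaEstimate(0.155, 0, volume_mL = 2, mass_g = 0.2),
               mdaEstimate(0.155, 0, volume_mL = 1, mass_g = 0.1))
  expect_warning(out <- mdaEstimate(0.1, 0.2, volume_mL = 1, mass_g = 0.1),
                 "clipped")
  expect_equal(out, 0)
  expect_error(mdaEstimate(0.1, 0, volume_mL = 1, mass_g = 0), "> 0")
})

test_that("trait matrix assembly averages replicates and keeps orientation", {
  design <- designConfig(rng_seed = 2)
  reps <- generateTraitReplicates(design, effectConfig(design))
  tm <- assembleTraitMatrix(reps)
  df <- records(reps)
  # means match a direct aggregation
  manual <- tapply(df$value[df$trait == "ec_uS_cm_g"],
                   paste(df$cultivar, df$lot)[df$trait == "ec_uS_cm_g"], mean)
  expect_equal(unname(traitValues(tm)[, "ec_uS_cm_g"]),
               as.numeric(manual[paste(traitKeys(tm)$cultivar,
                                       traitKeys(tm)$lot)]))
  expect_equal(unname(traitOrientation(tm)[c("ec_uS_cm_g", "mda_nmol_g",
                                             "aass_pct")]),
               c("lower", "lower", "higher"))
  # permuting the record order changes nothing
  perm <- TraitReplicateTable(df[sample.int(nrow(df)), ])
  expect_equal(traitValues(assembleTraitMatrix(perm)), traitValues(tm))
  # single replicate per cell: matrix equals the raw values
  single <- TraitReplicateTable(df[df$replicate == 1, ])
  one <- traitValues(assembleTraitMatrix(single))
  expect_equal(unname(one["cv1.lot1", "mda_nmol_g"]),
               df$value[df$cultivar == "cv1" & df$lot == "lot1" &
                          df$trait == "mda_nmol_g" & df$replicate == 1])
})

test_that("missing trait/lot combinations abort assembly with a gap list", {
  design <- designConfig(rng_seed = 2)
  df <- records(generateTraitReplicates(design, effectConfig(design)))
  df <- df[!(df$lot == "lot2" & df$cultivar == "cv2" &
               df$trait == "aass_pct"), ]
  expect_error(assembleTraitMatrix(TraitReplicateTable(df)),
               "missing trait/lot.*aass_pct")
})

test_that("EC and MDA run higher in the low-vigor lot of strong-effect data", {
  design <- designConfig(rng_seed = 6)
  tm <- assembleTraitMatrix(
    generateTraitReplicates(design, effectConfig(design)))
  vals <- traitValues(tm)
  keys <- traitKeys(tm)
  for (cv in c("cv1", "cv2")) {
    hi <- keys$cultivar == cv & keys$lot == "lot1"   # lot 1 is high vigor
    lo <- keys$cultivar == cv & keys$lot == "lot2"
    expect_gt(vals[lo, "ec_uS_cm_g"], vals[hi, "ec_uS_cm_g"])
    expect_gt(vals[lo, "mda_nmol_g"], vals[hi, "mda_nmol_g"])
    expect_gt(vals[hi, "aass_pct"], vals[lo, "aass_pct"])
  }
})

test_that("Tukey letters separate what differs and only that", {
  set.seed(10)
  # overwhelming separation: distinct letters
  x <- c(rnorm(6, 0), rnorm(6, 10))
  g <- rep(c("low", "high"), each = 6)
  expect_equal(unname(tukeyLetters(x, g)), c("a", "b"))
  # three groups, middle one bridging: shared letters chain a-ab-b
  y <- c(rnorm(8, 0, 0.5), rnorm(8, 1, 0.5), rnorm(8, 2.2, 0.5))
  gy <- rep(c("g1", "g2", "g3"), each = 8)
  lett <- tukeyLetters(y, gy)
  expect_false(grepl("b", lett[["g1"]]) && grepl("b", lett[["g3"]]) ||
                 grepl("a", lett[["g1"]]) && grepl("a", lett[["g3"]]))
  # relabeling groups permutes letters consistently
  lett_swapped <- tukeyLetters(y, factor(gy, levels = c("g3", "g2", "g1")))
  share <- function(l, a, b) {
    any(strsplit(l[[a]], "")[[1]] %in% strsplit(l[[b]], "")[[1]])
  }
  for (pair in list(c("g1", "g2"), c("g2", "g3"), c("g1", "g3")))
    expect_equal(share(lett, pair[1], pair[2]),
                 share(lett_swapped, pair[1], pair[2]))
  # input order does not change the partition
  ord <- sample.int(length(y))
  lett_perm <- tukeyLetters(y[ord], gy[ord])
  for (pair in list(c("g1", "g2"), c("g2", "g3"), c("g1", "g3")))
    expect_equal(share(lett, pair[1], pair[2]),
                 share(lett_perm, pair[1], pair[2]))
})

test_that("degenerate Tukey inputs are flagged", {
  expect_warning(lett <- tukeyLetters(rep(c(1, 2), each = 3),
                                      rep(c("a", "b"), each = 3)),
                 "zero within-group variance")
  expect_equal(unname(lett), c("a", "b"))
  expect_error(tukeyLetters(rnorm(4), rep("g", 4)), "at least 2 groups")
  expect_error(tukeyLetters(rnorm(3), c("a", "a", "b")),
               "2 replicates per group")
})
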