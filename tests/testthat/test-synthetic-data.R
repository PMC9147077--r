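test_that("generators are deterministic under a fixed seed", {
  design <- designConfig(rng_seed = 7)
  effect <- effectConfig(design)
  expect_identical(records(generateCqTable(design, effect)),
                   records(generateCqTable(design, effect)))
  expect_identical(records(generateGerminationCourses(design, effect)),
                   records(generateGerminationCourses(design, effect)))
  expect_identical(records(generateTraitReplicates(design, effect)),
                   records(generateTraitReplicates(design, effect)))
  # a different seed changes the data
  other <- designConfig(rng_seed = 8)
  expect_false(identical(records(generateCqTable(design, effect)),
                         records(generateCqTable(other, effectConfig(other)))))
})

test_that("without a planted effect and regulation, all ddCt vanish", {
  design <- tiny_design()
  effect <- quiet_effect(design, loading = 0,
                         time_trend_log2 = c("6" = 0, "10" = 0))
  expr <- relativeExpression(generateCqTable(design, effect))
  expect_lt(max(abs(log2rq(expr))), 1e-6)
})

test_that("with loading 0 the expression is independent of lot vigor", {
  design <- tiny_design()
  effect <- quiet_effect(design, loading = 0,
                         vigor_by_lot = c(cv1.lot1 = 1, cv1.lot2 = -1))
  expr <- relativeExpression(generateCqTable(design, effect))
  info <- sampleInfo(expr)
  l2 <- log2rq(expr)
  for (tp in c(6, 10)) {
    m1 <- rowMeans(l2[, info$time_h == tp & info$lot == "lot1", drop = FALSE])
    m2 <- rowMeans(l2[, info$time_h == tp & info$lot == "lot2", drop = FALSE])
    expect_lt(max(abs(m1 - m2)), 1e-6)
  }
})

test_that("a planted gene with loading 1 shifts Cq by exactly -1 cycle per unit vigor", {
  design <- tiny_design()
  effect <- quiet_effect(design, loading = 1,
                         vigor_by_lot = c(cv1.lot1 = 1, cv1.lot2 = 0))
  df <- records(generateCqTable(design, effect))
  planted <- effect@planted_gene_set[1]
  at <- function(lot, tp) mean(df$cq[df$gene == planted & df$lot == lot &
                                       df$time_h == tp])
  expect_equal(at("lot1", 6) - at("lot2", 6), -1, tolerance = 1e-6)
  expect_equal(at("lot1", 10) - at("lot2", 10), -1, tolerance = 1e-6)
  # dry seeds are the shared control level: no vigor effect at 0 h
  expect_equal(at("lot1", 0) - at("lot2", 0), 0, tolerance = 1e-6)
  # an unplanted gene is unaffected at any time
  free <- setdiff(unique(df$gene[df$role == "target"]),
                  effect@planted_gene_set)[1]
  atf <- function(lot, tp) mean(df$cq[df$gene == free & df$lot == lot &
                                        df$time_h == tp])
  expect_equal(atf("lot1", 6) - atf("lot2", 6), 0, tolerance = 1e-6)
})

test_that("planted genes outside the panel are a configuration error", {
  design <- tiny_design()
  expect_error(effectConfig(design, planted_gene_set = c("G01", "G99")),
               "not in the target panel")
})

test_that("germination courses are bounded, monotone and recover their generating t50", {
  design <- tiny_design(seeds_per_rep = 2500, germ_reps = 2,
                        germination_conditions = c("25C", "15C"))
  effect <- effectConfig(design, t50_vigor_slope = 0.15)
  germ <- generateGerminationCourses(design, effect)
  df <- records(germ)
  expect_true(all(df$cumulative <= df$total))
  key <- paste(df$cultivar, df$lot, df$condition, df$replicate)
  for (k in unique(key))
    expect_true(all(diff(df$cumulative[key == k]) >= 0))
  # with 2500 seeds the binomial noise is tiny: fitted t50 within 2% of truth
  t50s <- t50Table(germ)$t50
  for (i in seq_len(nrow(t50s))) {
    v <- effect@vigor_by_lot[[paste(t50s$cultivar[i], t50s$lot[i], sep = ".")]]
    truth <- effect@t50_base_h[[t50s$condition[i]]] *
      exp(-effect@t50_vigor_slope * v)
    expect_lt(abs(t50s$t50_h[i] - truth) / truth, 0.02)
  }
})

test_that("equal lot vigor leaves only condition-driven t50 differences", {
  design <- tiny_design(seeds_per_rep = 2500, germ_reps = 2)
  effect <- effectConfig(design, vigor_by_lot = c(cv1.lot1 = 0.5,
                                                  cv1.lot2 = 0.5))
  summ <- t50Table(generateGerminationCourses(design, effect))$summary
  for (cond in unique(summ$condition)) {
    sub <- summ[summ$condition == cond, ]
    expect_lt(abs(diff(sub$mean_t50_h)) / mean(sub$mean_t50_h), 0.02)
  }
  # conditions still separate clearly
  expect_gt(max(summ$mean_t50_h), 2 * min(summ$mean_t50_h))
})

test_that("trait generator respects sign conventions and zero magnitudes", {
  design <- tiny_design()
  # zero magnitude: lots agree up to replicate noise
  eff0 <- effectConfig(design, trait_magnitude = setNames(
    rep(0, length(design@trait_names)), design@trait_names),
    trait_noise_sd = 0.3)
  df0 <- records(generateTraitReplicates(design, eff0))
  agg <- tapply(df0$value, list(df0$trait, df0$lot), mean)
  expect_lt(max(abs(agg[, 1] - agg[, 2])), 1)  # noise has sd 0.3 * magnitude 0
  # negative-sign traits are strictly lower in the high-vigor lot
  eff <- quiet_effect(design, vigor_by_lot = c(cv1.lot1 = 1, cv1.lot2 = -1))
  df <- records(generateTraitReplicates(design, eff))
  mda <- tapply(df$value[df$trait == "mda_nmol_g"],
                df$lot[df$trait == "mda_nmol_g"], mean)
  ec <- tapply(df$value[df$trait == "ec_uS_cm_g"],
               df$lot[df$trait == "ec_uS_cm_g"], mean)
  expect_lt(mda[["lot1"]], mda[["lot2"]])
  expect_lt(ec[["lot1"]], ec[["lot2"]])
  aass <- tapply(df$value[df$trait == "aass_pct"],
                 df$lot[df$trait == "aass_pct"], mean)
  expect_gt(aass[["lot1"]], aass[["lot2"]])
})

test_that("unknown trait names in the loading map are rejected", {
  design <- tiny_design()
  expect_error(
    effectConfig(design, trait_magnitude = c(not_a_trait = 1)),
    "without a loading entry|unknown trait")
})
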