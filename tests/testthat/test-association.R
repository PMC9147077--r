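make_study <- function(seed = 1) {
  design <- designConfig(rng_seed = seed)
  effect <- effectConfig(design)
  expr <- relativeExpression(generateCqTable(design, effect))
  tm <- assembleTraitMatrix(generateTraitReplicates(design, effect))
  list(design = design, effect = effect, expr = expr, tm = tm)
}

test_that("paired blocks follow the design arithmetic and align rows", {
  st <- make_study(1)
  blk <- pairedBlocks(st$expr, st$tm)
  # 2 cultivars x 2 lots x 2 times x 3 reps = 24 aligned rows
  expect_equal(nrow(blk$X), 24)
  expect_equal(nrow(blk$Y), 24)
  expect_equal(ncol(blk$X), 20)
  blk6 <- pairedBlocks(st$expr, st$tm, times = 6)
  expect_equal(nrow(blk6$X), 12)
  # permuting the trait-matrix rows changes nothing after alignment
  tm2 <- st$tm
  ord <- c(3, 1, 4, 2)
  tm2@values <- tm2@values[ord, ]
  tm2@keys <- tm2@keys[ord, ]
  blk_perm <- pairedBlocks(st$expr, tm2)
  expect_equal(blk_perm$X, blk$X)
  expect_equal(blk_perm$Y, blk$Y)
  # an unmatched lot is a pairing error
  tm3 <- st$tm
  tm3@keys$lot[1] <- "lot9"
  rownames(tm3@values) <- NULL
  expect_error(pairedBlocks(st$expr, tm3), "missing from the trait matrix")
})

test_that("a forced full-sample resample reduces the bootstrap to the plain fit", {
  st <- make_study(2)
  blk <- pairedBlocks(st$expr, st$tm)
  plain <- canonicalCorrelations(rccaFit(blk$X, blk$Y, 0.1, 0.1))[1]
  forced <- bootstrapRho1(blk$X, blk$Y, B = 1,
                          indices = matrix(seq_len(nrow(blk$X)), 1))
  expect_equal(rho1(forced), plain, tolerance = 1e-12)
})

test_that("the bootstrap is reproducible under a fixed seed and validates B", {
  st <- make_study(2)
  blk <- pairedBlocks(st$expr, st$tm)
  a <- bootstrapRho1(blk$X, blk$Y, B = 100, seed = 5)
  b <- bootstrapRho1(blk$X, blk$Y, B = 100, seed = 5)
  expect_identical(rho1(a), rho1(b))
  expect_true(all(rho1(a) >= 0 & rho1(a) <= 1))
  expect_error(bootstrapRho1(blk$X, blk$Y, B = 0), "positive integer")
})

test_that("the planted cluster dominates null clusters in mean bootstrap rho1", {
  st <- make_study(3)
  blk <- pairedBlocks(st$expr, st$tm)
  planted <- st$effect@planted_gene_set
  nulls <- setdiff(colnames(blk$X), planted)[1:6]
  bp <- bootstrapRho1(blk$X[, planted], blk$Y, B = 300, seed = 1,
                      group = "planted", genes = planted)
  bn <- bootstrapRho1(blk$X[, nulls], blk$Y, B = 300, seed = 2,
                      group = "null", genes = nulls)
  expect_gt(mean(rho1(bp)), mean(rho1(bn)))
  r <- rankGroups(list(bp, bn))
  expect_equal(r@top_group, "planted")
  expect_equal(sort(r@top_genes), sort(planted))
})

test_that("group ranking shares letters for identical distributions and checks B", {
  st <- make_study(4)
  blk <- pairedBlocks(st$expr, st$tm)
  d1 <- bootstrapRho1(blk$X, blk$Y, B = 200, seed = 3, group = "g1")
  d2 <- bootstrapRho1(blk$X, blk$Y, B = 200, seed = 3, group = "g2")
  r <- rankGroups(list(d1, d2))
  tab <- rankingTable(r)
  # identical draws: equal means and a shared letter
  expect_equal(tab$mean_rho1[1], tab$mean_rho1[2])
  expect_equal(tab$letters[1], tab$letters[2])
  d3 <- bootstrapRho1(blk$X, blk$Y, B = 100, seed = 4, group = "g3")
  expect_error(rankGroups(list(d1, d3)), "resample counts differ")
  expect_error(rankGroups(list(d1)), "at least 2 groups")
})

test_that("relabeling groups permutes the ranking consistently", {
  st <- make_study(5)
  blk <- pairedBlocks(st$expr, st$tm)
  planted <- st$effect@planted_gene_set
  nulls <- setdiff(colnames(blk$X), planted)[1:5]
  d_a <- bootstrapRho1(blk$X[, planted], blk$Y, B = 150, seed = 1,
                       group = "A", genes = planted)
  d_b <- bootstrapRho1(blk$X[, nulls], blk$Y, B = 150, seed = 2,
                       group = "B", genes = nulls)
  r1 <- rankingTable(rankGroups(list(d_a, d_b)))
  d_a@group <- "B"; d_b@group <- "A"
  r2 <- rankingTable(rankGroups(list(d_a, d_b)))
  expect_equal(r1$rank[r1$group == "A"], r2$rank[r2$group == "B"])
  expect_equal(r1$mean_rho1[r1$group == "A"], r2$mean_rho1[r2$group == "B"])
})

test_that("time consistency reports both timepoints symmetrically", {
  st <- make_study(6)
  tc <- timeConsistency(st$expr, st$tm, B = 150, seed = 9)
  expect_named(tc$means, c("6h", "10h"))
  tc_rev <- timeConsistency(st$expr, st$tm, times = c(10, 6), B = 150, seed = 9)
  expect_equal(sort(names(tc_rev$means)), sort(names(tc$means)))
  # the verdict does not depend on the order the times are listed
  expect_equal(tc_rev$pass, tc$pass)
  expect_error(timeConsistency(st$expr, st$tm, times = c(6, 14)),
               "no samples at timepoint|14")
})

test_that("replicate pairing matches trait replicate i to expression replicate i", {
  st <- make_study(7)
  reps <- generateTraitReplicates(st$design, st$effect)
  blk_b <- pairedBlocks(st$expr, st$tm)
  blk_r <- pairedBlocks(st$expr, st$tm, pairing = "replicate",
                        trait_replicates = reps)
  expect_equal(dim(blk_r$Y), dim(blk_b$Y))
  expect_false(isTRUE(all.equal(blk_r$Y, blk_b$Y)))
  expect_error(pairedBlocks(st$expr, st$tm, pairing = "replicate"),
               "trait_replicates")
})
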