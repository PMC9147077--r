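# A hand-built two-sample toy table: one cultivar, control (0 h, lot1) with
# two replicates, one treated sample (6 h). Reference Cq values differ so
# the multi-reference mean matters.
toy_cq <- function() {
  rows <- rbind(
    # cultivar lot   time rep gene   role        cq
    c("cv1", "lot1", 0, 1, "GA",  "target",    24.0),
    c("cv1", "lot1", 0, 1, "GB",  "target",    26.0),
    c("cv1", "lot1", 0, 1, "REF1", "reference", 20.0),
    c("cv1", "lot1", 0, 1, "REF2", "reference", 21.0),
    c("cv1", "lot1", 0, 2, "GA",  "target",    24.5),
    c("cv1", "lot1", 0, 2, "GB",  "target",    25.5),
    c("cv1", "lot1", 0, 2, "REF1", "reference", 20.5),
    c("cv1", "lot1", 0, 2, "REF2", "reference", 20.5),
    c("cv1", "lot1", 6, 1, "GA",  "target",    22.0),
    c("cv1", "lot1", 6, 1, "GB",  "target",    28.0),
    c("cv1", "lot1", 6, 1, "REF1", "reference", 19.5),
    c("cv1", "lot1", 6, 1, "REF2", "reference", 20.5))
  df <- data.frame(cultivar = rows[, 1], lot = rows[, 2],
                   time_h = as.numeric(rows[, 3]), rep = as.integer(rows[, 4]),
                   gene = rows[, 5], role = rows[, 6],
                   cq = as.numeric(rows[, 7]))
  CqTable(df)
}

test_that("reference Cq is the arithmetic mean of the sample's reference genes", {
  tab <- toy_cq()
  expect_equal(referenceCq(tab, "cv1", "lot1", 0, 1), 20.5)  # (20 + 21) / 2
  expect_equal(referenceCq(tab, "cv1", "lot1", 0, 2), 20.5)
  expect_equal(referenceCq(tab, "cv1", "lot1", 6, 1), 20.0)  # (19.5 + 20.5) / 2
  # identical refs and a single ref are identities
  one <- CqTable(data.frame(cultivar = "c", lot = "l", time_h = 0, rep = 1,
                            gene = "R", role = "reference", cq = 22.5))
  expect_equal(referenceCq(one, "c", "l", 0, 1), 22.5)
  expect_error(referenceCq(tab, "cv1", "lot2", 0, 1), "no reference Cq")
})

test_that("relative expression matches the spreadsheet arithmetic cell by cell", {
  expr <- relativeExpression(toy_cq())
  # hand computation:
  # dCt(GA): ctrl rep1 = 24.0 - 20.5 = 3.5; rep2 = 24.5 - 20.5 = 4.0
  #          -> control mean 3.75; treated = 22.0 - 20.0 = 2.0
  # ddCt(GA, treated) = 2.0 - 3.75 = -1.75 -> RQ = 2^1.75
  # dCt(GB): ctrl = 5.5, 5.0 -> mean 5.25; treated = 28.0 - 20.0 = 8.0
  # ddCt(GB, treated) = 2.75 -> RQ = 2^-2.75
  info <- sampleInfo(expr)
  treated <- which(info$time_h == 6)
  expect_equal(rq(expr)["GA", treated], 2^1.75)
  expect_equal(rq(expr)["GB", treated], 2^-2.75)
  # control cells: ddCt = dCt - mean -> +/-0.25 around 0
  ctrl <- which(info$time_h == 0)
  expect_equal(unname(log2rq(expr)["GA", ctrl]), c(0.25, -0.25))
  # control self-normalization: mean log2RQ of control replicates is 0
  expect_equal(unname(rowMeans(log2rq(expr)[, ctrl])), c(0, 0))
})

test_that("RQ identities hold at ddCt in {0, 1, -2}", {
  df <- records(toy_cq())
  # engineer treated dCt = control mean + 1 and - 2 for the two genes
  df$cq[df$time_h == 6 & df$gene == "GA"] <- 20.0 + 3.75 + 1   # ddCt = +1
  df$cq[df$time_h == 6 & df$gene == "GB"] <- 20.0 + 5.25 - 2   # ddCt = -2
  expr <- relativeExpression(CqTable(df))
  treated <- which(sampleInfo(expr)$time_h == 6)
  expect_equal(rq(expr)["GA", treated], 0.5)
  expect_equal(rq(expr)["GB", treated], 4)
})

test_that("adding a constant to every Cq of a sample leaves all RQ unchanged", {
  design <- designConfig(rng_seed = 3)
  tab <- generateCqTable(design, effectConfig(design))
  base <- rq(relativeExpression(tab))
  df <- records(tab)
  bump <- function(df, cultivar, lot, tp, rep) {
    sel <- df$cultivar == cultivar & df$lot == lot & df$time_h == tp &
      df$rep == rep
    df$cq[sel] <- df$cq[sel] + 3.3
    df
  }
  df <- bump(df, "cv1", "lot2", 6, 2)    # a treated sample
  df <- bump(df, "cv2", "lot1", 0, 1)    # a control sample
  shifted <- rq(relativeExpression(CqTable(df)))
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("missing Cq cells stay missing and absent control genes error", {
  df <- records(toy_cq())
  df$cq[df$time_h == 6 & df$gene == "GA"] <- NA
  expr <- relativeExpression(CqTable(df))
  treated <- which(sampleInfo(expr)$time_h == 6)
  expect_true(is.na(rq(expr)["GA", treated]))
  expect_false(anyNA(rq(expr)["GB", ]))
  # gene measured only in the treated sample cannot be normalized
  df2 <- records(toy_cq())
  extra <- df2[df2$time_h == 6 & df2$gene == "GA", ]
  extra$gene <- "GC"
  expect_error(relativeExpression(CqTable(rbind(df2, extra))),
               "absent from the control")
})

test_that("own-lot control mode normalizes each lot to its own dry seeds", {
  design <- designConfig(rng_seed = 5)
  tab <- generateCqTable(design, effectConfig(design))
  expr <- relativeExpression(tab, control = "own_lot")
  info <- sampleInfo(expr)
  for (lt in c("lot1", "lot2")) {
    ctrl <- which(info$time_h == 0 & info$lot == lt & info$cultivar == "cv1")
    expect_equal(max(abs(rowMeans(log2rq(expr)[, ctrl]))), 0, tolerance = 1e-9)
  }
})

test_that("randomization test matches exhaustive enumeration for 3 vs 3", {
  set.seed(42)
  for (i in 1:5) {
    ctl <- cbind(rnorm(3, 24), rnorm(3, 20, 0.1))
    trt <- cbind(rnorm(3, 23 + i * 0.3), rnorm(3, 20, 0.1))
    res <- randomizationTest(ctl, trt)
    expect_true(res$exhaustive)
    expect_identical(res$n_realloc, 20L)  # C(6, 3)
    p_oracle <- randomization_p_oracle(ctl[, 1] - ctl[, 2],
                                       trt[, 1] - trt[, 2])
    expect_equal(res$p.value, p_oracle)
    # two-sided statistic: swapping group labels changes nothing
    expect_equal(randomizationTest(trt, ctl)$p.value, res$p.value)
  }
})

test_that("well-separated groups reach the minimal exhaustive p-value", {
  ctl <- cbind(c(26, 26.1, 25.9), c(20, 20, 20))
  trt <- cbind(c(22, 22.1, 21.9), c(20, 20, 20))
  res <- randomizationTest(ctl, trt)
  # only the observed split and its mirror reach the observed statistic
  expect_equal(res$p.value, 2 / 20)
})

test_that("randomization degenerate and Monte Carlo branches behave", {
  same <- cbind(c(24, 24, 24), c(20, 20, 20))
  expect_warning(res <- randomizationTest(same, same), "degenerate")
  expect_equal(res$p.value, 1)
  # 8 vs 8 with n_perm 500 forces Monte Carlo; seeded draws are reproducible
  set.seed(9)
  ctl <- cbind(rnorm(8, 24), rnorm(8, 20, 0.1))
  trt <- cbind(rnorm(8, 23.4), rnorm(8, 20, 0.1))
  a <- randomizationTest(ctl, trt, n_perm = 500, seed = 11)
  b <- randomizationTest(ctl, trt, n_perm = 500, seed = 11)
  expect_false(a$exhaustive)
  expect_identical(a$p.value, b$p.value)
  expect_error(randomizationTest(ctl[1, , drop = FALSE], trt),
               "at least 2 replicates")
})
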