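hill_pct <- function(t, gmax, t50, h) gmax * t^h / (t50^h + t^h)

test_that("a noiseless Hill curve is recovered within 1%", {
  t <- seq(6, 60, 6)
  course <- data.frame(time_h = t, cumulative = hill_pct(t, 90, 30, 6),
                       total = 100)
  fit <- fitHill(course)
  expect_true(fit@converged)
  expect_lt(abs(fit@gmax - 90) / 90, 0.01)
  expect_lt(abs(fit@t50 - 30) / 30, 0.01)
  expect_lt(abs(fit@shape - 6) / 6, 0.01)
  # Hill identity: the curve evaluated at the fitted t50 is half the maximum
  expect_lt(abs(hill_pct(fit@t50, fit@gmax, fit@t50, fit@shape) -
                  fit@gmax / 2), 1e-6)
})

test_that("the fit is invariant to counts versus percentages", {
  t <- seq(6, 72, 6)
  counts <- round(25 * hill_pct(t, 92, 33, 5) / 100)
  as_counts <- data.frame(time_h = t, cumulative = counts, total = 25)
  as_pct <- data.frame(time_h = t, cumulative = 100 * counts / 25, total = 100)
  f1 <- fitHill(as_counts)
  f2 <- fitHill(as_pct)
  expect_equal(f1@t50, f2@t50, tolerance = 1e-8)
  expect_equal(f1@gmax, f2@gmax, tolerance = 1e-8)
})

test_that("degenerate courses raise informative errors", {
  expect_error(fitHill(data.frame(time_h = c(6, 12, 18), cumulative = c(0, 1, 5),
                                  total = 25)), "insufficient data")
  expect_error(fitHill(data.frame(time_h = seq(6, 30, 6),
                                  cumulative = rep(0, 5), total = 25)),
               "insufficient data")
  expect_error(t50Interpolated(data.frame(time_h = seq(6, 30, 6),
                                          cumulative = rep(0, 5), total = 25)),
               "undefined")
})

test_that("interpolated t50 brackets the half-maximum crossing", {
  # crossing hit exactly at an observation
  exact <- data.frame(time_h = c(12, 18, 24, 30),
                      cumulative = c(10, 25, 40, 80), total = 100)
  expect_equal(t50Interpolated(exact), 24)  # half of 80 is 40, met at 24 h
  # crossing between observations: 50 between (24, 30) and (30, 70)
  between <- data.frame(time_h = c(24, 30, 36),
                        cumulative = c(30, 70, 100), total = 100)
  expect_equal(t50Interpolated(between), 27)
  # time-scaling equivariance
  doubled <- between
  doubled$time_h <- doubled$time_h * 2
  expect_equal(t50Interpolated(doubled), 54)
})

test_that("binomial-noise courses recover t50 with < 10% median error", {
  set.seed(21)
  errs <- replicate(40, {
    t50_true <- runif(1, 25, 45)
    t <- seq(6, 96, 6)
    p <- hill_pct(t, 95, t50_true, 6) / 100
    # simulate 25 seeds with per-seed germination times implied by the curve
    times <- t50_true * (runif(25) / (1 - runif(25)))^(1 / 6)
    keep <- runif(25) < 0.95
    cum <- vapply(t, function(tt) sum(times[keep] <= tt), integer(1))
    fit <- fitHill(data.frame(time_h = t, cumulative = cum, total = 25))
    abs(fit@t50 - t50_true) / t50_true
  })
  expect_lt(median(errs), 0.10)
})

test_that("t50Table summarizes per condition and tolerates empty input", {
  t <- seq(6, 60, 6)
  one <- data.frame(condition = "25C", replicate = 1, time_h = t,
                    cumulative = hill_pct(t, 90, 30, 6), total = 100)
  two <- one
  two$replicate <- 2
  tab <- t50Table(GerminationCourses(rbind(one, two)))
  expect_equal(nrow(tab$t50), 2)
  expect_equal(tab$summary$sd_t50_h, 0, tolerance = 1e-8)

  empty <- GerminationCourses(data.frame(condition = character(),
                                         replicate = integer(),
                                         time_h = numeric(),
                                         cumulative = numeric(),
                                         total = numeric()))
  out <- t50Table(empty)
  expect_equal(nrow(out$t50), 0)
})

test_that("lots generated slower to germinate rank slower after fitting", {
  set.seed(4)
  t <- seq(6, 120, 6)
  course_at <- function(t50_true, rep) {
    times <- t50_true * (runif(25) / (1 - runif(25)))^(1 / 6)
    data.frame(condition = sprintf("t%g", t50_true), replicate = rep,
               time_h = t,
               cumulative = vapply(t, function(tt) sum(times <= tt),
                                   integer(1)),
               total = 25)
  }
  courses <- do.call(rbind, c(lapply(1:4, function(r) course_at(35, r)),
                              lapply(1:4, function(r) course_at(45, r))))
  summ <- t50Table(GerminationCourses(courses))$summary
  expect_lt(summ$mean_t50_h[summ$condition == "t35"],
            summ$mean_t50_h[summ$condition == "t45"])
})
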