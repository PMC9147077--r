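# Germination kinetics: Hill-curve fitting of cumulative time courses and
# extraction of t50 (time to 50% of the fitted maximum root protrusion).

.courseFrame <- function(course) {
  if (is(course, "GerminationCourses")) {
    df <- course@records
    keys <- unique(.courseKey(df))
    if (length(keys) != 1L)
      .stopf("fitHill()/t50Interpolated() expect a single course; got %d (use t50Table())",
             length(keys))
    course <- df
  }
  df <- as.data.frame(course)
  df <- df[order(df$time_h), ]
  df
}

#' Fit a Hill curve to a cumulative germination course
#'
#' Least-squares fit of `G(t) = gmax * t^h / (t50^h + t^h)` to the
#' cumulative germination percentage, the model used by seed-germination
#' curve-fitting tools to extract t50. The fit is multi-started: `t50` is
#' initialized from linear interpolation at half-maximum and the Hill
#' exponent from each of `h = 1, 4, 10`; the best converged start (lowest
#' residual sum of squares) wins. Because the model is parameterized in
#' `t50`, `G(t50) = gmax / 2` holds exactly for every fit. If no start
#' converges the interpolated t50 is returned with `converged = FALSE`.
#'
#' The fit is invariant to expressing the course as counts or percentages:
#' counts are converted to percentages of `total` before fitting.
#'
#' @param course a single-course [GerminationCourses] object or a
#'   `data.frame` with columns `time_h`, `cumulative`, `total`.
#' @param lag optional lag time (h) subtracted from the observation times
#'   before fitting; off (0) by default.
#' @return a [HillFit].
#' @examples
#' t <- seq(6, 60, 6)
#' g <- 90 * t^6 / (30^6 + t^6)
#' fitHill(data.frame(time_h = t, cumulative = g, total = 100))
#' @export
fitHill <- function(course, lag = 0) {
  df <- .courseFrame(course)
  if (nrow(df) < 4L)
    .stopf("insufficient data: need >= 4 observation times, got %d", nrow(df))
  if (max(df$cumulative) <= 0)
    .stopf("insufficient data: no germination observed")
  t <- df$time_h - lag
  y <- 100 * df$cumulative / df$total
  t50_0 <- tryCatch(t50Interpolated(df), error = function(e) NA_real_)
  if (is.na(t50_0)) t50_0 <- stats::median(t)
  gmax_0 <- min(max(y), 100)

  best <- NULL
  for (h0 in c(1, 4, 10)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ gmax * t^h / (t50^h + t^h),
        start = list(gmax = gmax_0, t50 = t50_0, h = h0),
        lower = c(gmax = 1e-6, t50 = 1e-6, h = 1e-6),
        upper = c(gmax = 100, t50 = Inf, h = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- c(as.list(stats::coef(fit)), rss = rss)
  }
  if (is.null(best)) {
    return(new("HillFit", gmax = gmax_0, t50 = t50_0, shape = NA_real_,
               rss = NA_real_, converged = FALSE, n_obs = nrow(df)))
  }
  new("HillFit", gmax = best$gmax, t50 = best$t50, shape = best$h,
      rss = best$rss, converged = TRUE, n_obs = nrow(df))
}

#' Interpolated t50 of a cumulative course
#'
#' Fallback estimator: the time at which the cumulative count crosses half
#' of its final value, linearly interpolated between the bracketing
#' observation times (taking `(0, 0)` as the germination start before the
#' first observation).
#'
#' @inheritParams fitHill
#' @return t50 in hours.
#' @examples
#' t50Interpolated(data.frame(time_h = c(24, 30, 36),
#'                            cumulative = c(30, 70, 100), total = 100))  # 27
#' @export
t50Interpolated <- function(course) {
  df <- .courseFrame(course)
  half <- max(df$cumulative) / 2
  if (max(df$cumulative) <= 0)
    .stopf("t50 undefined: the course never crosses half-maximum")
  i <- which(df$cumulative >= half)[1]
  t1 <- if (i == 1L) 0 else df$time_h[i - 1L]
  c1 <- if (i == 1L) 0 else df$cumulative[i - 1L]
  if (df$cumulative[i] == c1) return(df$time_h[i])
  t1 + (df$time_h[i] - t1) * (half - c1) / (df$cumulative[i] - c1)
}

#' t50 per course, with per-condition summaries
#'
#' Fits every course in the table with [fitHill()] (falling back to
#' interpolation where the fit does not converge) and returns one t50 per
#' replicate plus a mean +/- sd summary per condition group.
#'
#' @param courses a [GerminationCourses] table.
#' @return a list with `t50`: a `data.frame` of per-course results
#'   (identifier columns, `t50_h`, `gmax_pct`, `converged`), and `summary`:
#'   mean and sd of `t50_h` per condition group.
#' @export
t50Table <- function(courses) {
  stopifnot(is(courses, "GerminationCourses"))
  df <- courses@records
  id_cols <- intersect(c("cultivar", "lot", "condition", "replicate"), names(df))
  if (!nrow(df)) {
    empty <- df[id_cols]
    empty$t50_h <- numeric()
    empty$gmax_pct <- numeric()
    empty$converged <- logical()
    return(list(t50 = empty, summary = empty[setdiff(id_cols, "replicate")]))
  }
  key <- .courseKey(df)
  pieces <- lapply(unique(key), function(k) {
    sub <- df[key == k, ]
    fit <- fitHill(sub)
    out <- sub[1, id_cols, drop = FALSE]
    out$t50_h <- fit@t50
    out$gmax_pct <- fit@gmax
    out$converged <- fit@converged
    out
  })
  t50 <- do.call(rbind, pieces)
  rownames(t50) <- NULL
  grp_cols <- setdiff(id_cols, "replicate")
  grp <- interaction(t50[grp_cols], drop = TRUE, lex.order = TRUE)
  summ <- do.call(rbind, lapply(levels(grp), function(g) {
    sub <- t50[grp == g, ]
    out <- sub[1, grp_cols, drop = FALSE]
    out$mean_t50_h <- mean(sub$t50_h)
    out$sd_t50_h <- if (nrow(sub) > 1) sd(sub$t50_h) else 0
    out$n <- nrow(sub)
    out
  }))
  rownames(summ) <- NULL
  list(t50 = t50, summary = summ)
}
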