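#' Pair current and future occurrence probabilities at random coordinates
#'
#' Draws `n` random points over the jointly valid cells of the two grids
#' (cell-uniform, jittered within cells) and extracts both probabilities,
#' so every pair is complete by construction.
#'
#' @param current,future Aligned probability [env_grid()]s.
#' @param n Number of points (default 10000).
#' @param seed Integer seed.
#' @return A tibble with `lon`, `lat`, `p_current`, `p_future`.
#' @export
pair_probabilities <- function(current, future, n = 10000, seed = 1L) {
  stop_if_misaligned(current, future)
  joint <- current$values
  joint[is.na(future$values)] <- NA_real_
  mask <- env_grid(joint, current$origin_lon, current$origin_lat,
                   current$cellsize)
  pts <- sample_random_points(mask, n, seed = seed)
  lin <- cbind(pts$row, pts$col)
  tibble::tibble(lon = pts$lon, lat = pts$lat,
                 p_current = current$values[lin],
                 p_future = future$values[lin])
}

#' Least-squares fit of future on current probabilities
#'
#' Fits `p_future = beta0 + beta1 * p_current` by ordinary least squares and
#' reports the estimates, their standard errors, the overall F statistic
#' with (1, n-2) degrees of freedom, and R-squared.
#'
#' @param pairs A data frame with `p_current` and `p_future` columns (e.g.
#'   from [pair_probabilities()]).
#' @return An object of class `identity_ols`.
#' @export
ols_fit <- function(pairs) {
  df <- as.data.frame(pairs)
  if (!all(c("p_current", "p_future") %in% names(df)))
    stop("`pairs` must have p_current and p_future columns", call. = FALSE)
  if (nrow(df) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(df$p_current) == 0)
    stop("current probabilities are constant; slope undefined",
         call. = FALSE)
  fit <- stats::lm(p_future ~ p_current, data = df)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  n <- nrow(df)
  # an (all but) exact linear relation leaves no residual scale to test with
  degenerate <- sm$sigma <= 1e-10 * max(1, stats::sd(df$p_future))
  fstat <- if (!degenerate) unname(sm$fstatistic[1]) else Inf
  structure(
    list(beta0 = unname(co[1, 1]), beta1 = unname(co[2, 1]),
         se_beta0 = unname(co[1, 2]), se_beta1 = unname(co[2, 2]),
         sigma = sm$sigma, r_squared = sm$r.squared,
         f_statistic = fstat, df = c(1L, n - 2L), n = n,
         degenerate_se = degenerate, fit = fit),
    class = "identity_ols")
}

#' @export
print.identity_ols <- function(x, ...) {
  cat(sprintf("<identity_ols> Pf = %.3f + %.3f Pc  (n = %d)\n",
              x$beta0, x$beta1, x$n))
  cat(sprintf("  F(%d, %d) = %.3f, R^2 = %.3f\n",
              x$df[1], x$df[2], x$f_statistic, x$r_squared))
  invisible(x)
}

#' @export
#' @method tidy identity_ols
tidy.identity_ols <- function(x, ...) {
  tibble::tibble(
    term = c("beta0", "beta1"),
    estimate = c(x$beta0, x$beta1),
    std.error = c(x$se_beta0, x$se_beta1))
}

#' @export
#' @method glance identity_ols
glance.identity_ols <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, sigma = x$sigma,
    statistic = x$f_statistic, df = x$df[1], df.residual = x$df[2],
    nobs = x$n)
}

#' Student t-tests of the regression against the identity line
#'
#' Tests `beta0 = 0` and `beta1 = 1` (two-sided, `n - 2` df). The
#' no-climate-change null predicts the identity line; an "expansion" flag is
#' raised when the fitted line lies above the identity line at the mean of
#' the current probabilities and the intercept is positive.
#'
#' @param report An [ols_fit()] object.
#' @param beta0_null,beta1_null Theoretical values (0 and 1).
#' @param alpha Significance level.
#' @return A one-row tibble: `t0`, `p0`, `reject_beta0`, `t1`, `p1`,
#'   `reject_beta1`, `expansion_above_identity`, `degenerate`.
#' @export
test_against_theory <- function(report, beta0_null = 0, beta1_null = 1,
                                alpha = 0.05) {
  stopifnot(inherits(report, "identity_ols"))
  if (report$degenerate_se || report$se_beta0 == 0 || report$se_beta1 == 0) {
    warning("degenerate standard errors; no test decision", call. = FALSE)
    return(tibble::tibble(
      t0 = NA_real_, p0 = NA_real_, reject_beta0 = NA,
      t1 = NA_real_, p1 = NA_real_, reject_beta1 = NA,
      expansion_above_identity = NA, degenerate = TRUE))
  }
  dfree <- report$df[2]
  t0 <- (report$beta0 - beta0_null) / report$se_beta0
  t1 <- (report$beta1 - beta1_null) / report$se_beta1
  p0 <- 2 * stats::pt(abs(t0), dfree, lower.tail = FALSE)
  p1 <- 2 * stats::pt(abs(t1), dfree, lower.tail = FALSE)
  xbar <- mean(report$fit$model$p_current)
  above <- report$beta0 > 0 &&
    (report$beta0 + report$beta1 * xbar) > xbar
  tibble::tibble(
    t0 = t0, p0 = p0, reject_beta0 = p0 < alpha,
    t1 = t1, p1 = p1, reject_beta1 = p1 < alpha,
    expansion_above_identity = above, degenerate = FALSE)
}

#' Change-regression table across scenarios
#'
#' Runs [pair_probabilities()], [ols_fit()] and [test_against_theory()] for
#' each scenario grid against the current grid, reusing one seeded point set
#' across scenarios for comparability. No multiple-testing correction is
#' applied across scenarios.
#'
#' @param current Current probability [env_grid()].
#' @param futures Named list of future probability grids.
#' @param n Points per regression.
#' @param seed Integer seed (one point set shared across scenarios).
#' @param alpha Significance level.
#' @return A tibble, one row per scenario: estimates, F, R-squared, test
#'   decisions, and a fitted-function string.
#' @export
change_table <- function(current, futures, n = 10000, seed = 1L,
                         alpha = 0.05) {
  rows <- lapply(names(futures), function(lbl) {
    pairs <- pair_probabilities(current, futures[[lbl]], n = n, seed = seed)
    rep_ <- ols_fit(pairs)
    dec <- test_against_theory(rep_, alpha = alpha)
    tibble::tibble(
      scenario = lbl, n = rep_$n,
      beta0 = rep_$beta0, beta1 = rep_$beta1,
      se_beta0 = rep_$se_beta0, se_beta1 = rep_$se_beta1,
      f_statistic = rep_$f_statistic, df1 = rep_$df[1], df2 = rep_$df[2],
      r_squared = rep_$r_squared,
      t0 = dec$t0, p0 = dec$p0, reject_beta0 = dec$reject_beta0,
      t1 = dec$t1, p1 = dec$p1, reject_beta1 = dec$reject_beta1,
      expansion_above_identity = dec$expansion_above_identity,
      fitted_function = sprintf("Pf = %.3f%s + %.3f%s * Pc",
                                rep_$beta0,
                                ifelse(isTRUE(dec$reject_beta0), " *", ""),
                                rep_$beta1,
                                ifelse(isTRUE(dec$reject_beta1), " *", "")))
  })
  dplyr::bind_rows(rows)
}
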