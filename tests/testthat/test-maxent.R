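# Feature expansion -----------------------------------------------------

test_that("feature expansion scales, counts, and drops degenerate pieces", {
  df <- data.frame(a = c(0, 5, 10), b = c(-1, 0, 1))
  lin <- build_features(df, kinds = "linear")
  F1 <- feature_matrix(lin, df)
  expect_equal(ncol(F1), 2)
  expect_equal(range(F1[, "a"]), c(0, 1))
  expect_equal(range(F1[, "b"]), c(0, 1))

  lq <- build_features(df, kinds = c("linear", "quadratic"))
  expect_equal(length(lq$features), 4)

  full <- build_features(df, n_hinge_knots = 5)
  kinds <- vapply(full$features, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "product"), 1)
  expect_equal(sum(kinds == "hinge"), 10)  # knot at the max is dropped
  Ff <- feature_matrix(full, df)
  expect_true(all(Ff >= 0 & Ff <= 1))

  expect_warning(build_features(data.frame(a = c(1, 2), c = c(3, 3))),
                 "constant")
})

test_that("hinge features rise linearly from their knot", {
  df <- data.frame(a = seq(0, 10, by = 1))
  expn <- build_features(df, kinds = "hinge", n_hinge_knots = 2)
  # knots at 0 and 5
  Fm <- feature_matrix(expn, data.frame(a = c(0, 2.5, 5, 7.5, 10)))
  expect_equal(Fm[, 1], c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(Fm[, 2], c(0, 0, 0, 0.5, 1))
})

# Fitting ----------------------------------------------------------------

test_that("the unconstrained model is uniform over the background", {
  B <- matrix(numeric(0), nrow = 100, ncol = 0)
  P <- matrix(numeric(0), nrow = 5, ncol = 0)
  m <- fit_maxent(P, B)
  raw <- predict_raw(m, B)
  expect_equal(raw, rep(1 / 100, 100))
  expect_equal(to_logistic(m, raw), rep(0.5, 100))
  expect_equal(training_gain(m, P), 0)
  expect_true(m$converged)
})

test_that("a single unpenalized linear feature matches the Newton oracle", {
  set.seed(31)
  for (rep in 1:5) {
    bg <- runif(400)
    pres <- sample(bg, 60, replace = TRUE, prob = bg^2)
    lam_star <- newton_single_feature(pres, bg)
    m <- fit_maxent(matrix(pres), matrix(bg), betas = 0,
                    max_iter = 5000, tol = 1e-10)
    expect_true(m$converged)
    expect_equal(m$lambda, lam_star, tolerance = 1e-6)
  }
})

test_that("an active L1 penalty pins the moment gap at beta", {
  set.seed(32)
  bg <- runif(500)
  pres <- sample(bg, 80, replace = TRUE, prob = exp(3 * bg))
  beta <- 0.1
  m <- fit_maxent(matrix(pres), matrix(bg), betas = beta,
                  max_iter = 5000, tol = 1e-9)
  stopifnot(m$lambda != 0)
  q <- predict_raw(m, matrix(bg))
  gap <- mean(pres) - sum(q * bg)
  expect_equal(abs(gap), beta, tolerance = 1e-6)
})

test_that("KKT certificate holds on every converged fit", {
  w <- tiny_world(seed = 33)
  bg <- nichecast:::draw_background(w$stack, w$occ, 350, seed = 1)
  expn <- build_features(bg$values)
  B <- feature_matrix(expn, bg$values)
  pv <- extract_values(w$stack, w$occ)
  P <- feature_matrix(expn, pv)
  betas <- default_betas(expn, P)
  m <- fit_maxent(P, B, betas = betas, expansion = expn)
  expect_true(m$converged)
  q <- predict_raw(m, B)
  moments_bg <- as.numeric(crossprod(B, q))
  gap <- colMeans(P) - moments_bg
  expect_true(all(abs(gap) <= betas + 1e-4))
  active <- which(m$lambda != 0)
  expect_equal(gap[active], sign(m$lambda[active]) * betas[active],
               tolerance = 1e-3)
})

test_that("the fitted objective beats random weight vectors (convexity)", {
  w <- tiny_world(seed = 34, nrows = 12, ncols = 12, n_presences = 50)
  bg <- nichecast:::draw_background(w$stack, w$occ, 144, seed = 2)
  expn <- build_features(bg$values, kinds = c("linear", "quadratic"))
  B <- feature_matrix(expn, bg$values)
  P <- feature_matrix(expn, extract_values(w$stack, w$occ))
  betas <- default_betas(expn, P)
  m <- fit_maxent(P, B, betas = betas)
  obj <- function(lam) {
    eta <- as.numeric(B %*% lam)
    mx <- max(eta)
    mx + log(sum(exp(eta - mx))) - sum(colMeans(P) * lam) +
      sum(betas * abs(lam))
  }
  fitted_obj <- obj(m$lambda)
  set.seed(99)
  for (i in 1:100)
    expect_gte(obj(rnorm(ncol(B))), fitted_obj - 1e-10)
})

test_that("shifting a variable by a constant leaves raw predictions unchanged", {
  w <- tiny_world(seed = 35, nrows = 15, ncols = 15, n_presences = 60)
  bg <- nichecast:::draw_background(w$stack, w$occ, 225, seed = 3)
  pv <- extract_values(w$stack, w$occ)
  fit_on <- function(bvals, pvals) {
    expn <- build_features(bvals, kinds = c("linear", "quadratic", "hinge"))
    B <- feature_matrix(expn, bvals)
    P <- feature_matrix(expn, pvals)
    m <- fit_maxent(P, B, betas = default_betas(expn, P), expansion = expn,
                    max_iter = 2000, tol = 1e-8)
    list(raw = predict_raw(m, B), p = predict_raw(m, P))
  }
  a <- fit_on(bg$values, pv)
  bg2 <- bg$values; bg2$env1 <- bg2$env1 + 100
  pv2 <- pv; pv2$env1 <- pv2$env1 + 100
  b <- fit_on(bg2, pv2)
  expect_equal(a$raw, b$raw, tolerance = 1e-5)
  expect_equal(auc(a$p, a$raw), auc(b$p, b$raw), tolerance = 1e-6)
})

# Prediction and gain ----------------------------------------------------

test_that("raw weights normalize over the background and rank monotonically", {
  w <- tiny_world(seed = 36, nrows = 10, ncols = 10, n_presences = 40)
  bg <- nichecast:::draw_background(w$stack, w$occ, 100, seed = 4)
  expn <- build_features(bg$values, kinds = "linear")
  B <- feature_matrix(expn, bg$values)
  P <- feature_matrix(expn, extract_values(w$stack, w$occ))
  m <- fit_maxent(P, B, betas = 0, expansion = expn)
  raw <- predict_raw(m, B)
  expect_true(all(raw > 0))
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  eta <- as.numeric(B %*% m$lambda)
  expect_equal(order(eta), order(raw))
  p <- to_logistic(m, raw)
  expect_equal(order(raw), order(p))
  expect_true(all(p > 0 & p < 1))
  expect_error(predict_raw(m, B[, -1, drop = FALSE]), "width")
})

test_that("training gain matches an independent log-likelihood summation", {
  w <- tiny_world(seed = 37, nrows = 10, ncols = 10, n_presences = 40)
  bg <- nichecast:::draw_background(w$stack, w$occ, 100, seed = 5)
  expn <- build_features(bg$values, kinds = c("linear", "quadratic"))
  B <- feature_matrix(expn, bg$values)
  P <- feature_matrix(expn, extract_values(w$stack, w$occ))
  betas <- default_betas(expn, P)
  m <- fit_maxent(P, B, betas = betas)
  # oracle: direct re-summation from eta and an explicit log Z
  eta_p <- as.numeric(P %*% m$lambda)
  eta_b <- as.numeric(B %*% m$lambda)
  log_z <- log(sum(exp(eta_b)))
  oracle <- mean(eta_p - log_z + log(nrow(B))) - sum(betas * abs(m$lambda))
  expect_equal(training_gain(m, P), oracle, tolerance = 1e-10)
  # unregularized fits cannot fall below the uniform model
  m0 <- fit_maxent(P, B, betas = 0)
  expect_gte(training_gain(m0, P), -1e-8)
})

test_that("response curves follow the fitted model's shape", {
  set.seed(38)
  bvals <- data.frame(env1 = runif(300), env2 = runif(300))
  pvals <- data.frame(env1 = runif(60)^0.3, env2 = runif(60))
  expn <- build_features(bvals, kinds = "linear")
  B <- feature_matrix(expn, bvals)
  P <- feature_matrix(expn, pvals)
  m <- fit_maxent(P, B, betas = 0, expansion = expn)
  stopifnot(m$lambda[1] > 0)
  means <- vapply(bvals, mean, numeric(1))
  rc <- response_curve(m, "env1", means, n_points = 50)
  expect_true(all(diff(rc$probability) >= -1e-12))
  # endpoints equal direct predictions at the range ends
  at_ends <- predict_maxent(m, data.frame(
    env1 = range(bvals$env1), env2 = rep(means["env2"], 2)))
  expect_equal(rc$probability[c(1, 50)], at_ends, tolerance = 1e-12)
  # flat model: constant 0.5
  m0 <- fit_maxent(P[, 0, drop = FALSE], B[, 0, drop = FALSE],
                   expansion = build_features(bvals[0 < 1, ],
                                              kinds = "linear"))
  m0$lambda <- c(0, 0)
  expect_error(response_curve(m, "nope", means), "unknown")
})

test_that("model serialization reproduces predictions exactly", {
  w <- tiny_world(seed = 39, nrows = 10, ncols = 10, n_presences = 50)
  bg <- nichecast:::draw_background(w$stack, w$occ, 100, seed = 6)
  expn <- build_features(bg$values)
  B <- feature_matrix(expn, bg$values)
  P <- feature_matrix(expn, extract_values(w$stack, w$occ))
  m <- fit_maxent(P, B, betas = default_betas(expn, P), expansion = expn)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent(m, path)
  m2 <- read_maxent(path)
  expect_equal(predict_raw(m2, B), predict_raw(m, B), tolerance = 1e-12)
  expect_equal(predict_maxent(m2, bg$values), predict_maxent(m, bg$values),
               tolerance = 1e-12)
  expect_equal(m2$lambda, m$lambda, tolerance = 1e-12)
  expect_identical(m2$feature_names, m$feature_names)
})
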