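test_that("presence splitting is seeded, disjoint, and exhaustive", {
  occ <- occ_table(lon = runif(100), lat = runif(100))
  sp <- split_presences(occ, seed = 3)
  expect_length(sp$train, 75)
  expect_length(sp$test, 25)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), occ$record_id)
  expect_identical(sp, split_presences(occ, seed = 3))
  expect_false(identical(sp, split_presences(occ, seed = 4)))
  expect_error(split_presences(occ_table(lon = 1:3, lat = 1:3)),
               "at least 4")
})

test_that("AUC equals brute-force all-pairs concordance", {
  expect_equal(auc(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  expect_equal(auc(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  set.seed(41)
  for (i in 1:100) {
    np <- sample(1:200, 1); nb <- sample(1:200, 1)
    # discrete support forces ties through both code paths
    pres <- sample(seq(0, 1, by = 0.05), np, replace = TRUE)
    bg <- sample(seq(0, 1, by = 0.05), nb, replace = TRUE)
    expect_equal(auc(pres, bg), brute_auc(pres, bg), tolerance = 1e-12)
  }
})

test_that("a one-run ensemble integrates to that run's grid", {
  w <- tiny_world(seed = 43)
  ens <- run_ensemble(w$occ, w$stack,
                      config = ensemble_config(n_runs = 1,
                                               n_background = 400),
                      seed = 7)
  m <- ens$models[[1]]
  single <- predict_grid(m, w$stack)
  expect_equal(ens$integrated$values, single$values, tolerance = 1e-12)
  expect_equal(nrow(ens$runs), 1)
  expect_true(is.na(ens$auc_se) || ens$auc_se == 0)
})

test_that("the ensemble is reproducible and discriminates on a synthetic world", {
  w <- tiny_world(seed = 44, nrows = 25, ncols = 25, n_presences = 120)
  cfg <- ensemble_config(n_runs = 6, n_background = 625)
  ens <- run_ensemble(w$occ, w$stack, config = cfg, seed = 8)
  ens2 <- run_ensemble(w$occ, w$stack, config = cfg, seed = 8)
  expect_equal(ens$integrated$values, ens2$integrated$values)
  expect_identical(ens$runs$auc, ens2$runs$auc)
  expect_gt(ens$auc_mean, 0.7)
  expect_true(all(ens$runs$converged))
  # bootstrap semantics: train size fixed, test = out-of-bag, both non-empty
  expect_true(all(ens$runs$n_train == round(0.75 * nrow(ens$occ))))
  expect_true(all(ens$runs$n_test > 0))
  for (r in seq_len(nrow(ens$runs)))
    expect_length(intersect(ens$runs$train_ids[[r]],
                            ens$runs$test_ids[[r]]), 0)
  # integration is the mean of converged run grids
  per_run <- lapply(ens$models, predict_grid, stack = w$stack)
  manual <- Reduce(`+`, lapply(per_run, `[[`, "values")) / length(per_run)
  expect_equal(ens$integrated$values, manual, tolerance = 1e-12)
})

test_that("subsample mode gives disjoint exhaustive splits per run", {
  w <- tiny_world(seed = 45)
  ens <- run_ensemble(w$occ, w$stack,
                      config = ensemble_config(n_runs = 3, n_background = 400,
                                               replicate_mode = "subsample"),
                      seed = 9)
  for (r in 1:3) {
    ids <- c(ens$runs$train_ids[[r]], ens$runs$test_ids[[r]])
    expect_setequal(ids, ens$occ$record_id)
  }
})

test_that("permutation contribution isolates informative variables", {
  set.seed(46)
  n_bg <- 400
  bvals <- data.frame(env1 = runif(n_bg), env2 = runif(n_bg))
  pvals <- data.frame(env1 = rbeta(80, 4, 1), env2 = runif(80))
  expn <- build_features(bvals, kinds = "linear")
  B <- feature_matrix(expn, bvals)
  P <- feature_matrix(expn, pvals)
  m <- fit_maxent(P, B, betas = default_betas(expn, P), expansion = expn)
  contrib <- permutation_contribution(m, pvals, bvals, n_perm = 5, seed = 1)
  expect_equal(sum(contrib$contribution_pct), 100, tolerance = 1e-9)
  expect_gt(contrib$contribution_pct[contrib$variable == "env1"], 50)

  # single-variable model: all contribution on that variable
  expn1 <- build_features(bvals["env1"], kinds = "linear")
  m1 <- fit_maxent(feature_matrix(expn1, pvals["env1"]),
                   feature_matrix(expn1, bvals["env1"]),
                   betas = 0, expansion = expn1)
  c1 <- permutation_contribution(m1, pvals["env1"], bvals["env1"],
                                 n_perm = 3, seed = 2)
  expect_equal(c1$contribution_pct, 100)

  # all-zero weights: uniform shares under a warning
  m0 <- m
  m0$lambda <- rep(0, length(m0$lambda))
  m0$log_z <- log(n_bg)
  expect_warning(c0 <- permutation_contribution(m0, pvals, bvals,
                                                n_perm = 2, seed = 3),
                 "uniform")
  expect_equal(c0$contribution_pct, c(50, 50))
})

test_that("jackknife gains reflect redundancy and information content", {
  set.seed(47)
  st <- tiny_stack(20, 20, n_layers = 2, seed = 48)
  # env3 duplicates env1; env2 is pure noise relative to the niche
  st <- grid_stack(c(st$layers,
                     list(env3 = st$layers$env1)))
  truth <- true_suitability(st, -1.5, c(env1 = 2.5))
  occ <- sample_occurrences(truth, 100, seed = 49)
  cfg <- ensemble_config(n_background = 400,
                         feature_kinds = c("linear", "quadratic"))
  jack <- jackknife_gains(occ, st, config = cfg, seed = 10)
  full <- attr(jack, "full_gain")
  expect_equal(nrow(jack), 3)
  expect_true(all(is.finite(c(jack$gain_only, jack$gain_without, full))))
  # dropping one of a duplicated pair costs (almost) nothing
  expect_equal(jack$gain_without[jack$variable == "env3"], full,
               tolerance = 0.05)
  # the informative variable outruns the noise variable alone
  expect_gt(jack$gain_only[jack$variable == "env1"],
            jack$gain_only[jack$variable == "env2"])
})

test_that("with-only gains never exceed the full unregularized gain", {
  w <- tiny_world(seed = 51, nrows = 15, ncols = 15, n_presences = 80)
  cfg <- ensemble_config(n_background = 225, reg_multiplier = 0,
                         feature_kinds = c("linear", "quadratic"),
                         max_iter = 2000, tol = 1e-7)
  jack <- jackknife_gains(w$occ, w$stack, config = cfg, seed = 11)
  full <- attr(jack, "full_gain")
  expect_true(all(jack$gain_only <= full + 1e-4))
  expect_true(all(jack$gain_without <= full + 1e-4))
})
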