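make_fitted <- function(seed = 61, n_runs = 3) {
  w <- tiny_world(seed = seed)
  ens <- run_ensemble(w$occ, w$stack,
                      config = ensemble_config(n_runs = n_runs,
                                               n_background = 400),
                      seed = seed + 1)
  list(w = w, ens = ens)
}

test_that("projection onto the training stack reproduces the integrated grid", {
  f <- make_fitted()
  proj <- project_ensemble(f$ens, f$w$stack)
  expect_equal(proj$values, f$ens$integrated$values, tolerance = 1e-12)
  # a single-run ensemble projects to that model's own prediction
  f1 <- make_fitted(seed = 62, n_runs = 1)
  proj1 <- project_ensemble(f1$ens, f1$w$stack)
  expect_equal(proj1$values,
               predict_grid(f1$ens$models[[1]], f1$w$stack)$values,
               tolerance = 1e-12)
  expect_error(project_ensemble(f$ens, grid_stack(f$w$stack$layers[1])),
               "lacks layer")
})

test_that("habitat classification follows the 0.1/0.5 thresholds", {
  p <- env_grid(matrix(c(0.05, 0.3, 0.7, 0.1, 0.5, NA), 2, 3), 0, 2, 1)
  cls <- classify_habitat(p)
  expect_equal(cls$values[1, 1], 0)  # below 0.1: unsuitable
  expect_equal(cls$values[2, 1], 1)  # between 0.1 and 0.5: moderate
  expect_equal(cls$values[1, 2], 2)  # above 0.5: high
  expect_equal(cls$values[2, 2], 1)  # boundary 0.1 -> moderate
  expect_equal(cls$values[1, 3], 1)  # boundary 0.5 -> moderate
  expect_true(is.na(cls$values[2, 3]))
  expect_error(classify_habitat(p, t_low = 0.5, t_high = 0.1))
})

test_that("class fractions and zonal rows sum to 100 and conserve counts", {
  cls <- env_grid(matrix(c(2, 2, 1, 0), 2, 2), 0, 2, 1)
  fr <- class_fractions(cls)
  expect_equal(unlist(fr), c(high_pct = 50, moderate_pct = 25,
                             unsuitable_pct = 25))
  all_high <- class_fractions(env_grid(matrix(2, 3, 3)))
  expect_equal(all_high$high_pct, 100)

  # single zone equals global fractions
  z1 <- env_grid(matrix(1, 2, 2), 0, 2, 1)
  zo <- zonal_overlap(cls, z1)
  expect_equal(zo$high_pct, fr$high_pct)

  set.seed(63)
  for (i in 1:20) {
    cvals <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
    zvals <- matrix(sample(1:4, 64, replace = TRUE), 8, 8)
    cg <- env_grid(cvals, 0, 8, 1); zg <- env_grid(zvals, 0, 8, 1)
    t1 <- zonal_overlap(cg, zg)
    expect_equal(t1$high_pct + t1$moderate_pct + t1$unsuitable_pct,
                 rep(100, nrow(t1)), tolerance = 1e-9)
    # conservation: per-zone counts add up to global class counts
    for (code in 0:2) {
      zone_counts <- vapply(t1$zone, function(z)
        sum(zvals == z & cvals == code), numeric(1))
      expect_equal(sum(zone_counts), sum(cvals == code))
    }
    fr1 <- class_fractions(cg)
    expect_equal(fr1$high_pct + fr1$moderate_pct + fr1$unsuitable_pct, 100,
                 tolerance = 1e-9)
  }

  expect_error(class_fractions(env_grid(matrix(NA_real_, 2, 2))),
               "no valid cells")
})

test_that("MESS matches the brute-force oracle on random stacks", {
  set.seed(64)
  for (i in 1:50) {
    nv <- sample(2:4, 1)
    st <- make_env_stack(15, 15, paste0("v", seq_len(nv)), smoothness = 0,
                         seed = i)
    # widen some cells beyond the reference range to hit the f=0 and f=100
    # extrapolation branches
    st$layers$v1$values[1:3, 1] <- c(-10, 10, 0)
    ref <- as.data.frame(lapply(st$layers, function(l)
      sample(as.vector(l$values), 30)))
    m <- mess(ref, st)
    expect_equal(m$values, brute_mess(ref, st), tolerance = 1e-12)
  }
})

test_that("MESS hits its closed-form landmarks", {
  ref <- data.frame(v = 1:100)  # median 50.5, min 1, max 100
  st <- grid_stack(list(v = env_grid(matrix(c(50.5, 1, 0.5, 100, 120, 75),
                                            2, 3), 0, 2, 1)))
  m <- mess(ref, st)
  expect_equal(m$values[1, 1], 100)           # at the median: 2 * 50
  expect_equal(m$values[2, 1], 0)             # at the minimum: f = 0, p = min
  expect_lt(m$values[1, 2], 0)                # below the minimum
  expect_lt(m$values[1, 3], 0)                # above the maximum
  expect_equal(m$values[2, 2], 2)  # at the maximum: f = 99 (strict), 2(100-99)
  # reference cells themselves are never negative
  self_stack <- grid_stack(list(v = env_grid(matrix(ref$v, 10, 10))))
  ms <- mess(ref, self_stack)
  expect_true(all(ms$values >= 0))
  expect_true(all(ms$values <= 100))
  expect_error(mess(data.frame(v = c(2, 2)), st), "zero range")
})

test_that("MESS integration averages cellwise and signs at zero", {
  a <- env_grid(matrix(10, 2, 2)); b <- env_grid(matrix(-10, 2, 2))
  one <- integrate_mess(list(a))
  expect_equal(one$mean$values, a$values)
  both <- integrate_mess(list(a, b))
  expect_equal(both$mean$values, matrix(0, 2, 2))
  expect_equal(both$negative$values, matrix(0, 2, 2))  # mean 0: non-negative
  neg <- integrate_mess(list(b, b))
  expect_equal(neg$negative$values, matrix(1, 2, 2))
  expect_error(integrate_mess(list(a, env_grid(matrix(1, 3, 3)))),
               "geometry")
})

test_that("suitable-vs-negative overlap counts the right cells", {
  cls <- env_grid(matrix(c(2, 1, 1, 2, 0, 0), 2, 3), 0, 2, 1)
  all_pos <- env_grid(matrix(0, 2, 3), 0, 2, 1)
  expect_equal(suitable_negative_overlap(cls, all_pos), 0)
  all_neg <- env_grid(matrix(1, 2, 3), 0, 2, 1)
  expect_equal(suitable_negative_overlap(cls, all_neg), 100)
  one_neg <- env_grid(matrix(c(1, 0, 0, 0, 0, 0), 2, 3), 0, 2, 1)
  expect_equal(suitable_negative_overlap(cls, one_neg), 25)
  no_suit <- env_grid(matrix(0, 2, 3), 0, 2, 1)
  expect_warning(res <- suitable_negative_overlap(no_suit, all_neg),
                 "undefined")
  expect_true(is.na(res))
})

test_that("scenario summaries carry coherent fractions and MESS overlap", {
  f <- make_fitted(seed = 65, n_runs = 2)
  fut <- make_future_stack(f$w$stack, c(env1 = 0.5, env2 = -0.5))
  s <- scenario_summary(f$ens, fut, label = "test")
  expect_equal(s$fractions$high_pct + s$fractions$moderate_pct +
                 s$fractions$unsuitable_pct, 100, tolerance = 1e-9)
  expect_true(is.na(s$negative_overlap_pct) ||
                (s$negative_overlap_pct >= 0 && s$negative_overlap_pct <= 100))
  expect_true(all(s$mess_mean$values <= 100, na.rm = TRUE))
})

test_that("favourable scenario ladders never shrink the high-suitability class", {
  # linear features: the fitted surface is monotone in the shifted layers,
  # like the truth it recovers
  w <- tiny_world(seed = 66, nrows = 25, ncols = 25, n_presences = 150)
  ens <- run_ensemble(w$occ, w$stack,
                      config = ensemble_config(n_runs = 4, n_background = 625,
                                               feature_kinds = "linear"),
                      seed = 67)
  steps <- seq(0, 2, by = 0.5)
  highs <- vapply(steps, function(dlt) {
    fut <- make_future_stack(w$stack, c(env1 = dlt, env2 = -dlt))
    class_fractions(classify_habitat(project_ensemble(ens, fut)))$high_pct
  }, numeric(1))
  expect_true(all(diff(highs) >= -1e-9))
  # and the underlying truth moves the same way
  mean_true <- vapply(steps, function(dlt) {
    fut <- make_future_stack(w$stack, c(env1 = dlt, env2 = -dlt))
    mean(true_suitability(fut, -2, c(env1 = 2.5, env2 = -2))$values)
  }, numeric(1))
  expect_true(all(diff(mean_true) >= 0))
})
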