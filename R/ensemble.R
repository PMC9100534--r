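#' Split retained presences into training and test sets
#'
#' @param occ Occurrence tibble.
#' @param train_fraction Fraction used for training (default 0.75).
#' @param seed Integer seed.
#' @return A list with character vectors `train` and `test` of record ids
#'   (disjoint and exhaustive over retained records).
#' @export
split_presences <- function(occ, train_fraction = 0.75, seed = 1L) {
  validate_occ(occ)
  ids <- sort(occ$record_id[occ$retained])
  n <- length(ids)
  if (n < 4L) stop("need at least 4 retained presences to split",
                   call. = FALSE)
  n_train <- round(train_fraction * n)
  withr::local_seed(seed)
  train <- sort(ids[sample.int(n, n_train)])
  list(train = train, test = setdiff(ids, train))
}

#' Presence-background ROC AUC (Mann-Whitney concordance)
#'
#' `P(presence score > background score) + 0.5 P(tie)` over all pairs,
#' computed from average ranks.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0L || nb == 0L)
    stop("both score vectors must be non-empty", call. = FALSE)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Default ensemble configuration
#'
#' Mirrors the conventional presence-background design: 100 bootstrap
#' replicates, a 75/25 train/test statement, 10,000 background cells (or all
#' valid cells when fewer), auto feature classes (all four when >= 80
#' presences, linear+quadratic otherwise), unit regularization multiplier,
#' logistic output.
#'
#' @param n_runs Number of bootstrap replicates.
#' @param train_fraction Training fraction of the presences.
#' @param replicate_mode `"bootstrap"` (train = resample with replacement,
#'   test = out-of-bag) or `"subsample"` (plain random split).
#' @param n_background Background sample size.
#' @param feature_kinds `"auto"` or a character vector of classes.
#' @param n_hinge_knots Hinge knots per variable.
#' @param reg_multiplier L1 regularization multiplier.
#' @param max_iter,tol Optimizer settings.
#' @return A list of settings.
#' @export
ensemble_config <- function(n_runs = 100, train_fraction = 0.75,
                            replicate_mode = c("bootstrap", "subsample"),
                            n_background = 10000,
                            feature_kinds = "auto", n_hinge_knots = 10,
                            reg_multiplier = 1.0,
                            max_iter = 500, tol = 1e-5) {
  list(n_runs = n_runs, train_fraction = train_fraction,
       replicate_mode = match.arg(replicate_mode),
       n_background = n_background, feature_kinds = feature_kinds,
       n_hinge_knots = n_hinge_knots, reg_multiplier = reg_multiplier,
       max_iter = max_iter, tol = tol)
}

resolve_kinds <- function(feature_kinds, n_presences) {
  if (identical(feature_kinds, "auto")) {
    if (n_presences >= 80) c("linear", "quadratic", "product", "hinge")
    else c("linear", "quadratic")
  } else feature_kinds
}

# Background cells drawn without replacement from the stack's valid cells,
# with presence cells appended (presence-background convention).
draw_background <- function(stack, occ, n_background, seed) {
  mask <- stack_valid_mask(stack)
  g <- stack$layers[[1]]
  valid <- which(mask)
  n <- min(n_background, length(valid))
  withr::local_seed(seed)
  pick <- valid[sample.int(length(valid), n)]
  act <- retained_occ(occ)
  pidx <- cell_of(g, act$lon, act$lat)
  plin <- pidx$row + (pidx$col - 1L) * grid_nrow(g)
  cells <- unique(c(pick, plin[mask[plin]]))
  vals <- as.data.frame(lapply(stack$layers, function(l) l$values[cells]))
  list(cells = cells, values = vals)
}

#' Fit a bootstrap ensemble of maxent models
#'
#' One background sample is drawn for the whole ensemble; each replicate
#' resamples the training presences (with replacement at
#' `train_fraction * n`; out-of-bag records form the test set) or splits
#' them (`replicate_mode = "subsample"`), fits the L1-regularized model,
#' projects it onto the stack, and scores test presences against the
#' background by AUC. The integrated probability grid is the cellwise mean
#' of the replicate grids; non-converged replicates are excluded from
#' integration and flagged.
#'
#' @param occ Occurrence tibble (retained records are used).
#' @param stack A [grid_stack()] restricted to the selected variables (or
#'   pass `variables`).
#' @param config See [ensemble_config()].
#' @param seed Master seed for the ensemble.
#' @param variables Optional subset of layer names to model on.
#' @return An object of class `cnm_ensemble`: `runs` (tibble), `models`
#'   (list), `integrated` ([env_grid()]), `auc_mean`, `auc_se`,
#'   `background` (cells and values), `expansion`, `occ`.
#' @export
run_ensemble <- function(occ, stack, config = ensemble_config(), seed = 1L,
                         variables = NULL) {
  validate_occ(occ)
  stopifnot(inherits(stack, "grid_stack"))
  if (!is.null(variables)) {
    missing_layers <- setdiff(variables, names(stack$layers))
    if (length(missing_layers))
      stop(sprintf("stack lacks layer(s): %s",
                   paste(missing_layers, collapse = ", ")), call. = FALSE)
    stack <- grid_stack(stack$layers[variables])
  }
  act <- retained_occ(occ)
  n_pres <- nrow(act)
  if (n_pres < 4L) stop("need at least 4 retained presences", call. = FALSE)

  bg <- draw_background(stack, occ, config$n_background,
                        seed = derive_seed(seed, "background"))
  kinds <- resolve_kinds(config$feature_kinds, n_pres)
  expansion <- build_features(bg$values, kinds = kinds,
                              n_hinge_knots = config$n_hinge_knots)
  B <- feature_matrix(expansion, bg$values)

  pres_vals <- extract_values(stack, act)
  keep <- !pres_vals$missing
  act <- act[keep, , drop = FALSE]
  pres_vals <- pres_vals[keep, , drop = FALSE]
  P_all <- feature_matrix(expansion, pres_vals)
  rownames(P_all) <- act$record_id

  g <- stack$layers[[1]]
  mask <- stack_valid_mask(stack)
  cell_idx <- which(mask)
  grid_vals <- as.data.frame(lapply(stack$layers,
                                    function(l) l$values[cell_idx]))
  G <- feature_matrix(expansion, grid_vals)

  n_train <- round(config$train_fraction * nrow(act))
  runs <- vector("list", config$n_runs)
  models <- vector("list", config$n_runs)
  grid_sum <- numeric(length(cell_idx))
  n_ok <- 0L
  for (r in seq_len(config$n_runs)) {
    run_seed <- derive_seed(seed, "run", r)
    withr::local_seed(run_seed)
    if (config$replicate_mode == "bootstrap") {
      tr <- sample.int(nrow(act), n_train, replace = TRUE)
      te <- setdiff(seq_len(nrow(act)), unique(tr))
    } else {
      tr <- sample.int(nrow(act), n_train)
      te <- setdiff(seq_len(nrow(act)), tr)
    }
    P_tr <- P_all[tr, , drop = FALSE]
    betas <- default_betas(expansion, P_tr, config$reg_multiplier)
    model <- fit_maxent(P_tr, B, betas = betas, expansion = expansion,
                        max_iter = config$max_iter, tol = config$tol)
    eta_g <- to_logistic(model, exp(as.numeric(G %*% model$lambda) -
                                      model$log_z))
    test_auc <- if (length(te) > 0) {
      raw_te <- predict_raw(model, P_all[te, , drop = FALSE])
      raw_bg <- predict_raw(model, B)
      auc(raw_te, raw_bg)
    } else NA_real_
    if (model$converged) {
      grid_sum <- grid_sum + eta_g
      n_ok <- n_ok + 1L
    }
    models[[r]] <- model
    runs[[r]] <- tibble::tibble(
      run = r, seed = run_seed,
      n_train = length(tr), n_test = length(te),
      train_ids = list(act$record_id[sort(unique(tr))]),
      test_ids = list(act$record_id[te]),
      auc = test_auc, converged = model$converged,
      kkt_violation = model$kkt_violation, gain = training_gain(model, P_tr))
  }
  runs <- dplyr::bind_rows(runs)
  if (n_ok == 0L) stop("no ensemble run converged", call. = FALSE)
  if (any(!runs$converged))
    warning(sprintf("%d run(s) did not converge and were excluded from %s",
                    sum(!runs$converged), "integration"), call. = FALSE)
  integrated_vals <- matrix(NA_real_, grid_nrow(g), grid_ncol(g))
  integrated_vals[cell_idx] <- grid_sum / n_ok
  aucs <- runs$auc[runs$converged & !is.na(runs$auc)]
  structure(
    list(runs = runs, models = models,
         integrated = env_grid(integrated_vals, g$origin_lon, g$origin_lat,
                               g$cellsize),
         auc_mean = mean(aucs),
         auc_se = stats::sd(aucs) / sqrt(length(aucs)),
         background = bg, expansion = expansion, occ = act,
         presence_values = pres_vals,
         variables = names(stack$layers), seed = seed, config = config),
    class = "cnm_ensemble")
}

#' @export
print.cnm_ensemble <- function(x, ...) {
  cat(sprintf(
    "<cnm_ensemble> %d run(s) (%d converged), mean test AUC %.3f (SE %.3g)\n",
    nrow(x$runs), sum(x$runs$converged), x$auc_mean, x$auc_se))
  invisible(x)
}

#' @export
#' @method tidy cnm_ensemble
tidy.cnm_ensemble <- function(x, ...) {
  x$runs[c("run", "seed", "n_train", "n_test", "auc", "converged",
           "kkt_violation", "gain")]
}

#' @export
#' @method glance cnm_ensemble
glance.cnm_ensemble <- function(x, ...) {
  tibble::tibble(
    n_runs = nrow(x$runs),
    n_converged = sum(x$runs$converged),
    auc_mean = x$auc_mean,
    auc_se = x$auc_se,
    n_presences = nrow(x$occ),
    n_background = nrow(x$background$values))
}

#' Permutation-based variable contribution
#'
#' For each variable, its values are permuted across the pooled evaluation
#' points (presences and background together, which breaks the
#' presence/background association), features are rebuilt, and the drop in
#' presence-background AUC relative to the intact model is averaged over
#' `n_perm` permutations. Drops are floored at zero and normalized to
#' percentages summing to 100.
#'
#' @param model A [fit_maxent()] model (with stored expansion).
#' @param presence_values,background_values Value tables (points x
#'   variables) on the model's variables.
#' @param n_perm Permutations per variable.
#' @param seed Integer seed.
#' @return A tibble with `variable`, `auc_drop`, `contribution_pct`.
#' @export
permutation_contribution <- function(model, presence_values,
                                     background_values, n_perm = 10,
                                     seed = 1L) {
  exp_ <- model$expansion
  if (is.null(exp_)) stop("model carries no feature expansion", call. = FALSE)
  pv <- as.data.frame(presence_values)[exp_$variables]
  bv <- as.data.frame(background_values)[exp_$variables]
  base_auc <- auc(predict_raw(model, feature_matrix(exp_, pv)),
                  predict_raw(model, feature_matrix(exp_, bv)))
  np <- nrow(pv)
  withr::local_seed(seed)
  drops <- vapply(exp_$variables, function(v) {
    mean(vapply(seq_len(n_perm), function(k) {
      pooled <- sample(c(pv[[v]], bv[[v]]))
      pv2 <- pv; bv2 <- bv
      pv2[[v]] <- pooled[seq_len(np)]
      bv2[[v]] <- pooled[-seq_len(np)]
      base_auc - auc(predict_raw(model, feature_matrix(exp_, pv2)),
                     predict_raw(model, feature_matrix(exp_, bv2)))
    }, numeric(1)))
  }, numeric(1))
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) {
    warning("all permutation drops are zero; reporting uniform shares",
            call. = FALSE)
    shares <- rep(100 / length(drops), length(drops))
  } else {
    shares <- 100 * drops / sum(drops)
  }
  tibble::tibble(variable = exp_$variables, auc_drop = unname(drops),
                 contribution_pct = unname(shares))
}

#' Jackknife analysis of per-variable training gain
#'
#' Fits, on one training set, the full model plus a with-only and a without
#' model per variable, and reports their training gains — the conventional
#' jackknife display of variable importance.
#'
#' @param occ Occurrence tibble.
#' @param stack A [grid_stack()] of the selected variables.
#' @param config See [ensemble_config()].
#' @param seed Integer seed (controls the background and the training set).
#' @return A tibble with `variable`, `gain_only`, `gain_without`, plus the
#'   full-model gain in attribute `full_gain`.
#' @export
jackknife_gains <- function(occ, stack, config = ensemble_config(),
                            seed = 1L) {
  validate_occ(occ)
  vars <- names(stack$layers)
  if (length(vars) < 2L) stop("need at least two variables", call. = FALSE)
  act <- retained_occ(occ)
  bg <- draw_background(stack, occ, config$n_background,
                        seed = derive_seed(seed, "background"))
  pres_vals <- extract_values(stack, act)
  pres_vals <- pres_vals[!pres_vals$missing, , drop = FALSE]
  kinds <- resolve_kinds(config$feature_kinds, nrow(pres_vals))
  fit_subset <- function(v) {
    expn <- build_features(bg$values[v], kinds = setdiff(kinds, "product"),
                           n_hinge_knots = config$n_hinge_knots)
    fit_gain(expn, pres_vals, bg$values, config)
  }
  fit_gain <- function(expn, pv, bv, config) {
    P <- feature_matrix(expn, pv)
    B <- feature_matrix(expn, bv)
    betas <- default_betas(expn, P, config$reg_multiplier)
    m <- fit_maxent(P, B, betas = betas, expansion = expn,
                    max_iter = config$max_iter, tol = config$tol)
    list(model = m, gain = training_gain(m, P))
  }
  full_expn <- build_features(bg$values[vars], kinds = kinds,
                              n_hinge_knots = config$n_hinge_knots)
  full <- fit_gain(full_expn, pres_vals, bg$values, config)
  only <- vapply(vars, function(v) fit_subset(v)$gain, numeric(1))
  without <- vapply(vars, function(v) {
    keep <- setdiff(vars, v)
    expn <- build_features(bg$values[keep], kinds = kinds,
                           n_hinge_knots = config$n_hinge_knots)
    fit_gain(expn, pres_vals, bg$values, config)$gain
  }, numeric(1))
  out <- tibble::tibble(variable = vars, gain_only = unname(only),
                        gain_without = unname(without))
  attr(out, "full_gain") <- full$gain
  out
}
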