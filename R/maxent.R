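#' Build a maxent feature expansion from a training value table
#'
#' Variables are affinely scaled to `[0, 1]` using their training min/max.
#' Feature classes follow the presence-background maximum-entropy
#' convention:
#' * `linear` — the scaled variable;
#' * `quadratic` — its square;
#' * `product` — pairwise products of scaled variables;
#' * `hinge` — `max(0, (x - k) / (max - k))` at `n_hinge_knots` equally
#'   spaced knots `k` over the training range.
#'
#' All features lie in `[0, 1]` on the training data. Constant variables are
#' dropped with a warning; degenerate hinges (knot at the variable maximum)
#' are dropped silently.
#'
#' @param values Data frame of numeric training variables (bookkeeping
#'   columns `lon`, `lat`, `missing`, `record_id` are ignored).
#' @param kinds Feature classes to build.
#' @param n_hinge_knots Number of hinge knots per variable.
#' @return An object of class `feature_expansion`.
#' @export
build_features <- function(values,
                           kinds = c("linear", "quadratic", "product", "hinge"),
                           n_hinge_knots = 10) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  df <- as.data.frame(values)
  df <- df[setdiff(names(df), c("lon", "lat", "missing", "record_id"))]
  df <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(df) < 1L) stop("need at least one numeric variable", call. = FALSE)
  rng <- lapply(df, range, na.rm = TRUE)
  constant <- vapply(rng, function(r) r[1] == r[2], logical(1))
  if (any(constant)) {
    warning(sprintf("dropping constant variable(s): %s",
                    paste(names(df)[constant], collapse = ", ")),
            call. = FALSE)
    df <- df[!constant]
    rng <- rng[!constant]
  }
  if (ncol(df) < 1L) stop("all variables are constant", call. = FALSE)
  vars <- names(df)
  feats <- list()
  add <- function(name, kind, v1, v2 = NA_character_, knot = NA_real_)
    feats[[length(feats) + 1L]] <<- list(name = name, kind = kind,
                                         var1 = v1, var2 = v2, knot = knot)
  if ("linear" %in% kinds)
    for (v in vars) add(v, "linear", v)
  if ("quadratic" %in% kinds)
    for (v in vars) add(paste0(v, "^2"), "quadratic", v)
  if ("product" %in% kinds && length(vars) >= 2L) {
    cmb <- utils::combn(vars, 2L)
    for (j in seq_len(ncol(cmb)))
      add(paste0(cmb[1, j], "*", cmb[2, j]), "product", cmb[1, j], cmb[2, j])
  }
  if ("hinge" %in% kinds) {
    for (v in vars) {
      r <- rng[[v]]
      knots <- seq(r[1], r[2], length.out = n_hinge_knots + 1L)
      knots <- knots[-length(knots)]  # knot at max is identically zero
      for (k in knots)
        add(sprintf("hinge(%s,%.6g)", v, k), "hinge", v, knot = k)
    }
  }
  structure(
    list(variables = vars,
         mins = vapply(rng, `[`, numeric(1), 1L),
         maxs = vapply(rng, `[`, numeric(1), 2L),
         features = feats),
    class = "feature_expansion")
}

#' @export
print.feature_expansion <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, character(1), "kind")
  cat(sprintf("<feature_expansion> %d variable(s), %d feature(s): %s\n",
              length(x$variables), length(x$features),
              paste(sprintf("%s=%d", names(table(kinds)), table(kinds)),
                    collapse = ", ")))
  invisible(x)
}

#' Evaluate a feature expansion on new data
#'
#' @param expansion A [build_features()] object.
#' @param values Data frame containing the expansion's variables.
#' @return Numeric matrix, one column per feature (training-scaled).
#' @export
feature_matrix <- function(expansion, values) {
  df <- as.data.frame(values)
  missing_vars <- setdiff(expansion$variables, names(df))
  if (length(missing_vars))
    stop(sprintf("value table lacks variable(s): %s",
                 paste(missing_vars, collapse = ", ")), call. = FALSE)
  scaled <- lapply(expansion$variables, function(v) {
    mn <- expansion$mins[[v]]; mx <- expansion$maxs[[v]]
    (df[[v]] - mn) / (mx - mn)
  })
  names(scaled) <- expansion$variables
  n <- nrow(df)
  out <- matrix(0, n, length(expansion$features))
  colnames(out) <- vapply(expansion$features, `[[`, character(1), "name")
  for (j in seq_along(expansion$features)) {
    f <- expansion$features[[j]]
    out[, j] <- switch(f$kind,
      linear = scaled[[f$var1]],
      quadratic = scaled[[f$var1]]^2,
      product = scaled[[f$var1]] * scaled[[f$var2]],
      hinge = {
        mn <- expansion$mins[[f$var1]]; mx <- expansion$maxs[[f$var1]]
        x <- df[[f$var1]]
        pmax(0, (x - f$knot) / (mx - f$knot))
      })
  }
  out
}

#' Default L1 penalty per feature
#'
#' `beta_j = reg_multiplier * c(class) * s_j / sqrt(m)` with `m` the presence
#' count, `s_j` the presence standard deviation of feature `j`, and class
#' constants 1.0 (linear/quadratic/product) and 0.5 (hinge) — a simplified
#' form of the published maxent defaults.
#'
#' @param expansion A [build_features()] object.
#' @param presence_features Presence feature matrix.
#' @param reg_multiplier Global regularization multiplier.
#' @return Numeric vector of penalties, one per feature.
#' @export
default_betas <- function(expansion, presence_features, reg_multiplier = 1.0) {
  m <- nrow(presence_features)
  kinds <- vapply(expansion$features, `[[`, character(1), "kind")
  cls <- ifelse(kinds == "hinge", 0.5, 1.0)
  s <- apply(presence_features, 2L, stats::sd)
  s[!is.finite(s)] <- 0
  reg_multiplier * cls * s / sqrt(m)
}

#' Fit an L1-regularized maximum-entropy presence-background model
#'
#' Estimates the Gibbs distribution
#' `q(x) = exp(sum_j lambda_j f_j(x)) / Z` over the background sample by
#' minimizing the regularized negative mean presence log-likelihood
#' `log Z - mean_presence(sum_j lambda_j f_j) + sum_j beta_j |lambda_j|`
#' with FISTA proximal-gradient descent (soft-thresholding for the L1 term,
#' backtracking line search, monotone restarts). Convergence is declared
#' when the maximum KKT violation falls below `tol`:
#' `|mean_presence f_j - E_q f_j| <= beta_j` for every feature, with the
#' signed equality active wherever `lambda_j != 0`.
#'
#' @param presence_features,background_features Feature matrices built with
#'   the same [build_features()] expansion.
#' @param betas Per-feature L1 penalties (see [default_betas()]); scalar
#'   values are recycled.
#' @param expansion Optional [build_features()] object stored with the model
#'   (required for grid prediction and response curves).
#' @param max_iter Iteration cap.
#' @param tol KKT tolerance.
#' @return An object of class `maxent_model`: weights `lambda`, penalties
#'   `beta`, `log_z`, background entropy `H`, convergence diagnostics.
#' @export
fit_maxent <- function(presence_features, background_features,
                       betas = 0, expansion = NULL,
                       max_iter = 500, tol = 1e-5) {
  P <- as.matrix(presence_features)
  B <- as.matrix(background_features)
  if (nrow(P) < 1L) stop("need at least one presence row", call. = FALSE)
  if (nrow(B) < 2L) stop("need at least two background rows", call. = FALSE)
  d <- ncol(B)
  if (ncol(P) != d) stop("feature matrices disagree in width", call. = FALSE)
  beta <- rep_len(as.numeric(betas), d)
  if (any(beta < 0)) stop("penalties must be non-negative", call. = FALSE)
  n_bg <- nrow(B)
  pbar <- if (d > 0) colMeans(P) else numeric(0)

  if (d == 0L) {
    # no constraints: the maximum-entropy solution is uniform
    return(new_maxent_model(numeric(0), beta, log(n_bg), log(n_bg),
                            expansion, 0, TRUE, 0L, n_bg,
                            colnames(B)))
  }

  lse <- function(eta) { mx <- max(eta); mx + log(sum(exp(eta - mx))) }
  smooth_val <- function(lam, eta) lse(eta) - sum(pbar * lam)
  grad_fun <- function(eta) {
    q <- exp(eta - lse(eta))
    as.numeric(crossprod(B, q)) - pbar
  }
  kkt_violation <- function(lam, grad) {
    v <- ifelse(lam == 0, pmax(abs(grad) - beta, 0),
                abs(grad + sign(lam) * beta))
    max(v)
  }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  objective <- function(lam, eta) smooth_val(lam, eta) + sum(beta * abs(lam))

  # Orthant-wise Newton refinement on the active set: fixes the signs of the
  # active weights (zero weights with a violated optimality condition enter
  # with the descending sign), takes a damped Newton step on the smooth part
  # plus the signed penalty, and projects sign flips back to zero. Accepted
  # only when the full objective decreases.
  polish <- function(lam, eta) {
    for (inner in seq_len(20L)) {
      grad <- grad_fun(eta)
      viol <- ifelse(lam == 0, pmax(abs(grad) - beta, 0),
                     abs(grad + sign(lam) * beta))
      if (max(viol) <= tol) break
      active <- which(lam != 0 | viol > tol)
      if (length(active) == 0L || length(active) > 200L) break
      s <- sign(lam[active])
      s[s == 0] <- -sign(grad[active][s == 0])
      q <- exp(eta - lse(eta))
      BA <- B[, active, drop = FALSE]
      mu <- as.numeric(crossprod(BA, q))
      Hm <- crossprod(BA * sqrt(q)) - tcrossprod(mu)
      diag(Hm) <- diag(Hm) + 1e-10
      gsub <- grad[active] + beta[active] * s
      dir <- tryCatch(-solve(Hm, gsub), error = function(e) NULL)
      if (is.null(dir)) break
      f0 <- objective(lam, eta)
      step <- 1
      improved <- FALSE
      for (ls in seq_len(30L)) {
        cand <- lam
        new_a <- lam[active] + step * dir
        new_a[new_a * s < 0] <- 0  # orthant projection
        cand[active] <- new_a
        eta_c <- as.numeric(B %*% cand)
        if (objective(cand, eta_c) < f0 - 1e-14) {
          lam <- cand; eta <- eta_c; improved <- TRUE; break
        }
        step <- step / 2
      }
      if (!improved) break
    }
    list(lam = lam, eta = eta)
  }

  fista_chunk <- function(state, n_steps) {
    lam <- state$lam; y <- state$y; eta_y <- state$eta_y
    t_mom <- state$t_mom; L <- state$L; obj_old <- state$obj
    for (it in seq_len(n_steps)) {
      g_y <- smooth_val(y, eta_y)
      grad <- grad_fun(eta_y)
      repeat {
        lam_new <- soft(y - grad / L, beta / L)
        eta_new <- as.numeric(B %*% lam_new)
        dlt <- lam_new - y
        if (smooth_val(lam_new, eta_new) <=
            g_y + sum(grad * dlt) + (L / 2) * sum(dlt^2) + 1e-12) break
        L <- L * 2
      }
      obj_new <- objective(lam_new, eta_new)
      if (obj_new > obj_old) {
        # monotone restart: plain proximal step from the last iterate
        y <- lam
        eta_y <- as.numeric(B %*% y)
        t_mom <- 1
        grad <- grad_fun(eta_y)
        g_y <- smooth_val(y, eta_y)
        repeat {
          lam_new <- soft(y - grad / L, beta / L)
          eta_new <- as.numeric(B %*% lam_new)
          dlt <- lam_new - y
          if (smooth_val(lam_new, eta_new) <=
              g_y + sum(grad * dlt) + (L / 2) * sum(dlt^2) + 1e-12) break
          L <- L * 2
        }
        obj_new <- objective(lam_new, eta_new)
      }
      t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
      y <- lam_new + ((t_mom - 1) / t_new) * (lam_new - lam)
      eta_y <- as.numeric(B %*% y)
      lam <- lam_new
      t_mom <- t_new
      obj_old <- obj_new
      L <- max(L / 2, 1e-6)  # let the step length grow back
    }
    list(lam = lam, y = y, eta_y = eta_y, t_mom = t_mom, L = L,
         obj = obj_old)
  }

  lam <- numeric(d)
  state <- list(lam = lam, y = lam, eta_y = as.numeric(B %*% lam),
                t_mom = 1, L = 1,
                obj = objective(lam, as.numeric(B %*% lam)))
  converged <- FALSE
  iters <- 0L
  chunk <- 25L
  while (iters < max_iter) {
    n_steps <- min(chunk, max_iter - iters)
    state <- fista_chunk(state, n_steps)
    iters <- iters + n_steps
    lam <- state$lam
    eta_b <- as.numeric(B %*% lam)
    pol <- polish(lam, eta_b)
    if (!identical(pol$lam, lam)) {
      lam <- pol$lam
      eta_b <- pol$eta
      state$lam <- lam
      state$y <- lam
      state$eta_y <- eta_b
      state$t_mom <- 1
      state$obj <- objective(lam, eta_b)
    }
    if (kkt_violation(lam, grad_fun(eta_b)) <= tol) {
      converged <- TRUE
      break
    }
  }
  eta_b <- as.numeric(B %*% lam)
  log_z <- lse(eta_b)
  q <- exp(eta_b - log_z)
  H <- -sum(q * log(pmax(q, .Machine$double.xmin)))
  kkt <- kkt_violation(lam, grad_fun(eta_b))
  new_maxent_model(lam, beta, log_z, H, expansion, kkt, converged, iters,
                   n_bg, colnames(B))
}

new_maxent_model <- function(lambda, beta, log_z, H, expansion, kkt,
                             converged, iters, n_background, feature_names) {
  structure(
    list(lambda = as.numeric(lambda), beta = as.numeric(beta),
         log_z = log_z, entropy = H, expansion = expansion,
         kkt_violation = kkt, converged = converged, iterations = iters,
         n_background = n_background,
         feature_names = feature_names %||% character(length(lambda))),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d feature(s), %d non-zero weight(s), N = %d background\n",
    length(x$lambda), sum(x$lambda != 0), x$n_background))
  cat(sprintf("  entropy H = %.4f, log Z = %.4f, KKT violation = %.3g (%s)\n",
              x$entropy, x$log_z, x$kkt_violation,
              if (x$converged) sprintf("converged in %d iter", x$iterations)
              else "NOT converged"))
  invisible(x)
}

#' Raw Gibbs weights for a feature matrix
#'
#' `raw(x) = exp(sum_j lambda_j f_j(x) - log Z)`; over the training
#' background these sum to one.
#'
#' @param model A [fit_maxent()] model.
#' @param features Feature matrix built with the model's expansion.
#' @return Numeric vector of positive raw weights.
#' @export
predict_raw <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(model$lambda))
    stop("feature matrix width does not match the model's expansion",
         call. = FALSE)
  if (length(model$lambda) == 0L)  # unconstrained: exactly uniform
    return(rep(1 / model$n_background, nrow(features)))
  exp(as.numeric(features %*% model$lambda) - model$log_z)
}

#' Logistic occurrence probability from raw weights
#'
#' The maxent logistic transform with default prevalence 0.5:
#' `p = e^H * raw / (1 + e^H * raw)` with `H` the entropy of the background
#' Gibbs distribution. Strictly increasing in `raw`; the uniform model maps
#' to 0.5 everywhere.
#'
#' @param model A [fit_maxent()] model.
#' @param raw Raw weights from [predict_raw()].
#' @return Probabilities in `(0, 1)`.
#' @export
to_logistic <- function(model, raw) {
  if (length(model$lambda) == 0L)  # uniform model: e^H raw = 1 exactly
    return(rep(0.5, length(raw)))
  x <- exp(model$entropy) * raw
  x / (1 + x)
}

#' Logistic prediction for a value table
#' @param model A [fit_maxent()] model (with stored expansion).
#' @param values Data frame of variables.
#' @return Probabilities in `(0, 1)`.
#' @export
predict_maxent <- function(model, values) {
  if (is.null(model$expansion))
    stop("model carries no feature expansion; pass features to predict_raw",
         call. = FALSE)
  to_logistic(model, predict_raw(model, feature_matrix(model$expansion,
                                                       values)))
}

#' Project a fitted model onto a grid stack
#'
#' @param model A [fit_maxent()] model (with stored expansion).
#' @param stack A [grid_stack()] carrying the model's variables.
#' @return An [env_grid()] of logistic probabilities (no-data propagated).
#' @export
predict_grid <- function(model, stack) {
  stopifnot(inherits(stack, "grid_stack"))
  g <- stack$layers[[1]]
  mask <- stack_valid_mask(stack)
  idx <- which(mask)
  vals <- as.data.frame(lapply(stack$layers, function(l) l$values[idx]))
  p <- predict_maxent(model, vals)
  out <- matrix(NA_real_, grid_nrow(g), grid_ncol(g))
  out[idx] <- p
  env_grid(out, g$origin_lon, g$origin_lat, g$cellsize)
}

#' Regularized training gain of a fitted model
#'
#' `gain = mean_presence log(N * raw) - sum_j beta_j |lambda_j|`; zero for
#' the uniform (intercept-only) model, non-negative for any unregularized
#' maximum-likelihood fit.
#'
#' @param model A [fit_maxent()] model.
#' @param presence_features Presence feature matrix.
#' @return Numeric scalar.
#' @export
training_gain <- function(model, presence_features) {
  raw <- predict_raw(model, presence_features)
  mean(log(model$n_background * raw)) - sum(model$beta * abs(model$lambda))
}

#' Response curve of one variable
#'
#' Sweeps the variable over its training range while all other variables are
#' held at the supplied background means, and records the logistic
#' prediction.
#'
#' @param model A [fit_maxent()] model (with stored expansion).
#' @param variable Variable name.
#' @param background_means Named vector of means for the remaining variables
#'   (training-scale units).
#' @param n_points Sweep resolution.
#' @return A tibble with columns `variable`, `value`, `probability`.
#' @export
response_curve <- function(model, variable, background_means, n_points = 100) {
  exp_ <- model$expansion
  if (is.null(exp_)) stop("model carries no feature expansion", call. = FALSE)
  if (!variable %in% exp_$variables)
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  sweep_vals <- seq(exp_$mins[[variable]], exp_$maxs[[variable]],
                    length.out = n_points)
  df <- as.data.frame(as.list(background_means[exp_$variables]))
  names(df) <- exp_$variables
  df <- df[rep(1L, n_points), , drop = FALSE]
  df[[variable]] <- sweep_vals
  tibble::tibble(variable = variable, value = sweep_vals,
                 probability = predict_maxent(model, df))
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
#' @method tidy maxent_model
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_names,
    kind = if (!is.null(x$expansion))
      vapply(x$expansion$features, `[[`, character(1), "kind")
      else NA_character_,
    lambda = x$lambda,
    beta = x$beta)
}

#' @export
#' @method glance maxent_model
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$lambda),
    n_active = sum(x$lambda != 0),
    entropy = x$entropy,
    log_z = x$log_z,
    kkt_violation = x$kkt_violation,
    converged = x$converged,
    iterations = x$iterations)
}

#' Serialize a fitted model to JSON
#'
#' The document carries the expansion, scalers, weights, penalties,
#' normalizer and entropy — enough to reproduce predictions at full double
#' precision.
#'
#' @param model A [fit_maxent()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maxent <- function(model, path) {
  doc <- list(
    lambda = model$lambda, beta = model$beta, log_z = model$log_z,
    entropy = model$entropy, n_background = model$n_background,
    feature_names = model$feature_names,
    converged = model$converged, iterations = model$iterations,
    kkt_violation = model$kkt_violation,
    expansion = if (!is.null(model$expansion)) list(
      variables = model$expansion$variables,
      mins = as.list(model$expansion$mins),
      maxs = as.list(model$expansion$maxs),
      features = model$expansion$features))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a serialized model back
#' @param path JSON path written by [write_maxent()].
#' @return A `maxent_model`.
#' @export
read_maxent <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  expansion <- NULL
  if (!is.null(doc$expansion)) {
    feats <- lapply(doc$expansion$features, function(f)
      list(name = f$name, kind = f$kind, var1 = f$var1,
           var2 = if (is.null(f$var2)) NA_character_ else f$var2,
           knot = if (is.null(f$knot)) NA_real_ else f$knot))
    expansion <- structure(
      list(variables = doc$expansion$variables,
           mins = unlist(doc$expansion$mins),
           maxs = unlist(doc$expansion$maxs),
           features = feats),
      class = "feature_expansion")
  }
  new_maxent_model(doc$lambda, doc$beta, doc$log_z, doc$entropy, expansion,
                   doc$kkt_violation, doc$converged, doc$iterations,
                   doc$n_background, doc$feature_names)
}
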