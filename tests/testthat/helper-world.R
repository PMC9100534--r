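# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; oracles are deliberately naive re-implementations
# kept independent of the package's vectorized code paths.

tiny_stack <- function(nrows = 20, ncols = 20, n_layers = 3, seed = 42,
                       smoothness = 3) {
  make_env_stack(nrows, ncols, paste0("env", seq_len(n_layers)),
                 smoothness = smoothness, seed = seed)
}

tiny_world <- function(seed = 42, nrows = 20, ncols = 20, n_presences = 120) {
  st <- tiny_stack(nrows, ncols, seed = seed)
  truth <- true_suitability(st, -2, c(env1 = 2.5, env2 = -2))
  occ <- sample_occurrences(truth, n_presences, seed = seed + 1)
  list(stack = st, truth = truth, occ = occ)
}

occ_table <- function(lon, lat, ids = NULL) {
  n <- length(lon)
  tibble::tibble(
    record_id = ids %||% sprintf("r%03d", seq_len(n)),
    lon = lon, lat = lat, retained = TRUE, drop_reason = "none")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All-pairs Mann-Whitney AUC, O(n^2); oracle for the rank-based version.
brute_auc <- function(pres, bg) {
  wins <- 0
  for (p in pres) for (b in bg)
    wins <- wins + (p > b) + 0.5 * (p == b)
  wins / (length(pres) * length(bg))
}

# Naive per-cell, per-variable MESS with explicit percentile loops.
brute_mess <- function(reference, stack) {
  ref <- as.data.frame(reference)
  vars <- intersect(names(stack$layers), names(ref))
  g <- stack$layers[[1]]
  nr <- nrow(g$values); nc <- ncol(g$values)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    smin <- Inf
    bad <- FALSE
    for (v in vars) {
      p <- stack$layers[[v]]$values[i, j]
      if (is.na(p)) { bad <- TRUE; break }
      rv <- ref[[v]][is.finite(ref[[v]])]
      n <- length(rv)
      f <- 100 * sum(rv < p) / n
      rmin <- min(rv); rmax <- max(rv)
      s <- if (f == 0) 100 * (p - rmin) / (rmax - rmin)
      else if (f <= 50) 2 * f
      else if (f < 100) 2 * (100 - f)
      else 100 * (rmax - p) / (rmax - rmin)
      smin <- min(smin, s)
    }
    if (!bad) out[i, j] <- smin
  }
  out
}

# 1-D Newton solution of the Gibbs moment equation for a single feature
# with no penalty: find lambda with E_q[f] = presence mean of f.
newton_single_feature <- function(f_pres, f_bg, tol = 1e-12,
                                  max_iter = 200) {
  target <- mean(f_pres)
  lam <- 0
  for (i in seq_len(max_iter)) {
    eta <- lam * f_bg
    w <- exp(eta - max(eta))
    q <- w / sum(w)
    mu <- sum(q * f_bg)
    v <- sum(q * f_bg^2) - mu^2
    step <- (target - mu) / v
    lam <- lam + step
    if (abs(step) < tol) break
  }
  lam
}

# Moment-formula OLS of y on x (extended-precision style accumulation).
moment_ols <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  sxy <- sum((x - xb) * (y - yb))
  b1 <- sxy / sxx
  b0 <- yb - b1 * xb
  res <- y - b0 - b1 * x
  s2 <- sum(res^2) / (n - 2)
  se1 <- sqrt(s2 / sxx)
  se0 <- sqrt(s2 * (1 / n + xb^2 / sxx))
  list(b0 = b0, b1 = b1, se0 = se0, se1 = se1)
}
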