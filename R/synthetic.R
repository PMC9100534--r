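#' Generate a stack of smooth correlated environmental fields
#'
#' Each layer is Gaussian white noise convolved with an isotropic Gaussian
#' kernel (standard deviation `smoothness` cells, truncated at three
#' length-scales, reflective boundaries) and then standardized to mean 0 and
#' standard deviation 1 over valid cells. With `smoothness = 0` the layers
#' are iid standardized noise. Pairwise correlation between layers can be
#' induced by mixing every layer with a shared latent field:
#' `layer <- sqrt(1 - w^2) * own + w * shared` with `w = mix_weight`
#' (so `mix_weight = 1` makes all layers identical).
#'
#' @param nrows,ncols Lattice size.
#' @param layer_names Character vector of layer names.
#' @param smoothness Kernel length-scale in cells (>= 0).
#' @param seed Integer seed.
#' @param mix_weight Mixing weight in `[0, 1]` toward a shared field.
#' @return A [grid_stack()].
#' @export
make_env_stack <- function(nrows, ncols, layer_names,
                           smoothness = 6, seed = 1L, mix_weight = 0) {
  if (length(layer_names) == 0L)
    stop("`layer_names` must name at least one layer", call. = FALSE)
  stopifnot(smoothness >= 0, mix_weight >= 0, mix_weight <= 1)
  withr::local_seed(seed)
  shared <- smooth_field(matrix(stats::rnorm(nrows * ncols), nrows, ncols),
                         smoothness)
  layers <- lapply(layer_names, function(nm) {
    own <- smooth_field(matrix(stats::rnorm(nrows * ncols), nrows, ncols),
                        smoothness)
    f <- sqrt(1 - mix_weight^2) * own + mix_weight * shared
    f <- (f - mean(f)) / stats::sd(f)
    env_grid(f)
  })
  names(layers) <- layer_names
  grid_stack(layers)
}

# Separable Gaussian blur, kernel truncated at 3 sigma, reflective edges.
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  m <- apply(m, 2L, convolve_reflect, k = k)
  t(apply(m, 1L, convolve_reflect, k = k))
}

convolve_reflect <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))
  xp <- x[pmin(pmax(idx, 1L), n)]
  stats::convolve(xp, rev(k), type = "filter")
}

#' True suitability surface of a synthetic niche
#'
#' Evaluates `plogis(intercept + sum(coef * layer))` cell by cell. This is
#' the known truth that recovery tests compare fitted probability surfaces
#' against.
#'
#' @param stack A [grid_stack()].
#' @param intercept Intercept on the logit scale.
#' @param coefficients Named numeric vector; names must be stack layers.
#' @return An [env_grid()] with values in `[0, 1]`.
#' @export
true_suitability <- function(stack, intercept = 0, coefficients) {
  stopifnot(inherits(stack, "grid_stack"))
  missing_layers <- setdiff(names(coefficients), names(stack$layers))
  if (length(missing_layers))
    stop(sprintf("coefficient(s) name unknown layer(s): %s",
                 paste(missing_layers, collapse = ", ")), call. = FALSE)
  g <- stack$layers[[1]]
  eta <- matrix(intercept, grid_nrow(g), grid_ncol(g))
  for (nm in names(coefficients))
    eta <- eta + coefficients[[nm]] * stack$layers[[nm]]$values
  env_grid(stats::plogis(eta), g$origin_lon, g$origin_lat, g$cellsize)
}

#' Sample presence records proportional to suitability
#'
#' Draws `n` cells with probability proportional to the suitability surface
#' (with replacement across cells) and jitters each point uniformly within
#' its cell — the point-process sampling model that presence-background
#' maximum entropy assumes.
#'
#' @param truth An [env_grid()] of suitability values in `[0, 1]`.
#' @param n Number of presence points.
#' @param seed Integer seed.
#' @return An occurrence tibble (`record_id`, `lon`, `lat`, `retained`,
#'   `drop_reason`).
#' @export
sample_occurrences <- function(truth, n, seed = 1L) {
  stopifnot(inherits(truth, "env_grid"))
  w <- truth$values
  valid <- which(!is.na(w) & w > 0)
  if (length(valid) == 0L)
    stop("suitability surface has no valid cell with positive value",
         call. = FALSE)
  withr::local_seed(seed)
  pick <- valid[sample.int(length(valid), n, replace = TRUE,
                           prob = w[valid])]
  nr <- grid_nrow(truth)
  row <- ((pick - 1L) %% nr) + 1L
  col <- ((pick - 1L) %/% nr) + 1L
  u <- stats::runif(n); v <- stats::runif(n)
  tibble::tibble(
    record_id = sprintf("occ%05d", seq_len(n)),
    lon = truth$origin_lon + (col - 1 + u) * truth$cellsize,
    lat = truth$origin_lat - (row - 1 + v) * truth$cellsize,
    retained = TRUE,
    drop_reason = "none")
}

#' Apply an additive climate-change delta to a stack
#'
#' Named layers are shifted by the given amounts; unnamed layers are copied
#' unchanged. Geometry is preserved, so deltas compose additively.
#'
#' @param current A [grid_stack()].
#' @param shifts Named numeric vector of additive shifts (names are layers).
#' @return A new [grid_stack()].
#' @export
make_future_stack <- function(current, shifts) {
  stopifnot(inherits(current, "grid_stack"))
  unknown <- setdiff(names(shifts), names(current$layers))
  if (length(unknown))
    stop(sprintf("shift(s) name unknown layer(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  layers <- current$layers
  for (nm in names(shifts)) {
    g <- layers[[nm]]
    g$values <- g$values + shifts[[nm]]
    layers[[nm]] <- g
  }
  grid_stack(layers)
}

#' Scenario grid of periods by forcing pathways
#'
#' Builds the standard 3 x 4 scenario design — periods 2041-2060, 2061-2080,
#' 2081-2100 crossed with pathways at radiative forcing 2.6, 4.5, 7.0 and
#' 8.5 W/m2 — as a ladder of additive shifts. The shift applied to each
#' layer is `base_shift[layer] * intensity`, where the intensity grows with
#' both period and forcing: `intensity = period_index * forcing / 8.5`.
#'
#' @param base_shift Named numeric vector: per-layer shift at unit intensity.
#' @return A tibble with columns `label`, `period`, `ssp`, `forcing`,
#'   `intensity` and a list-column `shifts`.
#' @export
scenario_grid <- function(base_shift) {
  periods <- c("2041-2060", "2061-2080", "2081-2100")
  forcings <- c(2.6, 4.5, 7.0, 8.5)
  ssps <- c("SSP2.6", "SSP4.5", "SSP7.0", "SSP8.5")
  out <- tidyr::expand_grid(period = periods, ssp_i = seq_along(forcings))
  out$ssp <- ssps[out$ssp_i]
  out$forcing <- forcings[out$ssp_i]
  out$intensity <- match(out$period, periods) * out$forcing / max(forcings)
  out$label <- paste(out$period, out$ssp)
  out$shifts <- lapply(out$intensity, function(i) base_shift * i)
  out[c("label", "period", "ssp", "forcing", "intensity", "shifts")]
}

#' Random climate-unit partition of a lattice
#'
#' Voronoi partition (in cell index space) around `k` random seed cells;
#' every valid cell receives a code in `1..k`, all codes non-empty.
#'
#' @param nrows,ncols Lattice size.
#' @param k Number of zones.
#' @param seed Integer seed.
#' @param template Optional [env_grid()] supplying geometry and no-data mask.
#' @return An [env_grid()] of integer codes.
#' @export
make_zones <- function(nrows, ncols, k, seed = 1L, template = NULL) {
  if (!is.null(template)) {
    nrows <- grid_nrow(template); ncols <- grid_ncol(template)
  }
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (k > nrows * ncols)
    stop("`k` exceeds the number of cells", call. = FALSE)
  withr::local_seed(seed)
  centers <- sample.int(nrows * ncols, k)
  cr <- ((centers - 1L) %% nrows) + 1L
  cc <- ((centers - 1L) %/% nrows) + 1L
  rows <- matrix(rep(seq_len(nrows), ncols), nrows, ncols)
  cols <- matrix(rep(seq_len(ncols), each = nrows), nrows, ncols)
  best <- matrix(1L, nrows, ncols)
  bestd <- (rows - cr[1])^2 + (cols - cc[1])^2
  if (k > 1L) for (z in 2:k) {
    d <- (rows - cr[z])^2 + (cols - cc[z])^2
    upd <- d < bestd
    best[upd] <- z
    bestd[upd] <- d[upd]
  }
  zones <- best + 0  # numeric storage
  if (!is.null(template)) {
    zones[is.na(template$values)] <- NA_real_
    env_grid(zones, template$origin_lon, template$origin_lat,
             template$cellsize)
  } else {
    env_grid(zones)
  }
}

#' Build a complete synthetic study system
#'
#' Bundles everything a pipeline run needs with known truth: a current
#' climate stack, a logistic suitability truth, presence records sampled
#' from it, an urban mask, a climate-zone partition, and a ladder of 12
#' future scenarios (3 periods x 4 forcing pathways) whose additive shifts
#' move the informative layers toward the niche optimum as intensity grows.
#'
#' Defaults: a 100 x 100 lattice, 6 layers of which 2 carry the niche signal,
#' 300 presences.
#'
#' @param nrows,ncols Lattice size.
#' @param n_layers Number of environmental layers (>= 2).
#' @param n_presences Number of presence records to sample.
#' @param smoothness Field length-scale in cells.
#' @param intercept,coefficients Logistic truth parameters. The default —
#'   intercept -5, coefficient +3 on `env1`, -3 on `env2`, 0 on the rest —
#'   describes a species occupying roughly 15% of the landscape with a
#'   sharply climate-determined niche, the regime of a strongly invasive
#'   grass tracked by a high-accuracy niche model.
#' @param urban_fraction Fraction of cells flagged urban.
#' @param k_zones Number of climate units.
#' @param scenario_shift Per-layer shift at unit scenario intensity; default
#'   `+0.3` on `env1` and `-0.3` on `env2` (toward the niche optimum), i.e.
#'   roughly a third of the landscape's spatial standard deviation per unit
#'   of scenario intensity.
#' @param seed Master seed.
#' @return A list of class `synthetic_world` with elements `current`,
#'   `truth`, `occurrences`, `urban_mask`, `zones`, `scenarios`, `futures`,
#'   `niche` (intercept and coefficients), and `seed`.
#' @export
synthetic_world <- function(nrows = 100, ncols = 100, n_layers = 6,
                            n_presences = 300, smoothness = 8,
                            intercept = -5, coefficients = NULL,
                            urban_fraction = 0.02, k_zones = 8,
                            scenario_shift = NULL, seed = 1L) {
  stopifnot(n_layers >= 2)
  layer_names <- paste0("env", seq_len(n_layers))
  if (is.null(coefficients)) {
    coefficients <- stats::setNames(rep(0, n_layers), layer_names)
    coefficients["env1"] <- 3
    coefficients["env2"] <- -3
  }
  if (is.null(scenario_shift)) {
    scenario_shift <- c(env1 = 0.3, env2 = -0.3)
  }
  current <- make_env_stack(nrows, ncols, layer_names,
                            smoothness = smoothness,
                            seed = derive_seed(seed, "env"))
  truth <- true_suitability(current, intercept, coefficients)
  occurrences <- sample_occurrences(truth, n_presences,
                                    seed = derive_seed(seed, "occ"))
  withr::local_seed(derive_seed(seed, "urban"))
  urb <- matrix(as.numeric(stats::runif(nrows * ncols) < urban_fraction),
                nrows, ncols)
  urban_mask <- env_grid(urb, truth$origin_lon, truth$origin_lat,
                         truth$cellsize)
  zones <- make_zones(nrows, ncols, k_zones,
                      seed = derive_seed(seed, "zones"), template = truth)
  scenarios <- scenario_grid(scenario_shift)
  futures <- lapply(scenarios$shifts, function(s) make_future_stack(current, s))
  names(futures) <- scenarios$label
  structure(
    list(current = current, truth = truth, occurrences = occurrences,
         urban_mask = urban_mask, zones = zones, scenarios = scenarios,
         futures = futures,
         niche = list(intercept = intercept, coefficients = coefficients),
         seed = seed),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  g <- x$truth
  cat(sprintf(
    "<synthetic_world> %d x %d cells, %d layers, %d presences, %d scenarios\n",
    grid_nrow(g), grid_ncol(g), length(x$current$layers),
    nrow(x$occurrences), length(x$futures)))
  invisible(x)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic splitting of one master seed into independent per-stage
#' streams: `hash(master, stage, index)` folded into a 31-bit integer, so
#' inserting new stages does not shuffle existing streams.
#'
#' @param master Integer master seed.
#' @param stage Stage name (character scalar).
#' @param index Optional replicate index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  h <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  h <- (h * 131 + as.numeric(index)) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}
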