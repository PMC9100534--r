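#' Project an ensemble onto a (current or future) climate stack
#'
#' Each converged replicate predicts with its own training scalers (no
#' refit); the projection is the cellwise mean of the replicates' logistic
#' grids. Projecting onto the training stack reproduces the ensemble's
#' integrated grid.
#'
#' @param ensemble A [run_ensemble()] object.
#' @param stack A [grid_stack()] carrying the ensemble's variables.
#' @return An [env_grid()] of mean occurrence probabilities.
#' @export
project_ensemble <- function(ensemble, stack) {
  stopifnot(inherits(ensemble, "cnm_ensemble"), inherits(stack, "grid_stack"))
  missing_layers <- setdiff(ensemble$variables, names(stack$layers))
  if (length(missing_layers))
    stop(sprintf("stack lacks layer(s): %s",
                 paste(missing_layers, collapse = ", ")), call. = FALSE)
  stack <- grid_stack(stack$layers[ensemble$variables])
  g <- stack$layers[[1]]
  mask <- stack_valid_mask(stack)
  idx <- which(mask)
  vals <- as.data.frame(lapply(stack$layers, function(l) l$values[idx]))
  G <- feature_matrix(ensemble$expansion, vals)
  acc <- numeric(length(idx))
  n_ok <- 0L
  for (r in seq_along(ensemble$models)) {
    m <- ensemble$models[[r]]
    if (!m$converged) next
    acc <- acc + to_logistic(m, exp(as.numeric(G %*% m$lambda) - m$log_z))
    n_ok <- n_ok + 1L
  }
  out <- matrix(NA_real_, grid_nrow(g), grid_ncol(g))
  out[idx] <- acc / n_ok
  env_grid(out, g$origin_lon, g$origin_lat, g$cellsize)
}

#' Classify occurrence probabilities into habitat suitability classes
#'
#' `[0, t_low)` is unsuitable (0), `[t_low, t_high]` moderately suitable (1),
#' `(t_high, 1]` highly suitable (2); both boundary values belong to the
#' moderate class.
#'
#' @param prob An [env_grid()] of probabilities.
#' @param t_low,t_high Class thresholds (defaults 0.1 and 0.5).
#' @return An [env_grid()] with codes 0/1/2 (class `habitat_class` attr).
#' @export
classify_habitat <- function(prob, t_low = 0.1, t_high = 0.5) {
  stopifnot(inherits(prob, "env_grid"), t_low > 0, t_low < t_high, t_high < 1)
  p <- prob$values
  cls <- ifelse(p < t_low, 0, ifelse(p <= t_high, 1, 2))
  g <- env_grid(cls, prob$origin_lon, prob$origin_lat, prob$cellsize)
  attr(g, "thresholds") <- c(t_low = t_low, t_high = t_high)
  g
}

#' Percent cover of each suitability class
#'
#' @param cls A [classify_habitat()] grid.
#' @return A tibble with one row: `high_pct`, `moderate_pct`,
#'   `unsuitable_pct` (percent of valid cells, summing to 100).
#' @export
class_fractions <- function(cls) {
  v <- cls$values[!is.na(cls$values)]
  if (length(v) == 0L) stop("class grid has no valid cells", call. = FALSE)
  tibble::tibble(
    high_pct = 100 * mean(v == 2),
    moderate_pct = 100 * mean(v == 1),
    unsuitable_pct = 100 * mean(v == 0))
}

#' Suitability-class composition per climate unit
#'
#' Row percentages of high/moderate/unsuitable cover within each zone's
#' valid cells; each populated row sums to 100.
#'
#' @param cls A [classify_habitat()] grid.
#' @param zones An [env_grid()] of integer zone codes, aligned with `cls`.
#' @return A tibble: `zone`, `n_cells`, `high_pct`, `moderate_pct`,
#'   `unsuitable_pct`, `empty` (TRUE where a zone has no jointly valid cell).
#' @export
zonal_overlap <- function(cls, zones) {
  stop_if_misaligned(cls, zones)
  z <- zones$values
  c_ <- cls$values
  zcodes <- sort(unique(z[!is.na(z)]))
  rows <- lapply(zcodes, function(code) {
    v <- c_[!is.na(z) & z == code & !is.na(c_)]
    if (length(v) == 0L)
      tibble::tibble(zone = code, n_cells = 0L, high_pct = NA_real_,
                     moderate_pct = NA_real_, unsuitable_pct = NA_real_,
                     empty = TRUE)
    else
      tibble::tibble(zone = code, n_cells = length(v),
                     high_pct = 100 * mean(v == 2),
                     moderate_pct = 100 * mean(v == 1),
                     unsuitable_pct = 100 * mean(v == 0),
                     empty = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Multivariate environmental similarity surface (MESS)
#'
#' For each cell and variable, with `p` the cell value, `f` the percentage
#' of reference values strictly below `p`, and `min`/`max` the reference
#' range, the similarity is
#' `S = 100 (p - min)/(max - min)` when `f = 0`;
#' `S = 2 f` when `0 < f <= 50`;
#' `S = 2 (100 - f)` when `50 < f < 100`;
#' `S = 100 (max - p)/(max - min)` when `f = 100`.
#' The cell's MESS value is the minimum of `S` over variables: negative
#' exactly when some variable falls outside its reference range.
#'
#' @param reference Data frame (points x variables) of reference
#'   environments, e.g. training presences plus background.
#' @param stack A [grid_stack()] carrying the reference variables.
#' @return An [env_grid()] of MESS values (`<= 100`).
#' @export
mess <- function(reference, stack) {
  stopifnot(inherits(stack, "grid_stack"))
  ref <- as.data.frame(reference)
  vars <- intersect(names(stack$layers), names(ref))
  if (length(vars) == 0L)
    stop("reference shares no variables with the stack", call. = FALSE)
  for (v in vars) {
    if (sum(is.finite(ref[[v]])) < 2L)
      stop(sprintf("reference variable '%s' needs >= 2 finite values", v),
           call. = FALSE)
    if (min(ref[[v]], na.rm = TRUE) == max(ref[[v]], na.rm = TRUE))
      stop(sprintf("reference variable '%s' has zero range", v),
           call. = FALSE)
  }
  g <- stack$layers[[1]]
  mask <- stack_valid_mask(grid_stack(stack$layers[vars]))
  idx <- which(mask)
  smin <- rep(Inf, length(idx))
  for (v in vars) {
    rv <- sort(ref[[v]][is.finite(ref[[v]])])
    n <- length(rv)
    p <- stack$layers[[v]]$values[idx]
    f <- 100 * findInterval(p, rv, left.open = TRUE) / n
    rmin <- rv[1]; rmax <- rv[n]
    s <- ifelse(f == 0, 100 * (p - rmin) / (rmax - rmin),
         ifelse(f <= 50, 2 * f,
         ifelse(f < 100, 2 * (100 - f),
                100 * (rmax - p) / (rmax - rmin))))
    smin <- pmin(smin, s)
  }
  out <- matrix(NA_real_, grid_nrow(g), grid_ncol(g))
  out[idx] <- smin
  env_grid(out, g$origin_lon, g$origin_lat, g$cellsize)
}

#' Integrate per-replicate MESS grids
#'
#' Cellwise mean across replicates, plus the sign classification used for
#' overlap summaries: a cell is "negative" (novel climate) when the mean is
#' strictly below zero.
#'
#' @param per_run_mess List of aligned MESS [env_grid()]s.
#' @return A list with `mean` (env_grid) and `negative` (env_grid of 0/1).
#' @export
integrate_mess <- function(per_run_mess) {
  stopifnot(length(per_run_mess) >= 1L)
  g <- per_run_mess[[1]]
  for (other in per_run_mess[-1]) stop_if_misaligned(g, other)
  acc <- matrix(0, grid_nrow(g), grid_ncol(g))
  for (m in per_run_mess) acc <- acc + m$values
  acc <- acc / length(per_run_mess)
  neg <- (acc < 0) + 0
  neg[is.na(acc)] <- NA_real_
  list(mean = env_grid(acc, g$origin_lon, g$origin_lat, g$cellsize),
       negative = env_grid(neg, g$origin_lon, g$origin_lat, g$cellsize))
}

#' Percent of suitable habitat overlapping negative-MESS (novel) climate
#'
#' `100 * |class in {moderate, high} and MESS negative| /
#'  |class in {moderate, high}|`.
#'
#' @param cls A [classify_habitat()] grid.
#' @param mess_negative An aligned [env_grid()] of 0/1 negative flags.
#' @return Percentage (scalar); `NA` with a warning when no suitable cells.
#' @export
suitable_negative_overlap <- function(cls, mess_negative) {
  stop_if_misaligned(cls, mess_negative)
  suit <- !is.na(cls$values) & cls$values >= 1
  if (!any(suit)) {
    warning("no suitable cells; overlap undefined", call. = FALSE)
    return(NA_real_)
  }
  neg <- !is.na(mess_negative$values) & mess_negative$values > 0
  100 * sum(suit & neg) / sum(suit)
}

#' Full per-scenario summary of an ensemble projection
#'
#' Projects the ensemble on a scenario stack, classifies the probabilities,
#' runs the per-replicate MESS analyses against each replicate's reference
#' environments (training presences plus the shared background), integrates
#' them, and summarizes class cover and negative-MESS overlap — one
#' scenario row of the habitat-cover table.
#'
#' @param ensemble A [run_ensemble()] object.
#' @param stack Scenario [grid_stack()].
#' @param label Scenario label.
#' @param t_low,t_high Classification thresholds.
#' @param mess_reference `"presence_background"` (default) or
#'   `"presences_only"`.
#' @return A list of class `scenario_result`: `label`, `prob`, `class`,
#'   `fractions`, `mess_mean`, `mess_negative`, `negative_overlap_pct`.
#' @export
scenario_summary <- function(ensemble, stack, label = "scenario",
                             t_low = 0.1, t_high = 0.5,
                             mess_reference = c("presence_background",
                                                "presences_only")) {
  mess_reference <- match.arg(mess_reference)
  prob <- project_ensemble(ensemble, stack)
  cls <- classify_habitat(prob, t_low, t_high)
  vars <- ensemble$variables
  stack_v <- grid_stack(stack$layers[vars])
  pres_vals <- ensemble$presence_values
  per_run <- list()
  k <- 0L
  for (r in seq_along(ensemble$models)) {
    m <- ensemble$models[[r]]
    if (!m$converged) next
    ids <- ensemble$runs$train_ids[[r]]
    tr_vals <- pres_vals[match(ids, ensemble$occ$record_id), vars,
                         drop = FALSE]
    ref <- if (mess_reference == "presence_background")
      rbind(tr_vals, ensemble$background$values[vars])
    else tr_vals
    k <- k + 1L
    per_run[[k]] <- mess(ref, stack_v)
  }
  integ <- integrate_mess(per_run)
  tibble_row <- class_fractions(cls)
  list(label = label, prob = prob, class = cls, fractions = tibble_row,
       mess_mean = integ$mean, mess_negative = integ$negative,
       negative_overlap_pct = suitable_negative_overlap(cls, integ$negative))
}
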