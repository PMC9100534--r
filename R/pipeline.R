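#' Pipeline configuration
#'
#' Assembles and validates the settings for [run_pipeline()]. Exactly one of
#' `synthetic` (a list of [synthetic_world()] arguments) or `paths` (a list
#' with `occurrences`, `current` (named layer files), `futures` (named list
#' of named layer files), optional `zones`, `urban_mask`) must be given.
#' Defaults mirror the conventional design: 2.5-km thinning radius, 0.60
#' correlation threshold, 75% training fraction, 100 bootstrap replicates,
#' 0.1/0.5 classification thresholds, 10,000 change-test points, alpha 0.05.
#'
#' @param synthetic List of arguments to [synthetic_world()], or `NULL`.
#' @param paths List of input file paths, or `NULL`.
#' @param thin_radius_km Buffer-thinning radius.
#' @param cor_threshold Redundancy threshold for variable selection.
#' @param ensemble See [ensemble_config()].
#' @param t_low,t_high Habitat classification thresholds.
#' @param change_n,alpha Change-test sample size and significance level.
#' @param seed Master seed; every stage seed derives from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = list(), paths = NULL,
                            thin_radius_km = 2.5, cor_threshold = 0.60,
                            ensemble = ensemble_config(),
                            t_low = 0.1, t_high = 0.5,
                            change_n = 10000, alpha = 0.05, seed = 1L) {
  has_syn <- !is.null(synthetic)
  has_paths <- !is.null(paths)
  if (has_syn == has_paths)
    stop("exactly one of `synthetic` or `paths` must be given",
         call. = FALSE)
  stopifnot(thin_radius_km > 0, cor_threshold > 0, cor_threshold <= 1,
            t_low > 0, t_low < t_high, t_high < 1, change_n >= 3,
            alpha > 0, alpha < 1)
  structure(
    list(synthetic = synthetic, paths = paths,
         thin_radius_km = thin_radius_km, cor_threshold = cor_threshold,
         ensemble = ensemble, t_low = t_low, t_high = t_high,
         change_n = change_n, alpha = alpha, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with keys matching [pipeline_config()] arguments
#'   (ensemble settings under an `ensemble` mapping).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ens <- do.call(ensemble_config, y$ensemble %||% list())
  args <- y[setdiff(names(y), "ensemble")]
  args$ensemble <- ens
  do.call(pipeline_config, args)
}

# Dependency-free provenance fingerprint: position-weighted polynomial hash
# over file bytes, folded block-wise mod 2^31 - 1.
fnv1a_file <- function(path) {
  bytes <- as.integer(readBin(path, "raw", n = file.info(path)$size))
  p <- 2147483647
  h <- 2166136261 %% p
  block <- 4096L
  n <- length(bytes)
  i <- 1L
  while (i <= n) {
    chunk <- bytes[i:min(i + block - 1L, n)]
    s <- sum(chunk * seq_along(chunk)) %% p
    h <- (h * 131071 + s) %% p  # keeps h * 131071 < 2^49, exact in doubles
    i <- i + block
  }
  sprintf("%08x", h)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    args$seed <- derive_seed(config$seed, "world")
    world <- do.call(synthetic_world, args)
    list(current = world$current, futures = world$futures,
         occurrences = world$occurrences, zones = world$zones,
         urban_mask = world$urban_mask, truth = world$truth, world = world)
  } else {
    p <- config$paths
    current <- read_stack(unlist(p$current),
                          names = names(p$current))
    futures <- lapply(p$futures, function(fp)
      read_stack(unlist(fp), names = names(fp)))
    occ <- read_occurrences(p$occurrences,
                            lon_column = p$lon_column %||% "decimalLongitude",
                            lat_column = p$lat_column %||% "decimalLatitude")
    list(current = current, futures = futures, occurrences = occ,
         zones = if (!is.null(p$zones)) read_grid(p$zones),
         urban_mask = if (!is.null(p$urban_mask)) read_grid(p$urban_mask),
         truth = NULL, world = NULL)
  }
}

#' Run the full niche-modelling pipeline
#'
#' Stages, in order: ingest -> urban filter -> buffer thinning -> value
#' extraction -> correlation-based variable selection -> bootstrap maxent
#' ensemble -> projection, classification and zonal overlap per scenario ->
#' MESS integration and negative-overlap summaries -> identity-line change
#' regressions. All stage seeds derive from the master seed, so re-running
#' the same configuration reproduces every output byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); grids are written
#'   as ESRI ASCII, tables as CSV, and a JSON manifest records the
#'   configuration, seeds and output fingerprints.
#' @return Invisibly, a list with the in-memory results (`occ`, `selection`,
#'   `ensemble`, `scenario_table`, `zonal`, `change`, `deciles`, paths).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_pipeline_inputs(config)

  occ <- inputs$occurrences
  n0 <- sum(occ$retained)
  if (!is.null(inputs$urban_mask))
    occ <- filter_urban(occ, inputs$urban_mask)
  n1 <- sum(occ$retained)
  occ <- thin_buffers(occ, radius_km = config$thin_radius_km,
                      seed = derive_seed(config$seed, "thin"))
  n2 <- sum(occ$retained)
  message(sprintf("occurrences: %d ingested, %d after urban filter, %d after thinning",
                  n0, n1, n2))

  vals <- extract_values(inputs$current, retained_occ(occ))
  corr <- spearman_matrix(vals)
  selection <- select_variables(corr, threshold = config$cor_threshold)
  vars <- retained_variables(selection)
  message(sprintf("variables: %d of %d retained (threshold %.2f)",
                  length(vars), nrow(selection), config$cor_threshold))

  ens <- run_ensemble(occ, inputs$current, config = config$ensemble,
                      seed = derive_seed(config$seed, "ensemble"),
                      variables = vars)
  message(sprintf("ensemble: mean test AUC %.3f (SE %.3g)",
                  ens$auc_mean, ens$auc_se))

  deciles <- count_presences_per_decile(occ, ens$integrated)
  cls_current <- classify_habitat(ens$integrated, config$t_low,
                                  config$t_high)
  zonal <- if (!is.null(inputs$zones))
    zonal_overlap(cls_current, inputs$zones)

  current_row <- dplyr::bind_cols(
    tibble::tibble(scenario = "current"),
    class_fractions(cls_current),
    tibble::tibble(negative_mess_overlap_pct = NA_real_))
  scen_rows <- list(current_row)
  change_futures <- list()
  write_grid(ens$integrated, file.path(out_dir, "prob_current.asc"))
  write_grid(cls_current, file.path(out_dir, "class_current.asc"))
  for (lbl in names(inputs$futures)) {
    s <- scenario_summary(ens, inputs$futures[[lbl]], label = lbl,
                          t_low = config$t_low, t_high = config$t_high)
    scen_rows[[length(scen_rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(scenario = lbl), s$fractions,
      tibble::tibble(negative_mess_overlap_pct = s$negative_overlap_pct))
    change_futures[[lbl]] <- s$prob
    safe <- gsub("[^A-Za-z0-9.-]+", "_", lbl)
    write_grid(s$prob, file.path(out_dir, sprintf("prob_%s.asc", safe)))
    write_grid(s$class, file.path(out_dir, sprintf("class_%s.asc", safe)))
    write_grid(s$mess_mean, file.path(out_dir, sprintf("mess_%s.asc", safe)))
  }
  scenario_table <- dplyr::bind_rows(scen_rows)

  change <- if (length(change_futures))
    change_table(ens$integrated, change_futures, n = config$change_n,
                 seed = derive_seed(config$seed, "change"),
                 alpha = config$alpha)

  paths <- list(
    selection = file.path(out_dir, "variable_selection.csv"),
    correlations = file.path(out_dir, "correlation_matrix.csv"),
    occurrences = file.path(out_dir, "occurrences.csv"),
    runs = file.path(out_dir, "ensemble_runs.csv"),
    deciles = file.path(out_dir, "presence_deciles.csv"),
    scenario = file.path(out_dir, "scenario_summary.csv"),
    zonal = file.path(out_dir, "zonal_overlap.csv"),
    change = file.path(out_dir, "change_tests.csv"))
  readr::write_csv(selection, paths$selection)
  corr_df <- tibble::as_tibble(as.data.frame(unclass(corr)),
                               .name_repair = "minimal")
  corr_df <- dplyr::bind_cols(tibble::tibble(variable = colnames(corr)),
                              corr_df)
  readr::write_csv(corr_df, paths$correlations)
  write_occurrences(occ, paths$occurrences)
  readr::write_csv(tidy(ens), paths$runs)
  readr::write_csv(deciles, paths$deciles)
  readr::write_csv(scenario_table, paths$scenario)
  if (!is.null(zonal)) readr::write_csv(zonal, paths$zonal)
  if (!is.null(change)) readr::write_csv(change, paths$change)

  out_files <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- list(
    config = config_manifest(config),
    seed = config$seed,
    counts = list(ingested = n0, after_urban = n1, after_thinning = n2),
    variables = vars,
    auc_mean = ens$auc_mean, auc_se = ens$auc_se,
    outputs = stats::setNames(lapply(out_files, fnv1a_file),
                              basename(out_files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(occ = occ, correlations = corr, selection = selection,
                 ensemble = ens, deciles = deciles,
                 scenario_table = scenario_table, zonal = zonal,
                 change = change, class_current = cls_current,
                 inputs = inputs, paths = paths, out_dir = out_dir))
}

config_manifest <- function(config) {
  m <- unclass(config)
  m$synthetic <- if (!is.null(m$synthetic)) m$synthetic else NULL
  m
}
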