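#' Read occurrence records from delimited text
#'
#' Expects Darwin-Core-style decimal-degree coordinate columns (GBIF's
#' `decimalLongitude` / `decimalLatitude` by default). Rows with unparsable
#' or out-of-range coordinates are dropped with a message; record ids come
#' from an id column when present, otherwise from the row number.
#'
#' @param path Delimited text file (comma/tab sniffed by readr).
#' @param lon_column,lat_column Names of the coordinate columns.
#' @param id_column Optional record-id column.
#' @return An occurrence tibble: `record_id`, `lon`, `lat`, `retained`,
#'   `drop_reason` (all retained, reason `"none"`).
#' @export
read_occurrences <- function(path,
                             lon_column = "decimalLongitude",
                             lat_column = "decimalLatitude",
                             id_column = NULL) {
  raw <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                           progress = FALSE)
  for (col in c(lon_column, lat_column))
    if (!col %in% names(raw))
      stop(sprintf("occurrence file lacks column '%s'", col), call. = FALSE)
  lon <- suppressWarnings(as.numeric(raw[[lon_column]]))
  lat <- suppressWarnings(as.numeric(raw[[lat_column]]))
  ids <- if (!is.null(id_column)) {
    if (!id_column %in% names(raw))
      stop(sprintf("occurrence file lacks column '%s'", id_column),
           call. = FALSE)
    as.character(raw[[id_column]])
  } else {
    sprintf("rec%05d", seq_len(nrow(raw)))
  }
  if (anyDuplicated(ids))
    stop("record ids must be unique", call. = FALSE)
  ok <- is.finite(lon) & is.finite(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  n_bad <- sum(!ok)
  if (n_bad > 0)
    message(sprintf("dropped %d record(s) with invalid coordinates", n_bad))
  tibble::tibble(record_id = ids[ok], lon = lon[ok], lat = lat[ok],
                 retained = TRUE, drop_reason = "none")
}

retained_occ <- function(occ) occ[occ$retained, , drop = FALSE]

validate_occ <- function(occ) {
  need <- c("record_id", "lon", "lat", "retained", "drop_reason")
  if (!all(need %in% names(occ)))
    stop(sprintf("occurrence table lacks column(s): %s",
                 paste(setdiff(need, names(occ)), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(occ$record_id))
    stop("record ids must be unique", call. = FALSE)
  invisible(occ)
}

#' Flag occurrence records that fall on urban cells
#'
#' Records on cells where the mask is positive (non-zero, non-`NA`) get
#' `drop_reason = "urban"`; already-dropped records are untouched.
#'
#' @param occ Occurrence tibble.
#' @param urban_mask An [env_grid()]; positive cells are urban.
#' @return The occurrence tibble with urban records flagged.
#' @export
filter_urban <- function(occ, urban_mask) {
  validate_occ(occ)
  act <- which(occ$retained)
  if (length(act) == 0L) return(occ)
  idx <- cell_of(urban_mask, occ$lon[act], occ$lat[act])
  if (any(!idx$inside))
    stop(sprintf("occurrence point(s) outside urban mask extent at index: %s",
                 paste(utils::head(act[!idx$inside], 5), collapse = ", ")),
         call. = FALSE)
  v <- urban_mask$values[cbind(idx$row, idx$col)]
  hit <- !is.na(v) & v > 0
  occ$retained[act[hit]] <- FALSE
  occ$drop_reason[act[hit]] <- "urban"
  occ
}

#' Thin occurrence records by overlapping circular buffers
#'
#' Two records' buffers overlap when their great-circle distance is strictly
#' less than `2 * radius_km`. On each connected component of the overlap
#' graph exactly one record is kept, chosen uniformly at random with a
#' component-local seed derived from `seed` and the sorted member ids, so the
#' result is independent of row order. All retained pairwise distances are
#' therefore `>= 2 * radius_km`, and thinning an already-thinned table is a
#' no-op.
#'
#' @param occ Occurrence tibble.
#' @param radius_km Buffer radius in kilometres (default 2.5).
#' @param seed Integer seed for the per-component choice.
#' @return The occurrence tibble with thinned records flagged
#'   (`drop_reason = "thinned"`).
#' @export
thin_buffers <- function(occ, radius_km = 2.5, seed = 1L) {
  validate_occ(occ)
  stopifnot(radius_km > 0)
  act <- which(occ$retained)
  n <- length(act)
  if (n <= 1L) return(occ)
  d <- pairwise_km(occ$lon[act], occ$lat[act])
  adj <- d < 2 * radius_km
  diag(adj) <- FALSE
  comp <- connected_components(adj)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) == 1L) next
    ids <- sort(occ$record_id[act[members]])
    local_seed <- derive_seed(seed, paste(ids, collapse = "|"))
    withr::local_seed(local_seed)
    keep_id <- ids[sample.int(length(ids), 1L)]
    drop <- members[occ$record_id[act[members]] != keep_id]
    occ$retained[act[drop]] <- FALSE
    occ$drop_reason[act[drop]] <- "thinned"
  }
  occ
}

# Components of an undirected graph given a logical adjacency matrix.
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Count presences per probability decile
#'
#' Tallies retained records over the ten occurrence-probability deciles
#' `[0,0.1), ..., [0.9,1.0]` of a probability grid and reports counts,
#' percentages, and cumulative percentages. Records on no-data cells are
#' excluded with a warning.
#'
#' @param occ Occurrence tibble.
#' @param prob An [env_grid()] of probabilities in `[0, 1]`.
#' @return A tibble with columns `decile`, `lower`, `upper`, `count`,
#'   `percent`, `cumulative_percent`.
#' @export
count_presences_per_decile <- function(occ, prob) {
  validate_occ(occ)
  act <- retained_occ(occ)
  idx <- cell_of(prob, act$lon, act$lat)
  if (any(!idx$inside))
    stop("occurrence point(s) outside probability grid extent", call. = FALSE)
  p <- prob$values[cbind(idx$row, idx$col)]
  if (anyNA(p)) {
    warning(sprintf("%d record(s) on no-data cells excluded from decile counts",
                    sum(is.na(p))), call. = FALSE)
    p <- p[!is.na(p)]
  }
  dec <- pmin(floor(p * 10) + 1L, 10L)
  counts <- tabulate(dec, nbins = 10L)
  pct <- if (sum(counts) > 0) 100 * counts / sum(counts) else rep(0, 10)
  tibble::tibble(
    decile = 1:10,
    lower = seq(0, 0.9, by = 0.1),
    upper = seq(0.1, 1.0, by = 0.1),
    count = counts,
    percent = pct,
    cumulative_percent = cumsum(pct))
}

#' Write an occurrence table to CSV
#' @param occ Occurrence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  validate_occ(occ)
  readr::write_csv(occ, path)
  invisible(path)
}
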