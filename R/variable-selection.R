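#' Spearman rank-correlation matrix of candidate variables
#'
#' Computes pairwise-complete Spearman correlations (average ranks for ties)
#' over a points-by-variables value table, e.g. the output of
#' [extract_values()] at occurrence points. Rows flagged `missing` are
#' excluded pairwise-complete. Constant columns give undefined correlations,
#' reported as `NA` with a warning.
#'
#' @param values Data frame of numeric variables (non-numeric and
#'   `lon`/`lat`/`missing` bookkeeping columns are ignored).
#' @return A symmetric correlation matrix of class `spearman_matrix` with
#'   unit diagonal.
#' @export
spearman_matrix <- function(values) {
  df <- as.data.frame(values)
  df <- df[setdiff(names(df), c("lon", "lat", "missing", "record_id"))]
  df <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(df) < 2L)
    stop("need at least two numeric variables", call. = FALSE)
  if (sum(stats::complete.cases(df)) < 3L)
    stop("need at least three complete rows", call. = FALSE)
  constant <- vapply(df, function(x) stats::sd(x, na.rm = TRUE) == 0,
                     logical(1))
  if (any(constant))
    warning(sprintf("constant variable(s) give undefined correlations: %s",
                    paste(names(df)[constant], collapse = ", ")),
            call. = FALSE)
  m <- suppressWarnings(
    stats::cor(df, method = "spearman", use = "pairwise.complete.obs"))
  diag(m) <- 1
  class(m) <- c("spearman_matrix", class(m))
  m
}

#' Prune correlated variables by the redundancy rule
#'
#' Builds a redundancy graph with an edge wherever the correlation magnitude
#' exceeds `threshold` (strictly), then iterates: retain the variable with
#' the highest number of redundancy links (ties broken alphabetically), drop
#' its neighbours, remove all of them from the graph, and repeat until no
#' edges remain. Isolated variables are retained. The retained set never
#' contains a pair above the threshold.
#'
#' @param corr A correlation matrix (e.g. from [spearman_matrix()]).
#' @param threshold Redundancy threshold on the correlation (default 0.60).
#' @param use_absolute Compare `|rho|` (default) or signed `rho` against the
#'   threshold.
#' @return A tibble with one row per variable: `variable`, `retained`,
#'   `dropped_for` (the retained variable it was correlated with, or `NA`),
#'   `n_links` (initial redundancy degree).
#' @export
select_variables <- function(corr, threshold = 0.60, use_absolute = TRUE) {
  m <- unclass(corr)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  vars <- colnames(m)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(m)))
  cmp <- if (use_absolute) abs(m) else m
  adj <- !is.na(cmp) & cmp > threshold
  diag(adj) <- FALSE
  degree0 <- rowSums(adj)
  alive <- rep(TRUE, length(vars))
  retained <- rep(FALSE, length(vars))
  dropped_for <- rep(NA_character_, length(vars))
  repeat {
    sub <- adj & outer(alive, alive, `&`)
    deg <- rowSums(sub)
    if (all(deg == 0)) break
    # highest degree, alphabetical tie-break
    cand <- which(deg == max(deg))
    pick <- cand[order(vars[cand])][1L]
    retained[pick] <- TRUE
    nb <- which(sub[pick, ])
    dropped_for[nb] <- vars[pick]
    alive[c(pick, nb)] <- FALSE
  }
  retained[alive] <- TRUE  # isolated survivors
  tibble::tibble(variable = vars, retained = retained,
                 dropped_for = dropped_for, n_links = as.integer(degree0))
}

#' Names of the retained variables in a selection report
#' @param selection Output of [select_variables()].
#' @return Character vector.
#' @export
retained_variables <- function(selection) {
  selection$variable[selection$retained]
}
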