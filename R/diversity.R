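#' Hill number of order 1
#'
#' The exponential of the Shannon-Wiener index: the effective number of
#' equally abundant categories.  Zero counts are dropped (0 log 0 := 0).
#'
#' @param counts non-negative abundance vector with a positive total.
#' @return Effective number of categories, in \[1, number present\].
#' @export
hill_q1 <- function(counts) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("all counts are zero")
  p <- counts[counts > 0] / total
  exp(-sum(p * log(p)))
}

#' Rao's quadratic entropy
#'
#' Abundance-weighted expected pairwise dissimilarity,
#' \eqn{Q = \sum_i \sum_j d_{ij} p_i p_j} over ordered pairs (equivalently
#' \eqn{2\sum_{i<j} d_{ij} p_i p_j}), with \eqn{p} the relative abundances.
#' Computed on the plain dissimilarities (no d/2 or Euclidean rescaling);
#' set `halved = TRUE` for the d/2 convention used by some functional
#' diversity software.  Reported in the units of `d` (here Gower
#' dissimilarity, so Q lies in \[0, max d\]).
#'
#' @param counts named non-negative abundance vector (names = taxa).
#' @param d a `dissimilarity_matrix` (or plain symmetric matrix) covering
#'   every taxon with a positive count.
#' @param halved use d/2 instead of d.
#' @return Quadratic entropy Q >= 0.
#' @export
raoq <- function(counts, d, halved = FALSE) {
  d <- .as_dissim(d)
  if (is.null(names(counts)))
    stop("'counts' must be named by taxon")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("all counts are zero")
  absent <- setdiff(names(counts), d$taxa)
  if (length(absent))
    stop("taxa with positive counts absent from the dissimilarity matrix: ",
         paste(absent, collapse = ", "))
  dm <- d$d[names(counts), names(counts), drop = FALSE]
  if (anyNA(dm))
    stop("undefined dissimilarities among present taxa")
  p <- counts / sum(counts)
  q <- drop(p %*% dm %*% p)
  if (halved) q / 2 else q
}

#' Species, guild and functional diversity through time
#'
#' For each time point of a pooled series computes the Hill number of order
#' 1 on species counts, the same on guild counts, and Rao's quadratic
#' entropy on species counts with the trait dissimilarity matrix.
#'
#' @param series a `pooled_series` from [pool_by_time()].
#' @param model a `guild_model` (or named species-to-guild vector).
#' @param d the species `dissimilarity_matrix`.
#' @param halved passed to [raoq()].
#' @return Data frame with columns `time_months`, `is_pre`, `hill_species`,
#'   `hill_guild`, `raoq`.
#' @export
diversity_series <- function(series, model, d, halved = FALSE) {
  stopifnot(inherits(series, "pooled_series"))
  gc <- guild_counts(series, model)
  out <- data.frame(
    time_months = series$time_months,
    is_pre = series$is_pre,
    hill_species = apply(series$counts, 1, hill_q1),
    hill_guild = apply(gc, 1, hill_q1),
    raoq = apply(series$counts, 1, raoq, d = d, halved = halved))
  rownames(out) <- rownames(series$counts)
  out
}
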