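#' Agglomerative clustering of species by trait dissimilarity
#'
#' Hierarchical clustering of the species dissimilarity matrix, the first
#' step of guild assignment.  Clustering is delegated to [stats::hclust()]
#' on the precomputed dissimilarities; `"ward"` maps to Ward's criterion on
#' squared dissimilarities (`ward.D2`).
#'
#' @param d a `dissimilarity_matrix` from [gower_podani()] (validated, no
#'   undefined pairs) or a plain symmetric matrix.
#' @param linkage `"complete"` (default), `"average"` or `"ward"`.
#' @return An [stats::hclust] dendrogram with species as leaves.
#' @export
cluster_guilds <- function(d, linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  d <- .as_dissim(d)
  if (length(d$taxa) < 2L) stop("need at least 2 taxa to cluster")
  if (anyNA(d$d))
    stop("dissimilarity matrix has undefined pairs; resolve them before clustering")
  rep <- suppressWarnings(validate_matrix(d))
  if (!rep$ok) stop("invalid dissimilarity matrix: ", rep$problems[1])
  method <- c(complete = "complete", average = "average",
              ward = "ward.D2")[[linkage]]
  stats::hclust(stats::as.dist(d$d), method = method)
}

.partition_stats <- function(labels, dmat) {
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = dmat)
  sw <- sil[, "sil_width"]
  same <- outer(labels, labels, "==")
  ut <- upper.tri(dmat)
  w <- dmat[ut & same]
  b <- dmat[ut & !same]
  c(cluster_silhouette = mean(tapply(sw, sil[, "cluster"], mean)),
    silhouette = mean(sw),
    wb_ratio = if (length(w) == 0L) 0
               else mean(w) / max(mean(b), .Machine$double.eps))
}

#' Choose the guild cutoff on a dendrogram
#'
#' Scans candidate partitions (cutting the dendrogram at each number of
#' clusters in `k_range`) and scores each by a within/between-distance
#' tradeoff criterion.  The default, `cluster_silhouette`, is the silhouette
#' width macro-averaged over clusters (each cluster's mean silhouette
#' contributes equally), which resists over-partitioning: the pooled
#' per-species mean (`silhouette`) scores singleton splinters as a neutral
#' 0 diluted over all species and therefore tends to split small groups of
#' noisy species off their guilds.  The ratio of mean within-guild to mean
#' between-guild dissimilarity (`wb_ratio`, minimized) is reported as a
#' further alternative; it decreases monotonically with k and is only
#' useful comparatively.  The full per-candidate score trace is retained so
#' the criteria can be compared.  Ties are broken toward the smallest k; a
#' completely flat criterion triggers a warning.
#'
#' @param dend an [stats::hclust] dendrogram from [cluster_guilds()].
#' @param d the `dissimilarity_matrix` the dendrogram was built from.
#' @param k_range integer vector of candidate cluster numbers
#'   (default `2:(n-1)`).
#' @param criterion `"cluster_silhouette"` (default), `"silhouette"` or
#'   `"wb_ratio"`.
#' @return Object of class `guild_model`: the dendrogram, `cutoff_height`,
#'   `k`, `labels` (factor, species to guild, guilds lettered by decreasing
#'   size) and the criterion `trace` data frame.
#' @export
select_cutoff <- function(dend, d, k_range = NULL,
                          criterion = c("cluster_silhouette", "silhouette",
                                        "wb_ratio")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(dend, "hclust"))
  d <- .as_dissim(d)
  n <- length(dend$labels)
  dmat <- d$d[dend$labels, dend$labels]
  if (is.null(k_range)) k_range <- seq(2L, n - 1L)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("empty k_range")
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop("k_range must lie in [2, n-1]")
  cuts <- stats::cutree(dend, k = k_range)
  if (length(k_range) == 1L) cuts <- matrix(cuts, ncol = 1)
  scores <- t(apply(cuts, 2, .partition_stats, dmat = dmat))
  h <- sort(dend$height)
  # cutting midway between merge n-k and n-k+1 yields k clusters
  cut_h <- vapply(k_range, function(k)
    mean(c(h[n - k], if (n - k + 1L <= n - 1L) h[n - k + 1L] else max(h))),
    0)
  trace <- data.frame(k = k_range, height = cut_h,
                      cluster_silhouette = scores[, "cluster_silhouette"],
                      silhouette = scores[, "silhouette"],
                      wb_ratio = scores[, "wb_ratio"])
  crit <- switch(criterion,
                 cluster_silhouette = trace$cluster_silhouette,
                 silhouette = trace$silhouette,
                 wb_ratio = -trace$wb_ratio)
  if (diff(range(crit)) < 1e-12 && length(crit) > 1L)
    warning("criterion is flat across k_range; selecting smallest k")
  best <- which(crit >= max(crit) - 1e-12)[1L]  # ties -> smallest k
  k <- k_range[best]
  raw <- stats::cutree(dend, k = k)
  # letter guilds by decreasing size; ties by first species index
  sizes <- table(raw)
  ord <- order(-as.vector(sizes), vapply(names(sizes), function(g)
    which(raw == as.integer(g))[1L], 0L))
  letters_ <- make.unique(c(LETTERS, paste0("A", LETTERS)))[seq_along(sizes)]
  relabel <- stats::setNames(letters_, names(sizes)[ord])
  labels <- factor(relabel[as.character(raw)], levels = letters_)
  names(labels) <- names(raw)
  structure(list(dendrogram = dend, cutoff_height = trace$height[best],
                 k = k, labels = labels, criterion = criterion,
                 trace = trace),
            class = "guild_model")
}

#' @export
print.guild_model <- function(x, ...) {
  cat(sprintf("guild_model: %d guilds of %d species (criterion %s, cutoff height %.3f)\n",
              x$k, length(x$labels), x$criterion, x$cutoff_height))
  print(table(guild = x$labels))
  invisible(x)
}

#' Guild abundance
#'
#' Sums member-species counts per guild for each row of a pooled series or
#' per-surface abundance table; totals are conserved because every species
#' belongs to exactly one guild.
#'
#' @param x a `pooled_series` or `abundance_table`.
#' @param model a `guild_model` from [select_cutoff()] (or a named
#'   species-to-guild vector).
#' @return Matrix (row x guild) of individual counts.
#' @export
guild_counts <- function(x, model) {
  labels <- if (inherits(model, "guild_model")) model$labels else model
  counts <- if (inherits(x, "pooled_series") || inherits(x, "abundance_table"))
    x$counts else stop("'x' must be a pooled_series or abundance_table")
  map <- stats::setNames(as.character(labels), names(labels))
  lv <- if (is.factor(labels)) levels(labels) else sort(unique(map))
  .aggregate_taxa(counts, map, levels = lv)
}

#' Export a dendrogram in Newick format
#'
#' Writes the guild dendrogram as a Newick tree (merge heights as branch
#' lengths) via \pkg{ape}.
#'
#' @param x a `guild_model` or an [stats::hclust] object.
#' @param path output file.
#' @export
write_newick <- function(x, path) {
  hc <- if (inherits(x, "guild_model")) x$dendrogram else x
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Agreement between two partitions
#'
#' Adjusted Rand index between a recovered guild labelling and a reference
#' (e.g. the planted guilds of the synthetic generator); wraps
#' [mclust::adjustedRandIndex()].
#'
#' @param labels,reference two labellings of the same species (named vectors
#'   or factors; matched by name when both are named).
#' @return Adjusted Rand index (1 = identical partitions up to relabelling).
#' @export
partition_agreement <- function(labels, reference) {
  if (!is.null(names(labels)) && !is.null(names(reference)))
    reference <- reference[names(labels)]
  if (length(labels) != length(reference))
    stop("labellings differ in length")
  mclust::adjustedRandIndex(as.character(labels), as.character(reference))
}
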