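.sample_cols <- c("sample_id", "surface_kind", "epoch", "time_months",
                  "recovery_temp_C", "deployment_months")

.sample_aliases <- list(
  sample_id = c("sample_id", "sample", "sandwich", "surface", "id"),
  surface_kind = c("surface_kind", "kind", "surface_type", "sampler"),
  epoch = c("epoch", "period"),
  time_months = c("time_months", "months_since_eruption", "months", "time"),
  recovery_temp_C = c("recovery_temp_c", "recovery_temperature",
                      "temperature", "temp_c", "temp"),
  deployment_months = c("deployment_months", "deployment_duration",
                        "deployment"))

.normalize_samples <- function(meta) {
  out <- data.frame(sample_id = character(0))
  idx <- lapply(.sample_aliases, function(al)
    .find_col(meta, al, al[1], required = FALSE))
  if (is.na(idx$sample_id))
    stop("sample metadata must contain a sample identifier column")
  out <- data.frame(sample_id = as.character(meta[[idx$sample_id]]),
                    stringsAsFactors = FALSE)
  out$surface_kind <- if (!is.na(idx$surface_kind))
    as.character(meta[[idx$surface_kind]]) else "sandwich"
  out$epoch <- if (!is.na(idx$epoch))
    as.character(meta[[idx$epoch]]) else "post_eruption"
  out$time_months <- if (!is.na(idx$time_months))
    suppressWarnings(as.numeric(meta[[idx$time_months]])) else NA_real_
  out$recovery_temp_C <- if (!is.na(idx$recovery_temp_C))
    suppressWarnings(as.numeric(meta[[idx$recovery_temp_C]])) else NA_real_
  out$deployment_months <- if (!is.na(idx$deployment_months))
    suppressWarnings(as.numeric(meta[[idx$deployment_months]])) else NA_real_
  out
}

#' Construct a sample-by-taxon abundance table
#'
#' @param counts integer matrix, samples in rows, taxa in columns, with
#'   dimnames.
#' @param samples data.frame of per-sample metadata with columns
#'   `sample_id`, `surface_kind` (`"sandwich"`/`"block"`), `epoch`
#'   (`"pre_eruption"`/`"post_eruption"`), `time_months` (months since the
#'   eruption at recovery; `NA` for pre-eruption reference samples),
#'   `recovery_temp_C` and `deployment_months`.
#' @return Object of class `abundance_table`.
#' @export
abundance_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must carry sample and taxon dimnames")
  if (anyDuplicated(rownames(counts))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated taxa")
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- setdiff(.sample_cols, colnames(samples))
  if (length(need))
    stop("sample metadata missing columns: ", paste(need, collapse = ", "))
  samples <- samples[, .sample_cols]
  m <- match(rownames(counts), samples$sample_id)
  if (any(is.na(m)))
    stop("samples without metadata: ",
         paste(rownames(counts)[is.na(m)], collapse = ", "))
  samples <- samples[m, , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$epoch %in% c("pre_eruption", "post_eruption")))
    stop("epoch must be 'pre_eruption' or 'post_eruption'")
  post <- samples$epoch == "post_eruption"
  if (any(is.na(samples$time_months[post])) ||
      any(samples$time_months[post] < 0))
    stop("post-eruption samples need time_months >= 0")
  structure(list(samples = samples,
                 taxa = colnames(counts),
                 counts = counts),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf(
    "abundance_table: %d samples x %d taxa, %g individuals (%d pre-eruption samples)\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts),
    sum(x$samples$epoch == "pre_eruption")))
  invisible(x)
}

#' Read a species-abundance file
#'
#' Accepts the long dialect (`sample, species, count`, the canonical form)
#' and the wide dialect (one sample column followed by one count column per
#' species), auto-detected from the header.  Per-sample metadata (recovery
#' time, temperature, epoch, ...) is taken from `metadata` when supplied, or
#' from extra columns embedded in a long-form counts file.
#'
#' @param counts_file CSV path.
#' @param metadata a data.frame, or path to a CSV, of per-sample metadata;
#'   `NULL` to read metadata columns embedded in `counts_file`.
#' @return An [abundance_table()].
#' @export
read_abundance <- function(counts_file, metadata = NULL) {
  raw <- utils::read.csv(counts_file, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no samples in counts file")
  nm <- .norm_name(colnames(raw))
  long <- any(nm %in% c("species", "taxon", "species_name")) &&
    any(nm %in% c("count", "counts", "n", "abundance"))
  if (long) {
    i_sa <- .find_col(raw, .sample_aliases$sample_id, "sample")
    i_sp <- .find_col(raw, c("species", "taxon", "species_name"), "species")
    i_ct <- .find_col(raw, c("count", "counts", "n", "abundance"), "count")
    if (anyDuplicated(raw[c(i_sa, i_sp)]))
      stop("duplicate (sample, species) pairs in long-form counts file")
    ct <- suppressWarnings(as.numeric(raw[[i_ct]]))
    if (any(is.na(ct)) || any(ct < 0) || any(ct != round(ct)))
      stop("counts must be non-negative integers")
    sa <- unique(as.character(raw[[i_sa]]))
    sp <- unique(as.character(raw[[i_sp]]))
    counts <- matrix(0, length(sa), length(sp), dimnames = list(sa, sp))
    counts[cbind(match(raw[[i_sa]], sa), match(raw[[i_sp]], sp))] <- ct
    if (is.null(metadata)) {
      meta_raw <- raw[!duplicated(raw[[i_sa]]), -c(i_sp, i_ct), drop = FALSE]
      metadata <- .normalize_samples(meta_raw)
    }
  } else {
    i_sa <- .find_col(raw, .sample_aliases$sample_id, "sample",
                      required = FALSE)
    if (is.na(i_sa)) i_sa <- 1L
    if (anyDuplicated(raw[[i_sa]])) stop("duplicated sample rows")
    num <- lapply(raw[, -i_sa, drop = FALSE],
                  function(col) suppressWarnings(as.numeric(col)))
    counts <- matrix(unlist(num), nrow = nrow(raw),
                     dimnames = list(as.character(raw[[i_sa]]), names(num)))
    if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
      stop("counts must be non-negative integers")
  }
  if (is.null(metadata))
    stop("no sample metadata: supply 'metadata' or embed metadata columns")
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- utils::read.csv(metadata, check.names = FALSE,
                                stringsAsFactors = FALSE)
  abundance_table(counts, .normalize_samples(as.data.frame(metadata)))
}

#' Write an abundance table as long-form CSV
#'
#' Writes the canonical long dialect (every sample x taxon cell, zeros
#' included) and, optionally, the sample metadata.
#'
#' @param x an [abundance_table()].
#' @param counts_file output CSV path.
#' @param samples_file optional metadata CSV path.
#' @export
write_abundance <- function(x, counts_file, samples_file = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  long <- data.frame(
    sample_id = rep(rownames(x$counts), times = ncol(x$counts)),
    species = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts), stringsAsFactors = FALSE)
  utils::write.csv(long, counts_file, row.names = FALSE)
  if (!is.null(samples_file))
    utils::write.csv(x$samples, samples_file, row.names = FALSE)
  invisible(counts_file)
}

#' Filter samples by recovery temperature
#'
#' Retains samples whose recovery temperature lies in the closed window
#' `[temp_min, temp_max]`; the study window 1.9-6.5 degC selects the thermal
#' range adequately sampled across the full observation period.
#'
#' @param x an [abundance_table()].
#' @param temp_min,temp_max window bounds in degC (inclusive).
#' @return The filtered [abundance_table()], sample order preserved.
#' @export
filter_samples <- function(x, temp_min = 1.9, temp_max = 6.5) {
  stopifnot(inherits(x, "abundance_table"))
  if (temp_min > temp_max) stop("temp_min must not exceed temp_max")
  keep <- !is.na(x$samples$recovery_temp_C) &
    x$samples$recovery_temp_C >= temp_min &
    x$samples$recovery_temp_C <= temp_max
  if (!any(keep)) warning("temperature window retains no samples")
  out <- x
  out$samples <- x$samples[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  out$counts <- x$counts[keep, , drop = FALSE]
  out
}

#' Drop taxa without trait data
#'
#' Removes taxa absent from the trait table (insufficient trait data) and
#' reports what was dropped; the dropped taxa and their total counts are
#' attached as attribute `"dropped"`.
#'
#' @param x an [abundance_table()].
#' @param traits a [trait_table()].
#' @return The filtered [abundance_table()].
#' @export
retain_species <- function(x, traits) {
  stopifnot(inherits(x, "abundance_table"), inherits(traits, "trait_table"))
  keep <- x$taxa %in% traits$species
  dropped <- data.frame(taxon = x$taxa[!keep],
                        total_count = colSums(x$counts)[!keep],
                        stringsAsFactors = FALSE)
  rownames(dropped) <- NULL
  if (nrow(dropped))
    message(sprintf("retain_species: dropping %d taxa (%g individuals): %s",
                    nrow(dropped), sum(dropped$total_count),
                    paste(dropped$taxon, collapse = ", ")))
  if (!any(keep)) warning("no taxa retained")
  out <- x
  out$counts <- x$counts[, keep, drop = FALSE]
  out$taxa <- x$taxa[keep]
  attr(out, "dropped") <- dropped
  out
}

#' Pool abundances by recovery time
#'
#' Sums counts over all surfaces recovered at the same post-eruption time;
#' pre-eruption samples (the mature reference community) are pooled into a
#' single reference point.
#'
#' @param x an [abundance_table()].
#' @return Object of class `pooled_series` with elements `time_months`
#'   (numeric, `NA` for the pre-eruption point), `is_pre`, `taxa` and
#'   `counts` (time point x taxon).
#' @export
pool_by_time <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  key <- ifelse(x$samples$epoch == "pre_eruption", "pre",
                as.character(x$samples$time_months))
  pooled <- rowsum(x$counts, group = key, reorder = FALSE)
  is_pre <- rownames(pooled) == "pre"
  tm <- suppressWarnings(as.numeric(rownames(pooled)))
  ord <- order(!is_pre, tm)  # pre first, then increasing time
  pooled <- pooled[ord, , drop = FALSE]
  structure(list(time_months = tm[ord], is_pre = is_pre[ord],
                 taxa = colnames(pooled), counts = pooled),
            class = "pooled_series")
}

#' @export
print.pooled_series <- function(x, ...) {
  cat(sprintf("pooled_series: %d time points (%s pre-eruption) x %d taxa\n",
              nrow(x$counts), sum(x$is_pre), ncol(x$counts)))
  invisible(x)
}

# counts (rows x taxa) -> rows x category, mapping taxa through 'map'
# (character vector named by taxon, NA = contributes to no category).
.aggregate_taxa <- function(counts, map, levels) {
  taxa <- colnames(counts)
  if (any(!taxa %in% names(map)))
    stop("taxa without an assignment: ",
         paste(setdiff(taxa, names(map)), collapse = ", "))
  cat <- map[taxa]
  ind <- matrix(0, length(taxa), length(levels),
                dimnames = list(taxa, levels))
  ok <- !is.na(cat)
  ind[cbind(which(ok), match(cat[ok], levels))] <- 1
  counts %*% ind
}

#' Modality abundance within a trait
#'
#' The abundance of a modality is the total number of individuals expressing
#' it: for each row (time point of a [pool_by_time()] series, or individual
#' surface of an [abundance_table()]), counts are summed over the species
#' assigned that modality.  Species with a missing value for the trait
#' contribute to no modality.
#'
#' @param x a `pooled_series` or an `abundance_table`.
#' @param traits a [trait_table()].
#' @param trait a [trait_spec()] or the name of a trait in `traits`.
#' @param specs list of trait specs (required when `trait` is a name).
#' @return Matrix (row x modality) of individual counts.
#' @export
modality_abundance <- function(x, traits, trait, specs = NULL) {
  stopifnot(inherits(traits, "trait_table"))
  if (is.character(trait)) {
    if (is.null(specs)) stop("supply 'specs' when 'trait' is a name")
    trait <- .as_spec_list(specs)[[trait]]
    if (is.null(trait)) stop("unknown trait")
  }
  stopifnot(inherits(trait, "trait_spec"))
  if (!trait$name %in% traits$traits)
    stop("trait '", trait$name, "' not in trait table")
  counts <- if (inherits(x, "pooled_series")) x$counts
            else if (inherits(x, "abundance_table")) x$counts
            else stop("'x' must be a pooled_series or abundance_table")
  map <- stats::setNames(traits$assignment[[trait$name]], traits$species)
  .aggregate_taxa(counts, map, trait$levels)
}
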