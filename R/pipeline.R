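.load_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}

.run_defaults <- list(
  counts = NULL, samples = NULL, definitions = NULL, modalities = NULL,
  out_dir = NULL, temp_min = 1.9, temp_max = 6.5,
  linkage = "complete", criterion = "cluster_silhouette",
  n_rand = 1000L, seed = 1L, mode = "smoothed",
  raoq_exclude_times = NULL, pre_time_months = NULL)

#' Generate a synthetic fixture directory (pipeline entry point)
#'
#' Thin orchestration over [synth_config()] and [write_fixture()]: accepts
#' a YAML file or list with any `synth_config` fields plus `out_dir`.
#'
#' @param config list or YAML path; `out_dir` is required.
#' @return The fixture directory path (invisibly).
#' @export
cmd_simulate <- function(config = list()) {
  defaults <- c(list(out_dir = NULL), formals(synth_config))
  defaults <- defaults[setdiff(names(defaults), "trait_specs")]
  cfg <- .load_config(config, lapply(defaults, function(x)
    if (is.call(x) || is.name(x)) eval(x) else x))
  if (is.null(cfg$out_dir)) stop("config must set 'out_dir'")
  out_dir <- cfg$out_dir
  cfg$out_dir <- NULL
  sc <- do.call(synth_config, cfg)
  write_fixture(out_dir, sc)
  invisible(out_dir)
}

#' Run the full trait-succession pipeline
#'
#' Executes, in order: read trait and abundance tables; filter samples to
#' the recovery-temperature window; drop taxa without trait data; compute
#' the Gower-Podani dissimilarity matrix; cluster and select the guild
#' cutoff; pool counts by recovery time; tabulate modality abundance per
#' trait, guild abundance and the diversity series; and run the
#' randomization trend tests.  All outputs are written as tidy CSV (plus a
#' Newick dendrogram) under `out_dir`, together with a plain-text run log
#' recording the configuration, filters applied, taxa dropped and sample
#' counts.
#'
#' @param config list or YAML path with keys `counts`, `samples` (optional
#'   if metadata is embedded), `definitions`, `modalities`, `out_dir`, and
#'   optionally `temp_min`, `temp_max`, `linkage`, `criterion`, `n_rand`,
#'   `seed`, `mode`, `raoq_exclude_times`, `pre_time_months`.
#' @return Invisibly, a list with the computed objects (`abundance`,
#'   `dissimilarity`, `guild_model`, `series`, `diversity`,
#'   `trend_report`, ...) and the output paths.
#' @export
cmd_run <- function(config) {
  cfg <- .load_config(config, .run_defaults)
  for (key in c("counts", "definitions", "modalities", "out_dir"))
    if (is.null(cfg[[key]])) stop("config must set '", key, "'")
  for (key in c("counts", "samples", "definitions", "modalities"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("input file not found: ", cfg[[key]])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("run started %s", format(Sys.time())),
                 "config:", strsplit(yaml::as.yaml(
                   cfg[!vapply(cfg, is.null, TRUE)]), "\n")[[1]])

  tt <- read_trait_table(cfg$definitions, cfg$modalities)
  ab0 <- read_abundance(cfg$counts, metadata = cfg$samples)
  log_lines <- c(log_lines, sprintf("read %d samples x %d taxa",
                                    nrow(ab0$counts), ncol(ab0$counts)))
  ab1 <- filter_samples(ab0, cfg$temp_min, cfg$temp_max)
  log_lines <- c(log_lines, sprintf(
    "temperature filter [%g, %g] degC: %d -> %d samples",
    cfg$temp_min, cfg$temp_max, nrow(ab0$counts), nrow(ab1$counts)))
  ab <- retain_species(ab1, tt$table)
  dropped <- attr(ab, "dropped")
  log_lines <- c(log_lines, sprintf(
    "trait-data retention: %d -> %d taxa (%g individuals dropped)",
    ncol(ab1$counts), ncol(ab$counts),
    if (nrow(dropped)) sum(dropped$total_count) else 0))
  if (nrow(dropped))
    log_lines <- c(log_lines, paste("  dropped:", dropped$taxon,
                                    "n =", dropped$total_count))

  tt_sub <- trait_table(tt$table$assignment[ab$taxa, , drop = FALSE],
                        tt$specs)
  d <- gower_podani(tt_sub, tt$specs)
  rep <- validate_matrix(d)
  if (!rep$ok) stop("dissimilarity validation failed: ", rep$problems[1])
  hc <- cluster_guilds(d, linkage = cfg$linkage)
  model <- select_cutoff(hc, d, criterion = cfg$criterion)
  log_lines <- c(log_lines, sprintf(
    "clustering (%s linkage, %s criterion): %d guilds at cutoff %.3f",
    cfg$linkage, cfg$criterion, model$k, model$cutoff_height))

  series <- pool_by_time(ab)
  div <- diversity_series(series, model, d)
  report <- trend_report(ab, tt$table, tt$specs, model, d,
                         n_rand = cfg$n_rand, seed = cfg$seed,
                         mode = cfg$mode,
                         raoq_exclude_times = cfg$raoq_exclude_times,
                         pre_time_months = cfg$pre_time_months)

  out <- function(f) file.path(cfg$out_dir, f)
  write_dissimilarity(d, out("dissimilarity.csv"))
  write_newick(model, out("dendrogram.nwk"))
  utils::write.csv(data.frame(species = names(model$labels),
                              guild = as.character(model$labels)),
                   out("guilds.csv"), row.names = FALSE)
  utils::write.csv(model$trace, out("cutoff_trace.csv"), row.names = FALSE)
  for (tr in names(tt$specs)) {
    ma <- modality_abundance(series, tt$table, tt$specs[[tr]])
    utils::write.csv(data.frame(time = rownames(ma), ma, check.names = FALSE),
                     out(sprintf("modality_abundance_%s.csv", .norm_name(tr))),
                     row.names = FALSE)
  }
  gc_ <- guild_counts(series, model)
  utils::write.csv(data.frame(time = rownames(gc_), gc_, check.names = FALSE),
                   out("guild_abundance.csv"), row.names = FALSE)
  div_long <- data.frame(
    time = rep(rownames(div), 3),
    time_months = rep(div$time_months, 3),
    metric = rep(c("hill_species", "hill_guild", "raoq"), each = nrow(div)),
    value = c(div$hill_species, div$hill_guild, div$raoq))
  utils::write.csv(div_long, out("diversity.csv"), row.names = FALSE)
  utils::write.csv(report, out("trend_report.csv"), row.names = FALSE)
  log_lines <- c(log_lines, sprintf("run finished %s", format(Sys.time())))
  writeLines(log_lines, out("run_log.txt"))

  invisible(list(abundance = ab, trait_specs = tt$specs,
                 trait_table = tt$table, dissimilarity = d,
                 guild_model = model, series = series, diversity = div,
                 trend_report = report, out_dir = cfg$out_dir))
}

#' Scan linkage/criterion combinations for the guild cutoff
#'
#' Diagnostic for the unstated clustering choices: runs every combination
#' of linkage (`complete`, `average`, `ward`) and cutoff criterion
#' (`silhouette`, `wb_ratio`) on a trait table and reports the selected
#' number of guilds and both scores.
#'
#' @param config list or YAML path with `definitions` and `modalities`
#'   paths (as in [cmd_run()]), or alternatively pass a `dissimilarity`
#'   object directly.
#' @param d optional precomputed `dissimilarity_matrix` (skips the file
#'   reads).
#' @return Data frame (linkage, criterion, k, silhouette, wb_ratio); also
#'   written to `out_dir/scan_clustering.csv` when `out_dir` is set.
#' @export
cmd_scan_clustering <- function(config = list(), d = NULL) {
  cfg <- .load_config(config, list(definitions = NULL, modalities = NULL,
                                   out_dir = NULL, k_range = NULL))
  if (is.null(d)) {
    if (is.null(cfg$definitions) || is.null(cfg$modalities))
      stop("config must set 'definitions' and 'modalities' (or pass 'd')")
    tt <- read_trait_table(cfg$definitions, cfg$modalities)
    d <- gower_podani(tt$table, tt$specs)
  }
  if (!is.null(cfg$k_range) && length(cfg$k_range) == 0L)
    stop("empty k_range")
  grid <- expand.grid(linkage = c("complete", "average", "ward"),
                      criterion = c("cluster_silhouette", "silhouette",
                                    "wb_ratio"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    hc <- cluster_guilds(d, linkage = grid$linkage[i])
    m <- select_cutoff(hc, d, k_range = cfg$k_range,
                       criterion = grid$criterion[i])
    best <- m$trace[m$trace$k == m$k, ]
    data.frame(linkage = grid$linkage[i], criterion = grid$criterion[i],
               k = m$k, cluster_silhouette = best$cluster_silhouette,
               silhouette = best$silhouette, wb_ratio = best$wb_ratio)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(cfg$out_dir, "scan_clustering.csv"),
                     row.names = FALSE)
  }
  out
}
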