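.sub_seed <- function(seed, k) (as.integer(seed) + 7919L * as.integer(k)) %%
  .Machine$integer.max

#' Configuration of the synthetic community generator
#'
#' Defines the study conditions emulated by [make_traits()] and
#' [make_abundances()]: a colonization time series of sampling surfaces
#' whose species composition follows a quadratic-in-time log-linear
#' (softmax) model sampled multinomially, over a species pool organised in
#' planted functional guilds.  Defaults mirror the vent colonization study
#' design: 58 species in 12 guilds scored on the eight standard traits,
#' seven post-eruption recovery times (9-135 months) with 3-6 surfaces each
#' (30 in all), six pre-eruption reference blocks, and recovery
#' temperatures in the 1.9-6.5 degC analysis window.
#'
#' @param n_species,n_guilds species pool size and number of planted guilds.
#' @param trait_specs list of [trait_spec()] (default
#'   [default_trait_specs()]).
#' @param modality_flip_prob per-cell probability that a species' modality
#'   deviates from its guild template (ordered traits flip to an adjacent
#'   level; categorical traits to a uniform other level).
#' @param template_min_sep minimum pairwise Gower-Podani distance enforced
#'   between guild trait templates (rejection sampling).  Guilds are
#'   functional types, so their templates must be separated by more than
#'   the within-guild noise scale; 0.4 is comparable to the separation of
#'   the observed vent guilds.  Set to 0 for fully unconstrained templates
#'   (still forced distinct).
#' @param missing_prob per-cell probability of a missing modality.
#' @param times post-eruption recovery times in months.
#' @param surfaces_per_time surfaces recovered at each time (recycled).
#' @param individuals_mean Poisson mean of individuals per surface.
#' @param beta optional trend coefficients: matrix with columns
#'   (intercept, per-month, per-month^2) and one row per guild (recycled to
#'   species within guild) or per species; `NULL` draws guild-level
#'   coefficients from centred normals with `beta_sd`.
#' @param beta_sd standard deviations used to draw `beta` when `NULL`
#'   (intercept, linear, quadratic); the defaults give composition shifts
#'   of a few log-units across the 135-month series, comparable to the
#'   strong guild turnover seen in vent succession.
#' @param include_pre,n_pre_surfaces,pre_reference_months include
#'   pre-eruption reference blocks whose expected composition is the trend
#'   curve evaluated at `pre_reference_months` (a mature community ~85
#'   months after a prior eruption).
#' @param temp_range recovery-temperature window (degC) for simulated
#'   surfaces.
#' @param seed integer; every artifact of the generator is reproducible
#'   from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_species = 58L, n_guilds = 12L,
                         trait_specs = default_trait_specs(),
                         modality_flip_prob = 0.05, missing_prob = 0.03,
                         template_min_sep = 0.4,
                         times = c(9, 22, 33, 66, 96, 108, 135),
                         surfaces_per_time = c(6, 5, 4, 4, 4, 4, 3),
                         individuals_mean = 300,
                         beta = NULL, beta_sd = c(1, 0.02, 2e-4),
                         include_pre = TRUE, n_pre_surfaces = 6L,
                         pre_reference_months = 85,
                         temp_range = c(1.9, 6.5), seed = 1L) {
  stopifnot(n_species >= 2, n_guilds >= 1, n_guilds <= n_species,
            modality_flip_prob >= 0, modality_flip_prob <= 1,
            missing_prob >= 0, missing_prob <= 1,
            template_min_sep >= 0, template_min_sep <= 1,
            length(times) >= 2, all(times >= 0),
            all(surfaces_per_time >= 1), individuals_mean > 0,
            length(beta_sd) == 3, n_pre_surfaces >= 0,
            temp_range[1] <= temp_range[2])
  cfg <- list(n_species = as.integer(n_species),
              n_guilds = as.integer(n_guilds),
              trait_specs = .as_spec_list(trait_specs),
              modality_flip_prob = modality_flip_prob,
              missing_prob = missing_prob,
              template_min_sep = template_min_sep,
              times = as.numeric(times),
              surfaces_per_time = rep_len(as.integer(surfaces_per_time),
                                          length(times)),
              individuals_mean = individuals_mean,
              beta = beta, beta_sd = beta_sd,
              include_pre = isTRUE(include_pre),
              n_pre_surfaces = as.integer(n_pre_surfaces),
              pre_reference_months = pre_reference_months,
              temp_range = temp_range, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a trait table with planted guild structure
#'
#' Draws one random trait template per guild (templates forced distinct),
#' assigns species to guilds round-robin, and copies each guild template to
#' its member species with per-cell modality-flip noise and missing values.
#' Ordered traits flip to an adjacent level so the flip probability
#' controls ordinal distortion smoothly; categorical traits flip to a
#' uniformly chosen other level.  Each species keeps at least one
#' non-missing trait.
#'
#' @param config a [synth_config()].
#' @return `list(specs, table, guilds)` where `guilds` is the ground-truth
#'   species-to-guild factor.
#' @export
make_traits <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(.sub_seed(config$seed, 1L))
  specs <- config$trait_specs
  G <- config$n_guilds; S <- config$n_species
  draw_template <- function()
    vapply(specs, function(s) sample(s$levels, 1L), "")
  template_dist <- function(tm) {
    rownames(tm) <- sprintf("template_%02d", seq_len(nrow(tm)))
    gower_podani(trait_table(tm, specs), specs)$d
  }
  templates <- t(replicate(G, draw_template()))
  if (G > 1L) {
    # rejection sampling: templates must be mutually separated so the
    # planted guilds are real functional types, not sampling accidents
    for (tries in seq_len(10000L)) {
      dd <- template_dist(templates)
      diag(dd) <- Inf
      bad <- apply(dd, 1, min) < max(config$template_min_sep,
                                     .Machine$double.eps)
      if (!any(bad)) break
      # redraw the more crowded half of each offending set
      redraw <- which(bad & rank(apply(dd, 1, min), ties.method = "first") <=
                        ceiling(sum(bad) / 2))
      if (!length(redraw)) redraw <- which(bad)[1L]
      templates[redraw, ] <- t(vapply(redraw, function(i) draw_template(),
                                      character(length(specs))))
    }
    if (any(bad))
      stop("could not draw ", G, " guild templates separated by ",
           config$template_min_sep,
           "; lower 'template_min_sep' or 'n_guilds'")
  }
  guild <- rep_len(seq_len(G), S)  # round-robin assignment
  species <- sprintf("species_%02d", seq_len(S))
  a <- templates[guild, , drop = FALSE]
  rownames(a) <- species
  colnames(a) <- names(specs)
  for (j in seq_along(specs)) {
    s <- specs[[j]]
    flip <- stats::runif(S) < config$modality_flip_prob
    if (any(flip)) {
      if (s$kind == "ordered") {
        idx <- match(a[flip, j], s$levels)
        dir <- ifelse(idx == 1L, 1L,
                      ifelse(idx == length(s$levels), -1L,
                             sample(c(-1L, 1L), sum(flip), replace = TRUE)))
        a[flip, j] <- s$levels[idx + dir]
      } else {
        a[flip, j] <- vapply(a[flip, j], function(v)
          sample(setdiff(s$levels, v), 1L), "")
      }
    }
    miss <- stats::runif(S) < config$missing_prob
    a[miss, j] <- NA_character_
  }
  all_missing <- rowSums(!is.na(a)) == 0L
  if (any(all_missing)) {
    j <- sample.int(ncol(a), sum(all_missing), replace = TRUE)
    a[cbind(which(all_missing), j)] <- templates[cbind(guild[all_missing], j)]
  }
  truth <- factor(sprintf("g%02d", guild))
  names(truth) <- species
  list(specs = specs, table = trait_table(a, specs), guilds = truth)
}

.synth_beta <- function(config) {
  if (!is.null(config$beta)) {
    beta <- as.matrix(config$beta)
    if (ncol(beta) != 3) stop("'beta' must have 3 columns")
    if (nrow(beta) == config$n_guilds) {
      guild <- rep_len(seq_len(config$n_guilds), config$n_species)
      beta <- beta[guild, , drop = FALSE]
    } else if (nrow(beta) != config$n_species)
      stop("'beta' must have one row per guild or per species")
    return(beta)
  }
  bg <- cbind(stats::rnorm(config$n_guilds, 0, config$beta_sd[1]),
              stats::rnorm(config$n_guilds, 0, config$beta_sd[2]),
              stats::rnorm(config$n_guilds, 0, config$beta_sd[3]))
  guild <- rep_len(seq_len(config$n_guilds), config$n_species)
  bg[guild, , drop = FALSE]
}

#' Generate a colonization abundance time series
#'
#' Per-species expected relative abundances follow
#' \eqn{p(t) = softmax(\beta_0 + \beta_1 t + \beta_2 t^2)} — the exact
#' generative dual of the fitted multinomial model — and each surface draws
#' one multinomial sample of a Poisson number of individuals.  Recovery
#' temperatures are uniform in the configured window; optional pre-eruption
#' blocks use the trend curve at the reference age.
#'
#' @param config a [synth_config()].
#' @return An [abundance_table()]; the species-level coefficient matrix is
#'   attached as attribute `"beta"`.
#' @export
make_abundances <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(.sub_seed(config$seed, 2L))
  S <- config$n_species
  species <- sprintf("species_%02d", seq_len(S))
  beta <- .synth_beta(config)
  p_at <- function(t) {
    eta <- beta[, 1] + beta[, 2] * t + beta[, 3] * t^2
    eta <- eta - max(eta)
    exp(eta) / sum(exp(eta))
  }
  rows <- list(); meta <- list()
  i <- 0L
  for (ti in seq_along(config$times)) {
    t <- config$times[ti]
    p <- p_at(t)
    for (j in seq_len(config$surfaces_per_time[ti])) {
      i <- i + 1L
      n <- stats::rpois(1L, config$individuals_mean)
      rows[[i]] <- if (n > 0) as.vector(stats::rmultinom(1L, n, p))
                   else rep(0, S)
      meta[[i]] <- data.frame(
        sample_id = sprintf("post_%03dmo_s%d", round(t), j),
        surface_kind = "sandwich", epoch = "post_eruption",
        time_months = t,
        recovery_temp_C = round(stats::runif(1, config$temp_range[1],
                                             config$temp_range[2]), 1),
        deployment_months = round(stats::runif(1, 1.5, 48), 1),
        stringsAsFactors = FALSE)
    }
  }
  if (config$include_pre && config$n_pre_surfaces > 0) {
    p <- p_at(config$pre_reference_months)
    for (j in seq_len(config$n_pre_surfaces)) {
      i <- i + 1L
      n <- stats::rpois(1L, config$individuals_mean)
      rows[[i]] <- if (n > 0) as.vector(stats::rmultinom(1L, n, p))
                   else rep(0, S)
      meta[[i]] <- data.frame(
        sample_id = sprintf("pre_block_b%d", j),
        surface_kind = "block", epoch = "pre_eruption",
        time_months = NA_real_,
        recovery_temp_C = round(stats::runif(1, config$temp_range[1],
                                             config$temp_range[2]), 1),
        deployment_months = 37, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  samples <- do.call(rbind, meta)
  dimnames(counts) <- list(samples$sample_id, species)
  out <- abundance_table(counts, samples)
  attr(out, "beta") <- beta
  out
}

#' Write a complete synthetic fixture to disk
#'
#' Emits CSVs in the exact schemas read by [read_trait_table()] and
#' [read_abundance()] — `definitions.csv`, `modalities.csv` (long form),
#' `counts.csv` (long form, zeros included), `samples.csv` — plus a
#' ground-truth sidecar `truth.json` (planted guilds, trend coefficients,
#' seed).  Two runs with the same config are byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param config a [synth_config()].
#' @return Named character vector of the files written (invisibly); the
#'   generated objects are attached as attribute `"objects"`.
#' @export
write_fixture <- function(dir, config = synth_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- make_traits(config)
  ab <- make_abundances(config)
  paths <- c(definitions = file.path(dir, "definitions.csv"),
             modalities = file.path(dir, "modalities.csv"),
             counts = file.path(dir, "counts.csv"),
             samples = file.path(dir, "samples.csv"),
             truth = file.path(dir, "truth.json"))
  write_trait_table(tr$specs, tr$table, paths["definitions"],
                    paths["modalities"])
  write_abundance(ab, paths["counts"], paths["samples"])
  beta <- attr(ab, "beta")
  truth <- list(seed = config$seed,
                guilds = as.list(stats::setNames(as.character(tr$guilds),
                                                 names(tr$guilds))),
                beta = stats::setNames(
                  lapply(seq_len(nrow(beta)),
                         function(i) as.numeric(beta[i, ])),
                  tr$table$species))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  res <- invisible(paths)
  attr(res, "objects") <- list(specs = tr$specs, table = tr$table,
                               guilds = tr$guilds, abundance = ab)
  invisible(res)
}

#' Read a synthetic fixture back
#'
#' @param dir directory written by [write_fixture()].
#' @return `list(specs, table, abundance, truth)`.
#' @export
read_fixture <- function(dir) {
  tt <- read_trait_table(file.path(dir, "definitions.csv"),
                         file.path(dir, "modalities.csv"))
  ab <- read_abundance(file.path(dir, "counts.csv"),
                       metadata = file.path(dir, "samples.csv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path)
           else NULL
  list(specs = tt$specs, table = tt$table, abundance = ab, truth = truth)
}
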