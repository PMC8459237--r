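#' Planted-guild recovery experiment
#'
#' Repeatedly generates trait tables with planted guild structure, runs the
#' dissimilarity + clustering + cutoff-selection pipeline, and scores how
#' often the planted partition is recovered: the selected number of guilds
#' and the adjusted Rand index against the ground truth.
#'
#' @param n_seeds number of independent replicates; replicate i uses
#'   `config$seed + i - 1`.
#' @param config a [synth_config()]; its `n_guilds` is the target k.
#' @param linkage,criterion passed to [cluster_guilds()] /
#'   [select_cutoff()].
#' @return Data frame (seed, k_selected, ari) with attribute `"summary"`:
#'   the proportion of replicates with `k_selected == n_guilds`, with
#'   `ari >= 0.9`, and with both.
#' @export
guild_recovery_experiment <- function(n_seeds = 50L, config = synth_config(),
                                      linkage = "complete",
                                      criterion = "cluster_silhouette") {
  res <- lapply(seq_len(n_seeds), function(i) {
    cfg <- config
    cfg$seed <- .sub_seed(config$seed, 100L + i)
    tr <- make_traits(cfg)
    d <- gower_podani(tr$table, tr$specs)
    hc <- cluster_guilds(d, linkage = linkage)
    model <- select_cutoff(hc, d, criterion = criterion)
    data.frame(seed = cfg$seed, k_selected = model$k,
               ari = partition_agreement(model$labels, tr$guilds))
  })
  out <- do.call(rbind, res)
  attr(out, "summary") <- c(
    prop_k = mean(out$k_selected == config$n_guilds),
    prop_ari = mean(out$ari >= 0.9),
    prop_both = mean(out$k_selected == config$n_guilds & out$ari >= 0.9),
    mean_ari = mean(out$ari))
  out
}

#' Type-I error calibration of the randomization tests
#'
#' Simulates datasets with no temporal trend and measures how often each
#' randomization test rejects at level `alpha`.  For the deviance test each
#' dataset draws constant category probabilities (Dirichlet) and
#' per-surface multinomial counts of Poisson size at the study's surface
#' layout; for the \eqn{R^2} test each dataset is i.i.d. Gaussian noise at
#' the study time points.  Under the null the smoothed permutation p-value
#' is uniform on its achievable grid, so the expected rejection rate equals
#' `alpha` when `alpha * (n_rand + 1)` is an integer.
#'
#' @param n_datasets replicate datasets per test.
#' @param n_rand randomizations per dataset.
#' @param n_categories categories for the deviance-test generator.
#' @param times,surfaces_per_time,individuals_mean study layout.
#' @param alpha nominal level.
#' @param seed master seed.
#' @return List with the per-dataset smoothed p-values (`p_deviance`,
#'   `p_r2`) and rejection rates (`reject_deviance`, `reject_r2`).
#' @export
null_calibration <- function(n_datasets = 500L, n_rand = 199L,
                             n_categories = 4L,
                             times = c(9, 22, 33, 66, 96, 108, 135),
                             surfaces_per_time = c(6, 5, 4, 4, 4, 4, 3),
                             individuals_mean = 300, alpha = 0.05,
                             seed = 1L) {
  surfaces_per_time <- rep_len(surfaces_per_time, length(times))
  surf_times <- rep(times, surfaces_per_time)
  n_surf <- length(surf_times)
  set.seed(seed)
  dataset_seeds <- sample.int(2^28, 2L * n_datasets)
  p_dev <- numeric(n_datasets)
  p_r2 <- numeric(n_datasets)
  for (i in seq_len(n_datasets)) {
    set.seed(dataset_seeds[i])
    pr <- stats::rgamma(n_categories, 2)  # Dirichlet(2,...) null probabilities
    pr <- pr / sum(pr)
    n <- stats::rpois(n_surf, individuals_mean)
    counts <- t(vapply(n, function(ni)
      if (ni > 0) as.vector(stats::rmultinom(1, ni, pr))
      else rep(0, n_categories), numeric(n_categories)))
    colnames(counts) <- paste0("cat", seq_len(n_categories))
    rt <- suppressWarnings(randomization_test_deviance(
      counts, surf_times, n_rand = n_rand,
      seed = dataset_seeds[n_datasets + i], mode = "smoothed"))
    p_dev[i] <- rt$p_smoothed
    y <- stats::rnorm(length(times))
    r2 <- randomization_test_r2(y, times, n_rand = n_rand,
                                seed = dataset_seeds[n_datasets + i],
                                mode = "smoothed")
    p_r2[i] <- r2$p_smoothed
  }
  list(p_deviance = p_dev, p_r2 = p_r2,
       reject_deviance = mean(p_dev <= alpha),
       reject_r2 = mean(p_r2 <= alpha),
       alpha = alpha, n_datasets = n_datasets, n_rand = n_rand)
}
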