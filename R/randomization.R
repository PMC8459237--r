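.rand_test <- function(statistic, observed, null, n_rand, seed, mode,
                       smaller_is_extreme, n_not_converged = 0L) {
  # strict rule: printed convention (strict inequality, no add-one);
  # smoothed rule: add-one with inclusive ties, valid under degenerate ties
  if (smaller_is_extreme) {
    p_strict <- mean(null < observed)
    p_smoothed <- (1 + sum(null <= observed)) / (1 + n_rand)
  } else {
    p_strict <- mean(null > observed)
    p_smoothed <- (1 + sum(null >= observed)) / (1 + n_rand)
  }
  structure(list(statistic = statistic, observed = observed, null = null,
                 n_rand = n_rand, seed = seed, mode = mode,
                 p_strict = p_strict, p_smoothed = p_smoothed,
                 p_value = if (mode == "strict_paper") p_strict else p_smoothed,
                 tie_rule = if (mode == "strict_paper")
                   "strict inequality, ties count as non-extreme"
                 else "add-one smoothing, ties count as extreme",
                 n_not_converged = n_not_converged),
            class = "rand_test")
}

#' @export
print.rand_test <- function(x, ...) {
  cat(sprintf("randomization test (%s): observed %.4f, n_rand %d\n",
              x$statistic, x$observed, x$n_rand))
  cat(sprintf("  p (strict) = %.4g; p (smoothed) = %.4g [mode: %s]\n",
              x$p_strict, x$p_smoothed, x$mode))
  if (x$n_not_converged > 0)
    cat(sprintf("  %d randomized fits did not converge\n", x$n_not_converged))
  invisible(x)
}

#' Randomization test of a temporal trend in category composition
#'
#' Tests the quadratic-in-time multinomial model by randomization at the
#' sampling-surface level: the surface-to-time assignment is permuted
#' uniformly at random (observation times fixed), counts are re-pooled by
#' time, the model refitted and its deviance recorded.  A small observed
#' deviance relative to the null deviances indicates the quadratic trend
#' captures real temporal structure.  In `strict_paper` mode the p-value is
#' the proportion of randomizations whose deviance is strictly less than
#' the observed deviance; the default `smoothed` mode uses add-one
#' smoothing with inclusive ties, `p = (1 + #\{D <= D_obs\})/(1 + n_rand)`,
#' which cannot degenerate to 0 under ties.  Randomizing surfaces rather
#' than pooled counts keeps the test insensitive to extra-multinomial
#' variability from dependence between individuals on a surface.
#'
#' @param counts per-surface category counts (surface x category), e.g.
#'   from [modality_abundance()] or [guild_counts()] on an
#'   `abundance_table`.
#' @param times months since eruption, one per surface.
#' @param n_rand number of randomizations (study convention: 1000).
#' @param seed integer seed (randomization is reproducible given the seed).
#' @param mode `"smoothed"` (default) or `"strict_paper"`.
#' @param degree polynomial degree of the fitted trend.
#' @return A `rand_test` object with observed deviance, the null deviances
#'   and p-values under both tie rules.
#' @export
randomization_test_deviance <- function(counts, times, n_rand = 1000L,
                                        seed = NULL,
                                        mode = c("smoothed", "strict_paper"),
                                        degree = 2L) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (n_rand < 1L) stop("n_rand must be at least 1")
  if (length(times) != nrow(counts))
    stop("'times' must have one entry per surface")
  if (nrow(counts) < length(unique(times)))
    stop("fewer surfaces than time points")
  empty <- colSums(counts) == 0
  if (any(empty)) {
    warning("dropping categories empty in all surfaces: ",
            paste(colnames(counts)[empty], collapse = ", "))
    counts <- counts[, !empty, drop = FALSE]
  }
  if (ncol(counts) < 2L) stop("need at least 2 non-empty categories")
  if (!is.null(seed)) set.seed(seed)
  pool_fit <- function(tt) {
    pooled <- rowsum(counts, group = tt)
    fit_multinomial(pooled, as.numeric(rownames(pooled)), degree = degree)
  }
  obs_fit <- pool_fit(times)
  null <- numeric(n_rand)
  bad <- 0L
  n <- length(times)
  for (b in seq_len(n_rand)) {
    f <- pool_fit(times[sample.int(n)])
    null[b] <- f$deviance
    if (!f$converged) bad <- bad + 1L
  }
  out <- .rand_test("deviance", obs_fit$deviance, null, n_rand, seed, mode,
                    smaller_is_extreme = TRUE, n_not_converged = bad)
  out$fit <- obs_fit
  out
}

#' Quadratic ordinary least squares trend
#'
#' Fits `value ~ time + time^2` by OLS (via [stats::lm()]) and reports the
#' coefficient of determination \eqn{R^2 = 1 - SSE/SST} (defined as 0 for a
#' constant response).
#'
#' @param values response series (e.g. a diversity index per time point).
#' @param times months, one per value.
#' @return Object of class `ols_fit` with `coefficients`, `r_squared`,
#'   `fitted_values`, `residuals` and the underlying `lm` fit.
#' @export
fit_ols_quadratic <- function(values, times) {
  values <- as.numeric(values); times <- as.numeric(times)
  if (length(values) != length(times)) stop("length mismatch")
  if (length(unique(times)) < 3L)
    stop("need at least 3 distinct times for a quadratic fit")
  fit <- stats::lm(values ~ times + I(times^2))
  sst <- sum((values - mean(values))^2)
  sse <- sum(stats::residuals(fit)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  structure(list(coefficients = stats::coef(fit), r_squared = r2,
                 fitted_values = stats::fitted(fit),
                 residuals = stats::residuals(fit), lm = fit),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("quadratic OLS fit: R^2 = %.4f\n", x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' Randomization test of a quadratic trend in a series
#'
#' Permutes the response values against the fixed observation times and
#' compares the observed \eqn{R^2} of the quadratic OLS fit with the
#' permutation distribution.  `strict_paper` mode: p is the proportion of
#' randomizations whose \eqn{R^2} strictly exceeds the observed value;
#' `smoothed` mode (default) uses add-one smoothing with inclusive ties.
#'
#' @inheritParams randomization_test_deviance
#' @param values response series.
#' @return A `rand_test` object.
#' @export
randomization_test_r2 <- function(values, times, n_rand = 1000L, seed = NULL,
                                  mode = c("smoothed", "strict_paper")) {
  mode <- match.arg(mode)
  values <- as.numeric(values); times <- as.numeric(times)
  if (n_rand < 1L) stop("n_rand must be at least 1")
  if (length(values) != length(times)) stop("length mismatch")
  if (length(unique(times)) < 3L)
    stop("need at least 3 distinct times")
  if (!is.null(seed)) set.seed(seed)
  X <- cbind(1, times, times^2)
  qrX <- qr(X)
  r2_of <- function(Y) {
    res <- qr.resid(qrX, Y)
    sse <- colSums(res^2)
    sst <- colSums((Y - rep(colMeans(Y), each = nrow(Y)))^2)
    ifelse(sst > 0, 1 - sse / sst, 0)
  }
  obs <- r2_of(matrix(values, ncol = 1))
  perm <- replicate(n_rand, values[sample.int(length(values))])
  null <- r2_of(perm)
  .rand_test("R2", obs, null, n_rand, seed, mode,
             smaller_is_extreme = FALSE)
}

#' Temporal-trend report for traits, guilds and diversity indices
#'
#' Orchestrates the full inference stage: for every trait, per-surface
#' modality counts are tested for a quadratic-in-time trend with the
#' randomization-deviance test; the guild composition likewise; and each
#' diversity index (species Hill number, guild Hill number, Rao Q, plus
#' optionally Rao Q excluding listed outlier time points) is tested with the
#' randomization-\eqn{R^2} test on the pooled series.  Pre-eruption samples
#' are excluded from all regressions unless `pre_time_months` supplies a
#' time value for them.  Per-unit seeds are drawn deterministically from
#' `seed`.
#'
#' @param abund an [abundance_table()] (filtered and species-retained).
#' @param traits a [trait_table()].
#' @param specs list of [trait_spec()].
#' @param model a `guild_model`.
#' @param d the species `dissimilarity_matrix`.
#' @param n_rand,seed,mode randomization settings (see
#'   [randomization_test_deviance()]).
#' @param raoq_exclude_times time points (months) to exclude in an
#'   additional Rao Q test row, e.g. an early outlier.
#' @param pre_time_months optional time value at which pre-eruption samples
#'   enter the regressions; `NULL` (default) excludes them.
#' @return Data frame, one row per tested unit: `unit`, `statistic`,
#'   `observed`, `p_strict`, `p_smoothed`, `n_rand`, `seed`, `converged`,
#'   `note`.
#' @export
trend_report <- function(abund, traits, specs, model, d, n_rand = 1000L,
                         seed = 1L, mode = c("smoothed", "strict_paper"),
                         raoq_exclude_times = NULL, pre_time_months = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(abund, "abundance_table"))
  specs <- .as_spec_list(specs)
  pre <- abund$samples$epoch == "pre_eruption"
  if (!is.null(pre_time_months)) {
    abund$samples$time_months[pre] <- pre_time_months
    abund$samples$epoch[pre] <- "post_eruption"
  } else if (any(pre)) {
    keep <- !pre
    abund$samples <- abund$samples[keep, , drop = FALSE]
    abund$counts <- abund$counts[keep, , drop = FALSE]
  }
  times <- abund$samples$time_months
  units <- c(names(specs)[names(specs) %in% traits$traits], "guilds",
             "hill_species", "hill_guild", "raoq",
             if (!is.null(raoq_exclude_times))
               paste0("raoq_excl_", paste(raoq_exclude_times, collapse = "_")))
  set.seed(seed)
  unit_seeds <- sample.int(2^20, length(units))
  names(unit_seeds) <- units

  series <- pool_by_time(abund)
  div <- diversity_series(series, model, d)

  rows <- lapply(units, function(u) {
    us <- unit_seeds[[u]]
    row <- data.frame(unit = u, statistic = NA_character_,
                      observed = NA_real_, p_strict = NA_real_,
                      p_smoothed = NA_real_, n_rand = n_rand, seed = us,
                      converged = NA, note = NA_character_,
                      stringsAsFactors = FALSE)
    if (u %in% names(specs)) {
      cm <- modality_abundance(abund, traits, specs[[u]])
      if (sum(colSums(cm) > 0) < 2L) {
        row$note <- "skipped: fewer than 2 observed modalities"
        return(row)
      }
      rt <- suppressWarnings(
        randomization_test_deviance(cm, times, n_rand, seed = us, mode = mode))
      row$statistic <- "deviance"
      row$converged <- rt$fit$converged && rt$n_not_converged == 0L
    } else if (u == "guilds") {
      cm <- guild_counts(abund, model)
      if (sum(colSums(cm) > 0) < 2L) {
        row$note <- "skipped: fewer than 2 observed guilds"
        return(row)
      }
      rt <- suppressWarnings(
        randomization_test_deviance(cm, times, n_rand, seed = us, mode = mode))
      row$statistic <- "deviance"
      row$converged <- rt$fit$converged && rt$n_not_converged == 0L
    } else {
      metric <- if (startsWith(u, "raoq")) "raoq" else u
      dd <- div[!div$is_pre, , drop = FALSE]
      if (startsWith(u, "raoq_excl_"))
        dd <- dd[!dd$time_months %in% raoq_exclude_times, , drop = FALSE]
      rt <- randomization_test_r2(dd[[metric]], dd$time_months, n_rand,
                                  seed = us, mode = mode)
      row$statistic <- "R2"
      row$converged <- TRUE
    }
    row$observed <- rt$observed
    row$p_strict <- rt$p_strict
    row$p_smoothed <- rt$p_smoothed
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "master_seed") <- seed
  out
}
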