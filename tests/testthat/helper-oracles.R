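# Independent reference implementations used as oracles.  These are written
# as literal transcriptions of the definitions (explicit loops, counting
# ranks by hand) and deliberately share no code with the package.

# Gower coefficient with Podani's ordinal extension, pair by pair.
oracle_gower <- function(assign, specs, weights = NULL) {
  assign <- as.data.frame(assign, stringsAsFactors = FALSE)
  sp <- rownames(assign)
  S <- length(sp)
  trs <- colnames(assign)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(trs)), trs)
  D <- matrix(0, S, S, dimnames = list(sp, sp))
  defined <- matrix(TRUE, S, S, dimnames = list(sp, sp))
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (i == j) next
      num <- 0
      den <- 0
      for (tr in trs) {
        xi <- assign[i, tr]
        xj <- assign[j, tr]
        if (is.na(xi) || is.na(xj)) next
        s <- specs[[tr]]
        if (s$kind == "categorical") {
          delta <- if (xi == xj) 0 else 1
        } else if (xi == xj) {
          delta <- 0
        } else {
          obs <- assign[[tr]][!is.na(assign[[tr]])]
          pos <- match(obs, s$levels)
          # mid-rank of a value: (# strictly smaller) + (ties + 1)/2
          midrank <- function(x) {
            p <- match(x, s$levels)
            sum(pos < p) + (sum(pos == p) + 1) / 2
          }
          nties <- function(x) sum(pos == match(x, s$levels))
          lev_obs <- s$levels[s$levels %in% obs]
          lo <- lev_obs[1]
          hi <- lev_obs[length(lev_obs)]
          denom <- midrank(hi) - midrank(lo) -
            (nties(hi) - 1) / 2 - (nties(lo) - 1) / 2
          delta <- if (denom <= 0) 0 else
            (abs(midrank(xi) - midrank(xj)) -
               (nties(xi) - 1) / 2 - (nties(xj) - 1) / 2) / denom
        }
        num <- num + weights[[tr]] * delta
        den <- den + weights[[tr]]
      }
      if (den == 0) {
        defined[i, j] <- FALSE
        D[i, j] <- NA_real_
      } else D[i, j] <- num / den
    }
  }
  list(d = D, defined = defined)
}

# Naive O(n^3) agglomeration: returns the sorted merge heights.
oracle_linkage_heights <- function(dmat, method = c("complete", "average")) {
  method <- match.arg(method)
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best_h <- Inf
    best <- c(NA, NA)
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in seq(a + 1L, length(clusters))) {
        vals <- dmat[clusters[[a]], clusters[[b]]]
        h <- if (method == "complete") max(vals) else mean(vals)
        if (h < best_h) {
          best_h <- h
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Shannon entropy summed term by term; Rao Q as an explicit double loop.
oracle_hill1 <- function(x) {
  total <- sum(x)
  acc <- 0
  for (xi in x) {
    if (xi > 0) {
      p <- xi / total
      acc <- acc - p * log(p)
    }
  }
  exp(acc)
}

oracle_raoq <- function(x, dmat) {
  p <- unname(x) / sum(x)
  acc <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      acc <- acc + dmat[i, j] * p[i] * p[j]
    }
  }
  acc
}

# Quadratic OLS by the normal equations.
oracle_ols_quadratic <- function(y, t) {
  X <- cbind(1, t, t^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit <- X %*% beta
  sse <- sum((y - fit)^2)
  sst <- sum((y - mean(y))^2)
  list(coefficients = as.vector(beta),
       r_squared = if (sst > 0) 1 - sse / sst else 0)
}

# Multinomial log-likelihood for month-scale coefficients, coded directly.
oracle_multinom_loglik <- function(coefs, baseline, Y, times) {
  K <- ncol(Y)
  cats <- colnames(Y)
  b <- match(baseline, cats)
  ll <- 0
  for (t in seq_along(times)) {
    eta <- numeric(K)
    for (k in seq_len(K)) {
      if (k == b) next
      ck <- coefs[, match(cats[k], colnames(coefs))]
      eta[k] <- ck[1] + ck[2] * times[t] + ck[3] * times[t]^2
    }
    p <- exp(eta - max(eta))
    p <- p / sum(p)
    ll <- ll + sum(Y[t, Y[t, ] > 0] * log(p[Y[t, ] > 0]))
  }
  ll
}

# Small random trait table for property-style tests.
random_trait_table <- function(n_species, specs, missing_prob = 0.15) {
  a <- vapply(specs, function(s) sample(s$levels, n_species, replace = TRUE),
              character(n_species))
  a <- matrix(a, nrow = n_species,
              dimnames = list(sprintf("sp%02d", seq_len(n_species)),
                              names(specs)))
  miss <- matrix(stats::runif(length(a)) < missing_prob, nrow = n_species)
  # keep one guaranteed non-missing trait per species
  miss[cbind(seq_len(n_species),
             sample.int(ncol(a), n_species, replace = TRUE))] <- FALSE
  a[miss] <- NA_character_
  trait_table(a, specs)
}

# Mixed ordered/categorical specs for small fixtures.
toy_specs <- function() {
  list(size = trait_spec("size", "ordered", c("s", "m", "l", "xl")),
       colour = trait_spec("colour", "categorical", c("red", "green", "blue")),
       mobility = trait_spec("mobility", "ordered", c("low", "mid", "high")))
}

toy_abundance <- function() {
  counts <- rbind(
    a1 = c(3, 0, 2), a2 = c(2, 5, 0),
    b1 = c(1, 1, 1), b2 = c(0, 4, 4),
    pre1 = c(2, 2, 2))
  colnames(counts) <- c("sp1", "sp2", "sp3")
  samples <- data.frame(
    sample_id = rownames(counts),
    surface_kind = c(rep("sandwich", 4), "block"),
    epoch = c(rep("post_eruption", 4), "pre_eruption"),
    time_months = c(9, 9, 22, 22, NA),
    recovery_temp_C = c(2.0, 3.5, 5.0, 6.5, 1.9),
    deployment_months = c(6, 6, 12, 12, 37))
  abundance_table(counts, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Multinomial counts from month-scale coefficients (baseline = first column).
.sim_counts <- function(beta, times, n_per_time) {
  K <- ncol(beta) + 1
  eta <- cbind(0, cbind(1, times, times^2) %*% beta)
  P <- exp(eta - apply(eta, 1, max))
  P <- P / rowSums(P)
  Y <- t(vapply(seq_along(times), function(t)
    as.vector(stats::rmultinom(1, n_per_time, P[t, ])), numeric(K)))
  colnames(Y) <- paste0("c", seq_len(K))
  list(Y = Y, P = P)
}
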