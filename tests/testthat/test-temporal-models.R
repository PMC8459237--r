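test_that("no-signal data yields zero slopes and pooled proportions", {
  times <- c(9, 22, 33, 66, 96, 108, 135)
  Y <- cbind(c1 = rep(30, 7), c2 = rep(70, 7))
  f <- fit_multinomial(Y, times)
  expect_true(f$converged)
  expect_lt(max(abs(f$coefficients[c("time", "time^2"), ])), 1e-6)
  expect_equal(unname(f$fitted[, "c1"]), rep(0.3, 7), tolerance = 1e-6)
  expect_equal(f$deviance, 0, tolerance = 1e-8)
})

test_that("with 3 distinct times the quadratic model saturates exactly", {
  # T = 3, K = 3: 6 free parameters = 6 saturated degrees of freedom,
  # so the ML fit must reproduce the observed proportions
  times <- c(9, 22, 33)
  set.seed(701)
  Y <- matrix(rpois(9, 15) + 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  f <- fit_multinomial(Y, times)
  expect_true(f$converged)
  expect_equal(f$fitted, Y / rowSums(Y), ignore_attr = TRUE,
               tolerance = 1e-7)
  expect_equal(f$deviance, 0, tolerance = 1e-4)
})

test_that("maximized likelihood matches independent optimizers", {
  times <- c(9, 22, 33, 96)
  set.seed(702)
  Y <- matrix(rpois(12, 12) + 1, 4, dimnames = list(NULL, c("a", "b", "c")))
  f <- fit_multinomial(Y, times)
  # oracle 1: general-purpose optimizer on an independently coded likelihood
  t1 <- times; t2 <- times^2
  z1 <- (t1 - mean(t1)) / sd(t1); z2 <- (t2 - mean(t2)) / sd(t2)
  nll <- function(theta) {
    B <- matrix(theta, 3, 2)
    eta <- cbind(0, cbind(1, z1, z2) %*% B)
    -sum(Y * (eta - log(rowSums(exp(eta)))))
  }
  o <- optim(rep(0, 6), nll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(f$loglik, -o$value, tolerance = 1e-4)
  # the reported month-scale coefficients reproduce the same likelihood
  expect_equal(oracle_multinom_loglik(f$coefficients, f$baseline, Y, times),
               f$loglik, tolerance = 1e-6)
  # oracle 2: nnet::multinom on the same counts
  skip_if_not_installed("nnet")
  nf <- nnet::multinom(Y ~ z1 + z2, trace = FALSE, maxit = 1000,
                       reltol = 1e-14)
  expect_equal(f$loglik, -nf$value, tolerance = 1e-4)
})

test_that("planted coefficients are recovered at large counts", {
  times <- c(9, 22, 33, 66, 96, 108, 135)
  beta <- rbind(c(0.5, -0.4), c(0.02, -0.015), c(-1.2e-4, 1.0e-4))
  set.seed(703)
  sim <- .sim_counts(beta, times, n_per_time = 1e5)
  f <- fit_multinomial(sim$Y, times, baseline = "c1")
  expect_true(f$converged)
  # observed information gives the Monte Carlo scale; use a generous
  # 3-standard-error band via repeated simulation
  reps <- replicate(30, {
    s <- .sim_counts(beta, times, n_per_time = 1e5)
    as.vector(fit_multinomial(s$Y, times, baseline = "c1")$coefficients)
  })
  se <- apply(reps, 1, sd)
  est <- as.vector(f$coefficients)
  expect_true(all(abs(est - as.vector(beta)) <= 3 * se + 1e-12))
})

test_that("fits are invariant to the baseline category", {
  times <- c(9, 22, 33, 66, 96)
  set.seed(704)
  Y <- matrix(rpois(20, 40) + 1, 5, dimnames = list(NULL, letters[1:4]))
  fits <- lapply(letters[1:4], function(b)
    fit_multinomial(Y, times, baseline = b))
  for (f in fits[-1]) {
    expect_equal(f$fitted, fits[[1]]$fitted, tolerance = 1e-8)
    expect_equal(f$deviance, fits[[1]]$deviance, tolerance = 1e-8)
  }
})

test_that("deviance decreases from intercept-only to linear to quadratic", {
  times <- c(9, 22, 33, 66, 96, 108, 135)
  set.seed(705)
  for (rep in 1:5) {
    Y <- matrix(rpois(21, 25) + 1, 7, dimnames = list(NULL, c("a", "b", "c")))
    d0 <- fit_multinomial(Y, times, degree = 0)$deviance
    d1 <- fit_multinomial(Y, times, degree = 1)$deviance
    d2 <- fit_multinomial(Y, times, degree = 2)$deviance
    expect_lte(d1, d0 + 1e-6)
    expect_lte(d2, d1 + 1e-6)
    expect_gte(d2, -1e-6)
  }
})

test_that("degenerate multinomial inputs are rejected informatively", {
  expect_error(fit_multinomial(matrix(1:4, 2), c(1, 2)),
               "unidentifiable")
  expect_error(fit_multinomial(matrix(5, 1, 2), 1), "unidentifiable")
  Y <- matrix(c(1, 2, 3, 0, 0, 0), 3)
  expect_warning(expect_error(fit_multinomial(Y, c(1, 2, 3)), "2 non-empty"),
                 "empty")
})

test_that("quadratic OLS matches the normal-equations oracle", {
  t7 <- c(9, 22, 33, 66, 96, 108, 135)
  set.seed(706)
  y <- 2 + 0.1 * t7 - 5e-4 * t7^2 + rnorm(7, 0, 0.3)
  f <- fit_ols_quadratic(y, t7)
  orc <- oracle_ols_quadratic(y, t7)
  expect_equal(unname(f$coefficients), orc$coefficients, tolerance = 1e-9)
  expect_equal(f$r_squared, orc$r_squared, tolerance = 1e-12)
  # residual orthogonality to the design
  X <- cbind(1, t7, t7^2)
  expect_lt(max(abs(t(X) %*% f$residuals)), 1e-7)
  # exact parabola and constant response
  expect_equal(fit_ols_quadratic(1 + t7 - 0.01 * t7^2, t7)$r_squared, 1)
  expect_equal(fit_ols_quadratic(rep(3, 7), t7)$r_squared, 0)
})

test_that("permutation-invariant data exposes the two tie rules", {
  # all surfaces identical in composition: every randomized deviance equals
  # the observed one
  counts <- matrix(rep(c(10, 20), each = 8), 8,
                   dimnames = list(NULL, c("a", "b")))
  times <- rep(c(9, 22, 33, 66), 2)
  rt <- randomization_test_deviance(counts, times, n_rand = 99, seed = 1)
  expect_equal(rt$p_strict, 0)
  expect_equal(rt$p_smoothed, 1)
  # perfect parabola: no permutation can match the fit
  t7 <- c(9, 22, 33, 66, 96, 108, 135)
  y <- 1 + 0.2 * t7 - 1e-3 * t7^2
  r2 <- randomization_test_r2(y, t7, n_rand = 99, seed = 1)
  expect_equal(r2$observed, 1)
  expect_equal(r2$p_strict, 0)
  expect_equal(r2$p_smoothed, 1 / 100)
})

test_that("randomization tests are reproducible and seed-sensitive", {
  set.seed(707)
  counts <- matrix(rpois(32, 30), 8, dimnames = list(NULL, letters[1:4]))
  times <- rep(c(9, 22, 33, 66), 2)
  a <- randomization_test_deviance(counts, times, n_rand = 59, seed = 42)
  b <- randomization_test_deviance(counts, times, n_rand = 59, seed = 42)
  expect_identical(a$null, b$null)
  expect_identical(a$p_smoothed, b$p_smoothed)
  y <- rnorm(4)
  r1 <- randomization_test_r2(y, c(9, 22, 33, 66), n_rand = 59, seed = 42)
  r2 <- randomization_test_r2(y, c(9, 22, 33, 66), n_rand = 59, seed = 42)
  expect_identical(r1$null, r2$null)
})

test_that("permutation p-values are invariant to relabeling and time rescaling", {
  set.seed(708)
  counts <- matrix(rpois(32, 30), 8, dimnames = list(NULL, letters[1:4]))
  times <- rep(c(9, 22, 33, 66), 2)
  a <- randomization_test_deviance(counts, times, n_rand = 49, seed = 9)
  # category relabeling: permute columns
  b <- randomization_test_deviance(counts[, c(3, 1, 4, 2)], times,
                                   n_rand = 49, seed = 9)
  expect_equal(a$null, b$null, tolerance = 1e-7)
  expect_equal(a$p_smoothed, b$p_smoothed)
  # affine rescaling of the time axis spans the same model space
  c_ <- randomization_test_deviance(counts, times * 2 + 5, n_rand = 49,
                                    seed = 9)
  expect_equal(a$null, c_$null, tolerance = 1e-6)
  expect_equal(a$observed, c_$observed, tolerance = 1e-8)
})

test_that("a strong planted quadratic trend is detected with small p", {
  times <- c(9, 22, 33, 66, 96, 108, 135)
  beta <- rbind(c(1, -1), c(-0.06, 0.05), c(3e-4, -2.5e-4))
  set.seed(709)
  hits <- vapply(1:20, function(i) {
    surf_times <- rep(times, each = 4)
    K <- 3
    eta <- cbind(0, cbind(1, surf_times, surf_times^2) %*% beta)
    P <- exp(eta - apply(eta, 1, max)); P <- P / rowSums(P)
    counts <- t(vapply(seq_along(surf_times), function(s)
      as.vector(rmultinom(1, 250, P[s, ])), numeric(K)))
    colnames(counts) <- paste0("c", 1:K)
    rt <- randomization_test_deviance(counts, surf_times, n_rand = 199,
                                      seed = 1000 + i)
    rt$p_smoothed <= 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("trend_report covers traits, guilds and diversity with sane schema", {
  cfg <- synth_config(n_species = 12, n_guilds = 3, seed = 71,
                      individuals_mean = 150)
  tr <- make_traits(cfg)
  ab <- make_abundances(cfg)
  d <- gower_podani(tr$table, tr$specs)
  hc <- cluster_guilds(d)
  model <- select_cutoff(hc, d)
  rep <- trend_report(ab, tr$table, tr$specs, model, d, n_rand = 29,
                      seed = 5, raoq_exclude_times = 9)
  expect_setequal(rep$unit, c(names(tr$specs), "guilds", "hill_species",
                              "hill_guild", "raoq", "raoq_excl_9"))
  expect_true(all(rep$statistic %in% c("deviance", "R2") | !is.na(rep$note)))
  ok <- is.na(rep$note)
  expect_true(all(rep$p_strict[ok] >= 0 & rep$p_strict[ok] <= 1))
  expect_true(all(rep$p_smoothed[ok] > 0 & rep$p_smoothed[ok] <= 1))
  # reproducible under the same master seed
  rep2 <- trend_report(ab, tr$table, tr$specs, model, d, n_rand = 29,
                       seed = 5, raoq_exclude_times = 9)
  expect_identical(rep, rep2)
  # single-category unit is skipped with a reason
  specs1 <- list(mono = trait_spec("mono", "categorical", "only"))
  a1 <- data.frame(mono = rep("only", 12),
                   row.names = tr$table$species)
  tt1 <- trait_table(a1, specs1)
  rep3 <- trend_report(ab, tt1, specs1, model, d, n_rand = 9, seed = 5)
  expect_match(rep3$note[rep3$unit == "mono"], "fewer than 2")
})
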