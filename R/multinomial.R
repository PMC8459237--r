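# Core Newton maximizer for the baseline-category multinomial logistic
# likelihood.  Y: T x K counts; X: T x p design.  Parameters are one
# p-vector per non-baseline category (theta = vec(B), columns = categories).
# The Fisher information is assembled from t-wise kronecker blocks; a small
# ridge is added if the solve fails (quasi-separation); step halving guards
# the ascent.
.mfit <- function(Y, X, baseline = NULL, tol = 1e-10, max_iter = 100L) {
  Tn <- nrow(Y); K <- ncol(Y); p <- ncol(X)
  N <- rowSums(Y); Ntot <- sum(Y)
  if (is.null(baseline)) baseline <- which.max(colSums(Y))
  ks <- setdiff(seq_len(K), baseline)
  softmax_p <- function(B) {
    E <- matrix(0, Tn, K)
    E[, ks] <- X %*% B
    E <- E - apply(E, 1, max)
    W <- exp(E)
    W / rowSums(W)
  }
  ll_fun <- function(P) sum(Y[Y > 0] * log(P[Y > 0]))
  B <- matrix(0, p, K - 1L)
  tot <- colSums(Y)
  B[1L, ] <- log((tot[ks] + 0.5) / (tot[baseline] + 0.5))
  P <- softmax_p(B)
  ll <- ll_fun(P)
  converged <- FALSE
  it <- 0L
  ridged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    G <- crossprod(X, Y[, ks, drop = FALSE] - N * P[, ks, drop = FALSE])
    g <- as.vector(G)
    if (max(abs(g)) < tol * max(1, Ntot)) { converged <- TRUE; break }
    H <- matrix(0, p * (K - 1L), p * (K - 1L))
    for (t in seq_len(Tn)) {
      pt <- P[t, ks]
      M <- N[t] * (diag(pt, K - 1L) - tcrossprod(pt))
      H <- H + kronecker(M, tcrossprod(X[t, ]))
    }
    step <- tryCatch(solve(H, g), error = function(e) {
      ridged <<- TRUE
      solve(H + diag(1e-8 * max(1, max(abs(diag(H)))), nrow(H)), g)
    })
    step <- matrix(step, p, K - 1L)
    lam <- 1
    repeat {
      Bn <- B + lam * step
      Pn <- softmax_p(Bn)
      lln <- ll_fun(Pn)
      if (is.finite(lln) && lln >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { Bn <- B; Pn <- P; lln <- ll; break }
    }
    if (lln <= ll && lam < 1e-8) break  # no ascent possible
    B <- Bn; P <- Pn; ll <- lln
  }
  list(B = B, baseline = baseline, ks = ks, P = P, loglik = ll,
       converged = converged, iterations = it, ridged = ridged)
}

.loglik_saturated <- function(Y) {
  N <- rowSums(Y)
  pos <- Y > 0
  sum(Y[pos] * log((Y / N)[pos]))
}

#' Quadratic-in-time multinomial logistic regression
#'
#' Fits, by maximum likelihood, the baseline-category multinomial model in
#' which the log relative abundance of each category against a baseline is
#' quadratic in time:
#' \deqn{\log(p_k(t)/p_{b}(t)) = \beta_{0k} + \beta_{1k} t + \beta_{2k} t^2.}
#' Counts at each time point are treated as one multinomial draw.  Time and
#' time-squared are centred and scaled internally for conditioning; the
#' returned coefficients are on the month scale.  The deviance is
#' \eqn{2(\ell_{sat} - \ell)} against the saturated model with free
#' per-time probabilities.
#'
#' @param counts matrix (time point x category) of non-negative counts;
#'   categories empty at every time are dropped with a warning.
#' @param times observation times (months), one per row.
#' @param baseline baseline category name; default the most abundant
#'   overall (fitted probabilities and deviance do not depend on the
#'   choice).
#' @param degree polynomial degree in time (2 = quadratic default; 0 and 1
#'   are available for nested-model diagnostics).
#' @return Object of class `multinomial_fit`: `coefficients`
#'   ((degree+1) x K-1, month scale), `fitted` (T x K probabilities),
#'   `deviance`, `loglik`, `loglik_saturated`, `converged`, `diagnostics`.
#' @export
fit_multinomial <- function(counts, times, baseline = NULL, degree = 2L) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cat", seq_len(ncol(counts)))
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (length(times) != nrow(counts))
    stop("'times' must have one entry per row of 'counts'")
  empty <- colSums(counts) == 0
  if (any(empty)) {
    warning("dropping categories empty at all times: ",
            paste(colnames(counts)[empty], collapse = ", "))
    counts <- counts[, !empty, drop = FALSE]
  }
  K <- ncol(counts)
  if (K < 2L) stop("need at least 2 non-empty categories")
  degree <- as.integer(degree)
  if (degree < 0L || degree > 2L) stop("degree must be 0, 1 or 2")
  if (length(unique(times)) < degree + 1L)
    stop("need at least ", degree + 1L,
         " distinct times: polynomial trend unidentifiable")
  if (degree == 2L && length(unique(times)) < 3L)
    stop("quadratic trend unidentifiable with fewer than 3 distinct times")
  t1 <- as.numeric(times); t2 <- t1^2
  sd0 <- function(v) if (stats::sd(v) > 0) stats::sd(v) else 1
  m1 <- mean(t1); s1 <- sd0(t1)
  m2 <- mean(t2); s2 <- sd0(t2)
  X <- cbind(1, (t1 - m1) / s1, (t2 - m2) / s2)[, seq_len(degree + 1L),
                                                drop = FALSE]
  if (!is.null(baseline)) {
    baseline <- match(baseline, colnames(counts))
    if (is.na(baseline)) stop("unknown baseline category")
  }
  fit <- .mfit(counts, X, baseline = baseline)
  # map scaled-basis coefficients back to the month scale
  B <- fit$B
  coefs <- matrix(0, 3, K - 1L)
  coefs[1, ] <- B[1, ]
  if (degree >= 1L) {
    coefs[1, ] <- coefs[1, ] - B[2, ] * m1 / s1
    coefs[2, ] <- B[2, ] / s1
  }
  if (degree == 2L) {
    coefs[1, ] <- coefs[1, ] - B[3, ] * m2 / s2
    coefs[3, ] <- B[3, ] / s2
  }
  coefs <- coefs[seq_len(degree + 1L), , drop = FALSE]
  dimnames(coefs) <- list(c("(Intercept)", "time", "time^2")[seq_len(degree + 1L)],
                          colnames(counts)[fit$ks])
  ll_sat <- .loglik_saturated(counts)
  P <- fit$P
  dimnames(P) <- list(rownames(counts), colnames(counts))
  single <- colnames(counts)[colSums(counts > 0) == 1L]
  diagnostics <- if (!fit$converged && length(single))
    paste0("possible separation: categories observed at a single time: ",
           paste(single, collapse = ", "))
  else if (!fit$converged) "did not reach gradient tolerance"
  else NA_character_
  structure(list(categories = colnames(counts),
                 baseline = colnames(counts)[fit$baseline],
                 coefficients = coefs, fitted = P,
                 deviance = 2 * (ll_sat - fit$loglik),
                 loglik = fit$loglik, loglik_saturated = ll_sat,
                 converged = fit$converged, iterations = fit$iterations,
                 degree = degree, times = t1, counts = counts,
                 diagnostics = diagnostics),
            class = "multinomial_fit")
}

#' @export
print.multinomial_fit <- function(x, ...) {
  cat(sprintf(
    "multinomial_fit: %d categories (baseline '%s'), %d times, degree %d\n",
    length(x$categories), x$baseline, nrow(x$fitted), x$degree))
  cat(sprintf("  deviance %.4f; %sconverged in %d iterations\n",
              x$deviance, if (x$converged) "" else "NOT ", x$iterations))
  print(x$coefficients)
  invisible(x)
}

#' Predicted category probabilities
#'
#' @param object a `multinomial_fit`.
#' @param times months at which to evaluate the fitted relative-abundance
#'   curves (default: the observed times).
#' @param ... unused.
#' @return Matrix (time x category) of probabilities summing to 1 by row.
#' @export
predict.multinomial_fit <- function(object, times = object$times, ...) {
  t1 <- as.numeric(times)
  Xm <- cbind(1, t1, t1^2)[, seq_len(object$degree + 1L), drop = FALSE]
  K <- length(object$categories)
  b <- match(object$baseline, object$categories)
  E <- matrix(0, length(t1), K)
  E[, -b] <- Xm %*% object$coefficients
  E <- E - apply(E, 1, max)
  W <- exp(E)
  P <- W / rowSums(W)
  dimnames(P) <- list(as.character(times), object$categories)
  P
}
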