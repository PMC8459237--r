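#' Gower dissimilarity with Podani's ordinal extension
#'
#' Pairwise species dissimilarity over mixed categorical/ordered traits with
#' missing values.  For species i, j:
#' \deqn{d_{ij} = \sum_k w_{ijk}\delta_{ijk} / \sum_k w_{ijk}}
#' where \eqn{w_{ijk}} is the trait weight when both species have a
#' non-missing value for trait k and 0 otherwise.  Categorical traits score
#' \eqn{\delta = 0} on agreement, 1 on disagreement.  Ordered traits use
#' Podani's (1999) tie-corrected rank scoring: levels are converted to
#' mid-ranks r over the species observed for the trait, and for unequal
#' values
#' \deqn{\delta_{ijk} = \frac{|r_{ik}-r_{jk}| - (T_{ik}-1)/2 - (T_{jk}-1)/2}
#'                           {r_{max}-r_{min} - (T_{max}-1)/2 - (T_{min}-1)/2}}
#' with \eqn{T_x} the number of species tied at the rank of x and the
#' denominator using the tie counts at the extreme ranks; equal values score
#' 0, as does any trait on which all observed species are tied (a zero
#' denominator), while still contributing weight.
#'
#' Ranks are computed over the species actually present, not over the
#' declared level set; set `rank_over_levels = TRUE` to rank over declared
#' levels instead.
#'
#' @param traits a [trait_table()].
#' @param specs list of [trait_spec()] covering the table's traits.
#' @param weights non-negative per-trait weights (named or in trait order);
#'   default equal.
#' @param rank_over_levels rank ordered traits over their declared levels
#'   rather than the observed values.
#' @return Object of class `dissimilarity_matrix`: `taxa`, `d` (symmetric,
#'   values in \[0,1\], zero diagonal, `NA` for undefined pairs) and
#'   `defined_pairs` (logical mask; a pair is undefined when the two species
#'   share no non-missing trait).
#' @references Gower, J.C. (1971) Biometrics 27:857-871.  Podani, J. (1999)
#'   Taxon 48:331-340.
#' @export
gower_podani <- function(traits, specs, weights = NULL,
                         rank_over_levels = FALSE) {
  stopifnot(inherits(traits, "trait_table"))
  specs <- .as_spec_list(specs)
  missing_specs <- setdiff(traits$traits, names(specs))
  if (length(missing_specs))
    stop("no trait_spec for: ", paste(missing_specs, collapse = ", "))
  trs <- traits$traits
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(trs)), trs)
  if (is.null(names(weights))) names(weights) <- trs
  if (any(weights < 0) || any(is.na(weights)))
    stop("weights must be non-negative")
  weights <- weights[trs]

  S <- length(traits$species)
  num <- matrix(0, S, S)
  den <- matrix(0, S, S)
  for (tr in trs) {
    w <- weights[[tr]]
    if (w == 0) next
    spec <- specs[[tr]]
    v <- traits$assignment[[tr]]
    obs <- !is.na(v)
    if (!any(obs)) next
    mask <- outer(obs, obs, "&")
    delta <- matrix(0, S, S)
    if (spec$kind == "categorical") {
      delta[mask] <- outer(v, v, "!=")[mask]
    } else {
      idx <- match(v, spec$levels)
      if (rank_over_levels) {
        # ranks over the declared level set: each level a distinct rank
        r <- as.numeric(idx)
        tie <- rep(1, S)
        rmax <- length(spec$levels); rmin <- 1
        tmax <- 1; tmin <- 1
      } else {
        r <- rep(NA_real_, S)
        r[obs] <- rank(idx[obs], ties.method = "average")
        tab <- table(r[obs])
        tie <- rep(NA_real_, S)
        tie[obs] <- as.numeric(tab[as.character(r[obs])])
        rmax <- max(r[obs]); rmin <- min(r[obs])
        tmax <- tie[obs][which.max(r[obs])]
        tmin <- tie[obs][which.min(r[obs])]
      }
      denom <- rmax - rmin - (tmax - 1) / 2 - (tmin - 1) / 2
      if (denom > 0) {
        dmat <- (abs(outer(r, r, "-")) -
                   outer((tie - 1) / 2, (tie - 1) / 2, "+")) / denom
        eq <- outer(idx, idx, "==")
        eq[is.na(eq)] <- FALSE
        dmat[eq] <- 0  # equal values: maximally similar
        delta[mask] <- dmat[mask]
      }
    }
    num <- num + w * delta * mask
    den <- den + w * mask
  }
  defined <- den > 0
  d <- ifelse(defined, num / pmax(den, .Machine$double.eps), NA_real_)
  diag(d) <- 0
  diag(defined) <- TRUE
  dimnames(d) <- list(traits$species, traits$species)
  dimnames(defined) <- dimnames(d)
  structure(list(taxa = traits$species, d = d, defined_pairs = defined),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat(sprintf(
    "dissimilarity_matrix: %d taxa; off-diagonal range [%.3f, %.3f], mean %.3f; %d undefined pairs\n",
    length(x$taxa), min(off, na.rm = TRUE), max(off, na.rm = TRUE),
    mean(off, na.rm = TRUE), sum(!x$defined_pairs[upper.tri(x$d)])))
  invisible(x)
}

.as_dissim <- function(m) {
  if (inherits(m, "dissimilarity_matrix")) return(m)
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  structure(list(taxa = rownames(m), d = m, defined_pairs = !is.na(m)),
            class = "dissimilarity_matrix")
}

#' Validate a dissimilarity matrix
#'
#' Asserts symmetry, a zero diagonal, the \[0,1\] range, and flags undefined
#' pairs; reports simple summary statistics of the off-diagonal values.
#'
#' @param m a `dissimilarity_matrix` (or a plain square matrix).
#' @return Object of class `dissim_report` with elements `ok`, `problems`
#'   (character, naming offending pairs), `warnings` and `stats`.
#' @export
validate_matrix <- function(m) {
  m <- .as_dissim(m)
  d <- m$d
  problems <- character(0)
  warns <- character(0)
  if (nrow(d) != ncol(d)) problems <- c(problems, "matrix not square")
  bad_sym <- which(abs(d - t(d)) > 1e-12 |
                     (is.na(d) != is.na(t(d))), arr.ind = TRUE)
  if (nrow(bad_sym)) {
    i <- bad_sym[1, 1]; j <- bad_sym[1, 2]
    problems <- c(problems, sprintf("asymmetric at pair (%s, %s)",
                                    m$taxa[i], m$taxa[j]))
  }
  if (any(abs(diag(d)) > 1e-12, na.rm = TRUE) || anyNA(diag(d)))
    problems <- c(problems, "nonzero or missing diagonal")
  off <- d[upper.tri(d)]
  if (any(off < -1e-12 | off > 1 + 1e-12, na.rm = TRUE))
    problems <- c(problems, "values outside [0, 1]")
  undef <- which(!m$defined_pairs & upper.tri(d), arr.ind = TRUE)
  if (nrow(undef))
    warns <- c(warns, sprintf("%d undefined pairs (no shared non-missing trait), e.g. (%s, %s)",
                              nrow(undef), m$taxa[undef[1, 1]],
                              m$taxa[undef[1, 2]]))
  if (length(off) && any(!is.na(off)) && all(abs(off) < 1e-12, na.rm = TRUE))
    warns <- c(warns, "no trait variation: all dissimilarities are zero")
  stats <- c(min = suppressWarnings(min(off, na.rm = TRUE)),
             max = suppressWarnings(max(off, na.rm = TRUE)),
             mean = mean(off, na.rm = TRUE))
  out <- structure(list(ok = length(problems) == 0L, problems = problems,
                        warnings = warns, stats = stats,
                        n_undefined = nrow(undef)),
                   class = "dissim_report")
  for (w in warns) warning(w, call. = FALSE)
  out
}

#' @export
print.dissim_report <- function(x, ...) {
  cat(if (x$ok) "dissimilarity matrix: OK\n" else "dissimilarity matrix: INVALID\n")
  for (p in x$problems) cat("  problem:", p, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  cat(sprintf("  off-diagonal min/max/mean: %.4f / %.4f / %.4f\n",
              x$stats["min"], x$stats["max"], x$stats["mean"]))
  invisible(x)
}

#' Write / read a dissimilarity matrix as CSV
#'
#' `write_dissimilarity` writes the square form (taxa as header row and
#' first column); `read_dissimilarity` reads it back.
#'
#' @param m a `dissimilarity_matrix`.
#' @param path CSV path.
#' @export
write_dissimilarity <- function(m, path) {
  m <- .as_dissim(m)
  utils::write.csv(as.data.frame(m$d), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  .as_dissim(as.matrix(df))
}
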