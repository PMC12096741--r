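# Positive matrix factorization implemented from scratch.
#
# Model: x_ij = sum_k g_ik f_kj + e_ij with g, f >= 0, fitted by minimizing
# the uncertainty-weighted objective Q = sum_ij (e_ij / s_ij)^2.
#
# Solver: weighted multiplicative updates (monotone nonincreasing in Q) from
# multiple random starts, followed by an exact alternating nonnegativity-
# constrained weighted least-squares polish (one NNLS problem per sample row
# and per species column, via pracma::lsqnonneg).  The best-Q start wins.
# Scale indeterminacy is fixed by normalizing each profile row to sum 1 and
# absorbing the scale into g; factors are ordered by contribution percentage
# descending.

#' Build the uncertainty matrix for PMF
#'
#' Observed cells: s = sqrt((error_fraction * x)^2 + (0.5 * MDL)^2).
#' Censored (below-detection) cells: s = (5/6) * MDL.  This is the standard
#' error-fraction construction used with receptor models when per-sample
#' analytical uncertainties are not reported.
#'
#' @param samples a \code{pah_samples} table
#' @param error_fraction relative measurement error in (0, 1); default 0.10
#' @param catalog species catalogue supplying the MDLs
#' @return object of class \code{pah_uncertainty}: list(s = matrix,
#'   error_fraction, mdl)
#' @export
build_uncertainty <- function(samples, error_fraction = 0.10,
                              catalog = default_catalog()) {
  if (!(error_fraction > 0 && error_fraction < 1))
    stop("error_fraction must be in (0, 1)")
  validate_catalog(catalog)
  if (any(catalog$mdl <= 0)) stop("nonpositive MDL in catalogue")
  x <- conc_matrix(samples)
  cens <- censored_matrix(samples)
  mdl <- stats::setNames(catalog$mdl, catalog$code)[colnames(x)]
  mdlm <- matrix(mdl, nrow(x), ncol(x), byrow = TRUE,
                 dimnames = dimnames(x))
  s <- sqrt((error_fraction * x)^2 + (0.5 * mdlm)^2)
  s[cens] <- (5 / 6) * mdlm[cens]
  stopifnot(all(s > 0))
  structure(list(s = s, error_fraction = error_fraction, mdl = mdl),
            class = "pah_uncertainty")
}

as_unc_matrix <- function(s) {
  if (inherits(s, "pah_uncertainty")) s$s else as.matrix(s)
}

#' Weighted objective Q of a factorization
#'
#' @param x concentration matrix
#' @param g sample x factor contributions
#' @param f factor x species profiles
#' @param s uncertainty matrix (or \code{pah_uncertainty})
#' @return scalar Q = sum(((x - g f) / s)^2)
#' @export
pmf_q <- function(x, g, f, s) {
  s <- as_unc_matrix(s)
  sum(((x - g %*% f) / s)^2)
}

# One pass of weighted multiplicative updates (Lee-Seung generalized to
# elementwise weights w = 1/s^2); monotone nonincreasing in Q.
mu_step <- function(x, g, f, w, eps = 1e-12) {
  gf <- g %*% f
  g <- g * ((w * x) %*% t(f)) / (((w * gf) %*% t(f)) + eps)
  gf <- g %*% f
  f <- f * (t(g) %*% (w * x)) / ((t(g) %*% (w * gf)) + eps)
  list(g = g, f = f)
}

# One pass of exact alternating NNLS: each sample row of g, then each
# species column of f, solved to optimality with pracma::lsqnonneg.
anls_step <- function(x, g, f, s) {
  n <- nrow(x); m <- ncol(x); k <- ncol(g)
  for (i in seq_len(n)) {
    A <- t(f) / s[i, ]           # m x k
    b <- x[i, ] / s[i, ]
    g[i, ] <- pracma::lsqnonneg(A, b)$x
  }
  for (j in seq_len(m)) {
    A <- g / s[, j]              # n x k
    b <- x[, j] / s[, j]
    f[, j] <- pracma::lsqnonneg(A, b)$x
  }
  list(g = g, f = f)
}

#' Fit a positive matrix factorization
#'
#' @param x sample x species concentration matrix (or \code{pah_samples})
#' @param s uncertainty matrix (or \code{pah_uncertainty}) of the same shape
#' @param n_factors number of factors, < min(dim(x))
#' @param n_starts random initializations; the best-Q solution is returned
#' @param seed integer seed
#' @param tol relative Q-change convergence tolerance
#' @param max_iter multiplicative-update iterations per start
#' @param polish_iter exact alternating-NNLS refinement passes per start
#' @param final_polish_iter additional refinement passes granted to the
#'   best start, run until the relative Q change drops below \code{tol}
#' @param init optional list(g, f) initial matrices; when supplied a single
#'   deterministic start is run from them (n_starts is ignored)
#' @return object of class \code{factor_model} with fields f, g, s, x, q,
#'   q_expected, contribution_pct, n_starts, seed, converged, q_path
#' @export
fit_pmf <- function(x, s, n_factors, n_starts = 20, seed = 1,
                    tol = 1e-6, max_iter = 2000, polish_iter = 30,
                    final_polish_iter = 500, init = NULL) {
  if (inherits(x, "pah_samples")) x <- conc_matrix(x)
  x <- as.matrix(x)
  s <- as_unc_matrix(s)
  if (!all(dim(x) == dim(s))) stop("x and s dimensions disagree")
  if (any(x < 0)) stop("x must be nonnegative")
  if (any(s <= 0)) stop("uncertainties must be > 0")
  n <- nrow(x); m <- ncol(x); k <- as.integer(n_factors)
  if (k >= min(n, m)) stop("n_factors must be < min(n_samples, n_species)")
  w <- 1 / s^2

  set.seed(as.integer(seed))
  scale0 <- sqrt(mean(x) / k)
  best <- NULL
  diverged <- 0L
  if (!is.null(init)) n_starts <- 1L
  for (st in seq_len(n_starts)) {
    if (!is.null(init)) {
      g <- as.matrix(init$g); f <- as.matrix(init$f)
      stopifnot(dim(g) == c(n, k), dim(f) == c(k, m), all(g >= 0),
                all(f >= 0))
    } else {
      g <- matrix(stats::runif(n * k, 0.1, 1), n, k) * scale0
      f <- matrix(stats::runif(k * m, 0.1, 1), k, m) * scale0
    }
    q_prev <- pmf_q(x, g, f, s)
    q_path <- q_prev
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      upd <- mu_step(x, g, f, w)
      g <- upd$g; f <- upd$f
      if (it %% 10 == 0 || it == max_iter) {
        q <- pmf_q(x, g, f, s)
        q_path <- c(q_path, q)
        if (!is.finite(q)) break
        if (abs(q_prev - q) <= tol * max(q_prev, .Machine$double.eps)) {
          converged <- TRUE
          q_prev <- q
          break
        }
        q_prev <- q
      }
    }
    for (it in seq_len(polish_iter)) {
      upd <- anls_step(x, g, f, s)
      g <- upd$g; f <- upd$f
      q <- pmf_q(x, g, f, s)
      q_path <- c(q_path, q)
      if (abs(q_prev - q) <= tol * max(q_prev, .Machine$double.eps)) {
        converged <- TRUE
        q_prev <- q
        break
      }
      q_prev <- q
    }
    q_final <- pmf_q(x, g, f, s)
    if (!is.finite(q_final)) { diverged <- diverged + 1L; next }
    if (is.null(best) || q_final < best$q) {
      best <- list(g = g, f = f, q = q_final, q_path = q_path,
                   converged = converged)
    }
  }
  if (is.null(best))
    stop("all ", n_starts, " starts diverged (", diverged,
         " non-finite Q values)")

  # extended exact refinement of the winning start
  g <- best$g; f <- best$f
  q_prev <- best$q
  for (it in seq_len(final_polish_iter)) {
    upd <- anls_step(x, g, f, s)
    g <- upd$g; f <- upd$f
    q <- pmf_q(x, g, f, s)
    best$q_path <- c(best$q_path, q)
    if (abs(q_prev - q) <= tol * max(q_prev, .Machine$double.eps) ||
        q < 1e-12) {
      best$converged <- TRUE
      q_prev <- q
      break
    }
    q_prev <- q
  }
  best$g <- g; best$f <- f; best$q <- q_prev

  # fix scale: profile rows sum to 1, scale absorbed into g
  rs <- rowSums(best$f)
  keep <- rs > 0
  fnorm <- best$f
  fnorm[keep, ] <- fnorm[keep, , drop = FALSE] / rs[keep]
  gnorm <- best$g
  gnorm[, keep] <- sweep(gnorm[, keep, drop = FALSE], 2, rs[keep], "*")

  pct <- 100 * (colSums(gnorm) * rowSums(fnorm)) /
    sum(colSums(gnorm) * rowSums(fnorm))
  ord <- order(pct, decreasing = TRUE)
  fnorm <- fnorm[ord, , drop = FALSE]
  gnorm <- gnorm[, ord, drop = FALSE]
  pct <- pct[ord]
  fac_names <- paste0("F", seq_len(k))
  rownames(fnorm) <- fac_names
  colnames(gnorm) <- fac_names
  colnames(fnorm) <- colnames(x)
  names(pct) <- fac_names

  # report Q recomputed from the normalized matrices; normalization leaves
  # the reconstruction unchanged up to floating-point rounding
  q_final <- pmf_q(x, gnorm, fnorm, s)
  stopifnot(abs(q_final - best$q) <= 1e-6 * max(best$q, 1e-9))
  structure(list(
    f = fnorm, g = gnorm, s = s, x = x,
    q = q_final, q_expected = n * m - k * (n + m),
    contribution_pct = pct, n_starts = n_starts, seed = seed,
    converged = best$converged, q_path = best$q_path),
    class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> ", nrow(x$f), " factors, Q = ",
      format(x$q, digits = 6), " (Q/Qexp = ",
      format(x$q / x$q_expected, digits = 4), ")\n", sep = "")
  print(round(x$contribution_pct, 2))
  invisible(x)
}

#' Factor contribution percentages of reconstructed mass
#'
#' percent_k = 100 * sum_ij g_ik f_kj / sum over all factors; sums to 100.
#'
#' @param model a fitted \code{factor_model}
#' @return named numeric vector of percentages
#' @export
contribution_percentages <- function(model) {
  mass <- colSums(model$g) * rowSums(model$f)
  tot <- sum(mass)
  if (tot <= 0) stop("all-zero reconstruction: contributions undefined")
  stats::setNames(100 * mass / tot, rownames(model$f))
}

#' Aggregate contribution percentages over a factor group
#'
#' Sums the (already rounded, 2-decimal) per-factor percentages of the named
#' members and rounds the sum to 2 decimals — the aggregation rule used when
#' quoting cumulative source-category contributions.
#'
#' @param pct named percentage vector (or a fitted \code{factor_model})
#' @param members factor names or indices to aggregate
#' @return scalar percentage, 2 decimals
#' @export
sum_contributions <- function(pct, members) {
  if (inherits(pct, "factor_model")) pct <- contribution_percentages(pct)
  round(sum(round(pct[members], 2)), 2)
}

#' Default source-marker table
#'
#' Marker species characteristic of the five urban source types used to
#' label PMF factors.
#'
#' @return named list: source label -> character vector of species codes
#' @export
default_markers <- function() {
  list(
    "biomass burning"  = c("Chr", "BaA", "BaP"),
    "gasoline traffic" = c("Flu", "BkF", "BaP", "BghiP", "IcdP"),
    "steel industry"   = c("Ace", "DahA", "IcdP"),
    "coal combustion"  = c("Phe", "Flua", "Pyr", "Chr"),
    "diesel traffic"   = c("Ant", "BaA", "BghiP")
  )
}

#' Assign source labels to fitted factors
#'
#' Each species column of the profile matrix is normalized across factors;
#' a factor's score for a candidate label is the mean normalized loading of
#' that label's marker species.  The best-scoring label is assigned; exact
#' ties are reported as ambiguous with all tied labels.  Labels are
#' heuristic and reported with their score, never asserted as ground truth.
#'
#' @param model a fitted \code{factor_model}
#' @param markers marker table, default \code{default_markers()}
#' @return data.frame with factor, label, score, ambiguous
#' @export
label_factors <- function(model, markers = default_markers()) {
  f <- model$f
  cs <- colSums(f)
  fn <- sweep(f, 2, ifelse(cs > 0, cs, 1), "/")
  scores <- sapply(markers, function(sp) {
    sp <- intersect(sp, colnames(fn))
    if (!length(sp)) return(rep(NA_real_, nrow(fn)))
    rowMeans(fn[, sp, drop = FALSE])
  })
  out <- do.call(rbind, lapply(seq_len(nrow(f)), function(kk) {
    sc <- scores[kk, ]
    top <- max(sc, na.rm = TRUE)
    tied <- names(sc)[!is.na(sc) & abs(sc - top) <= 1e-9]
    data.frame(factor = rownames(f)[kk],
               label = paste(tied, collapse = " | "),
               score = top, ambiguous = length(tied) > 1)
  }))
  rownames(out) <- NULL
  out
}

#' Q versus number of factors
#'
#' Fits the model over a range of factor counts for transparency when
#' choosing the dimensionality.
#'
#' @param x concentration matrix (or \code{pah_samples})
#' @param s uncertainty matrix (or \code{pah_uncertainty})
#' @param k_range integer vector of factor counts to try
#' @param ... passed to \code{fit_pmf}
#' @return data.frame with n_factors, q, q_expected
#' @export
pmf_factor_scan <- function(x, s, k_range = 3:7, ...) {
  rows <- lapply(k_range, function(k) {
    m <- fit_pmf(x, s, n_factors = k, ...)
    data.frame(n_factors = k, q = m$q, q_expected = m$q_expected)
  })
  do.call(rbind, rows)
}
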