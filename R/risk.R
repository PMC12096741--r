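# Health risk: BaP-equivalent toxicity (TEQ = sum_i C_i * TEF_i) and the
# inhalation incremental lifetime cancer risk
#
#   ILCR = (TEQ * CSF * IR * EF * ED * CF) / (BW * AT)
#
# evaluated either at point values or by Monte Carlo with per-iteration
# input records kept for sensitivity analysis.
#
# Unit convention (dimensionally closed to a unitless risk):
#   TEQ ng/m3, CSF (kg*d)/mg, IR m3/d, EF d/a, ED a, CF 1e-6 mg/ng,
#   BW kg, AT d.

#' BaP toxic-equivalent concentration of each sample
#'
#' @param samples a \code{pah_samples} table
#' @param catalog species catalogue supplying the TEFs
#' @return numeric vector, ng/m3: sum over species of conc * TEF
#' @export
teq <- function(samples, catalog = default_catalog()) {
  conc <- conc_matrix(samples)
  tef <- stats::setNames(catalog$tef, catalog$code)[colnames(conc)]
  if (anyNA(tef))
    stop("species missing from catalogue: ",
         paste(colnames(conc)[is.na(tef)], collapse = ", "))
  as.numeric(conc %*% tef)
}

#' Exposure profile for a receptor population
#'
#' Ships configurable defaults for an adult and a child receptor.  The
#' inhalation rate and body weight values are documented placeholders in the
#' range of Chinese exposure-factor handbooks and should be replaced with
#' authoritative values for any real assessment; CSF, CF and AT are the
#' standard constants of the inhalation ILCR model.
#'
#' IR and BW are sampled from normal distributions truncated at zero with
#' the stated coefficient of variation; EF and ED are fixed.
#'
#' @param receptor "adult" or "child"
#' @param ir mean inhalation rate, m3/d
#' @param bw mean body weight, kg
#' @param ef exposure frequency, d/a
#' @param ed exposure duration, a
#' @param cv coefficient of variation for IR and BW draws
#' @param csf cancer slope factor, (kg*d)/mg
#' @param cf unit conversion factor, mg/ng
#' @param at averaging time, d
#' @return object of class \code{exposure_profile}
#' @export
exposure_profile <- function(receptor = c("adult", "child"),
                             ir = NULL, bw = NULL, ef = 350, ed = NULL,
                             cv = 0.2, csf = 3.14, cf = 1e-6, at = 25550) {
  receptor <- match.arg(receptor)
  if (is.null(ir)) ir <- if (receptor == "adult") 15.7 else 8.7
  if (is.null(bw)) bw <- if (receptor == "adult") 60.6 else 21.7
  if (is.null(ed)) ed <- if (receptor == "adult") 24 else 6
  vals <- c(ir = ir, bw = bw, ef = ef, ed = ed, csf = csf, cf = cf, at = at)
  if (any(vals <= 0)) stop("all exposure parameters must be > 0")
  structure(list(receptor = receptor, ir = ir, bw = bw, ef = ef, ed = ed,
                 cv = cv, csf = csf, cf = cf, at = at),
            class = "exposure_profile")
}

#' Point-value incremental lifetime cancer risk
#'
#' @param teq_value TEQ concentration, ng/m3
#' @param profile an \code{exposure_profile} (point values = means)
#' @return dimensionless risk
#' @export
ilcr_point <- function(teq_value, profile) {
  if (profile$bw <= 0 || profile$at <= 0) stop("BW and AT must be > 0")
  (teq_value * profile$csf * profile$ir * profile$ef * profile$ed *
     profile$cf) / (profile$bw * profile$at)
}

rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Monte Carlo incremental lifetime cancer risk
#'
#' Each iteration draws a TEQ value (resampled from the supplied daily
#' series, or from a lognormal fitted to it) and IR/BW from zero-truncated
#' normal distributions, then evaluates the ILCR formula.  Per-iteration
#' inputs are retained for sensitivity analysis.
#'
#' @param teq_samples nonempty vector of daily TEQ values, ng/m3
#' @param profile an \code{exposure_profile}
#' @param n_iter iterations (>= 1000)
#' @param seed integer seed
#' @param teq_model "empirical" (resample the series) or "lognormal" (fit
#'   and draw)
#' @return object of class \code{risk_result}: draws, percentiles {min, P5,
#'   P25, median, P75, P95, max}, per-iteration inputs, n_iter, seed
#' @export
ilcr_mc <- function(teq_samples, profile, n_iter = 10000, seed = 1,
                    teq_model = c("empirical", "lognormal")) {
  teq_model <- match.arg(teq_model)
  if (!length(teq_samples)) stop("teq_samples is empty")
  if (n_iter < 1000) stop("n_iter must be >= 1000")
  if (all(teq_samples == 0))
    warning("all TEQ values are zero; risk is identically zero")
  set.seed(as.integer(seed))
  tq <- if (teq_model == "empirical") {
    teq_samples[sample.int(length(teq_samples), n_iter, replace = TRUE)]
  } else {
    pos <- teq_samples[teq_samples > 0]
    if (!length(pos)) rep(0, n_iter) else
      stats::rlnorm(n_iter, mean(log(pos)), stats::sd(log(pos)))
  }
  ir <- rtruncnorm_pos(n_iter, profile$ir, profile$cv * profile$ir)
  bw <- rtruncnorm_pos(n_iter, profile$bw, profile$cv * profile$bw)
  draws <- (tq * profile$csf * ir * profile$ef * profile$ed * profile$cf) /
    (bw * profile$at)
  pr <- stats::quantile(draws, c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1),
                        type = 7, names = FALSE)
  names(pr) <- c("min", "P5", "P25", "median", "P75", "P95", "max")
  structure(list(receptor = profile$receptor, draws = draws,
                 percentiles = pr,
                 inputs = data.frame(teq = tq, ir = ir, bw = bw,
                                     ef = profile$ef, ed = profile$ed),
                 sensitivity = NULL, n_iter = n_iter, seed = seed,
                 profile = profile),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat("<risk_result> ", x$receptor, ", ", x$n_iter, " iterations\n",
      sep = "")
  print(signif(x$percentiles, 4))
  invisible(x)
}

#' Sensitivity of the Monte Carlo risk to its inputs
#'
#' Spearman rank correlation of each varying input with the ILCR draws, and
#' a variance-contribution score 100 * rho_k^2 / sum(rho^2) (the
#' rank-correlation normalization used by tornado-chart tools).  Constant
#' inputs are excluded with a note.
#'
#' @param result a \code{risk_result}
#' @return the result with \code{sensitivity} filled: data.frame(input,
#'   rho, contribution_pct)
#' @export
risk_sensitivity <- function(result) {
  inp <- result$inputs
  varying <- vapply(inp, function(v) stats::sd(v) > 0, logical(1))
  if (!any(varying)) {
    message("no varying inputs; sensitivity undefined")
    result$sensitivity <- data.frame(input = character(), rho = numeric(),
                                     contribution_pct = numeric())
    return(result)
  }
  excluded <- names(inp)[!varying]
  if (length(excluded))
    message("constant input(s) excluded from sensitivity: ",
            paste(excluded, collapse = ", "))
  rho <- vapply(inp[varying], function(v)
    suppressWarnings(stats::cor(v, result$draws, method = "spearman")),
    numeric(1))
  contrib <- 100 * rho^2 / sum(rho^2)
  result$sensitivity <- data.frame(input = names(rho), rho = as.numeric(rho),
                                   contribution_pct = as.numeric(contrib))
  result
}

#' Per-species share of the summed toxic equivalent
#'
#' share_i = 100 * sum_days conc_i * TEF_i / sum_days TEQ; shares sum to
#' 100.
#'
#' @param samples a \code{pah_samples} table
#' @param catalog species catalogue
#' @return named numeric vector of percentages
#' @export
species_risk_shares <- function(samples, catalog = default_catalog()) {
  conc <- conc_matrix(samples)
  tef <- stats::setNames(catalog$tef, catalog$code)[colnames(conc)]
  num <- colSums(conc) * tef
  tot <- sum(num)
  if (tot <= 0) stop("total TEQ is zero: shares undefined")
  100 * num / tot
}
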