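# Descriptive statistics: median/quartile summaries, limit-exceedance
# accounting, molecular-weight class proportions, rank correlations, and
# nonparametric group comparisons.

resolve_field <- function(samples, field) {
  if (field == "total_pah") return(total_pah(samples))
  if (!field %in% names(samples)) stop("unknown field: ", field)
  samples[[field]]
}

resolve_strata <- function(samples, by = c("all", "year", "site")) {
  by <- match.arg(by)
  switch(by,
    all = rep("all", nrow(samples)),
    year = as.character(sample_year(samples)),
    site = as.character(samples$site))
}

#' Median and quartile summary by stratum
#'
#' Quantiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7), fixed so the tables are reproducible.
#'
#' @param samples a \code{pah_samples} table
#' @param fields character vector of fields to summarize: species codes,
#'   "pm25", "total_pah", or meteorology columns
#' @param by stratification: "all", "year" or "site"
#' @return data.frame with stratum, field, n, median, p25, p75
#' @export
pah_summary <- function(samples, fields = c(pah_codes(), "total_pah", "pm25"),
                        by = "year") {
  strata <- resolve_strata(samples, by)
  out <- list()
  for (s in sort(unique(strata))) {
    idx <- strata == s
    if (!any(idx)) { warning("empty stratum ", s, " omitted"); next }
    for (f in fields) {
      v <- resolve_field(samples, f)[idx]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        stratum = s, field = f, n = sum(idx),
        median = q[2], p25 = q[1], p75 = q[3])
    }
  }
  do.call(rbind, out)
}

#' Limit-exceedance accounting
#'
#' Counts strict exceedances (value > limit; a day exactly at the limit does
#' not exceed) and reports the rate as a percentage rounded to 2 decimals.
#'
#' @param samples a \code{pah_samples} table
#' @param limit positive concentration threshold (same units as the field)
#' @param field "pm25" (ug/m3), a species code or "total_pah" (ng/m3)
#' @param by stratification: "all", "year" or "site"
#' @param strict use strict ">" (default); FALSE counts ">=" as exceedance
#' @return data.frame of class \code{exceedance_report} with stratum,
#'   n_total, n_exceed, rate
#' @export
exceedance <- function(samples, limit, field = "pm25", by = "all",
                       strict = TRUE) {
  if (limit <= 0) stop("limit must be > 0")
  v <- resolve_field(samples, field)
  hit <- if (strict) v > limit else v >= limit
  strata <- resolve_strata(samples, by)
  out <- do.call(rbind, lapply(sort(unique(strata)), function(s) {
    idx <- strata == s
    data.frame(stratum = s, limit = limit, field = field,
               n_total = sum(idx), n_exceed = sum(hit[idx]),
               rate = round(100 * sum(hit[idx]) / sum(idx), 2))
  }))
  class(out) <- c("exceedance_report", "data.frame")
  out
}

#' Molecular-weight class mass proportions by year
#'
#' Fraction of total PAH mass carried by low (2-3 ring), medium (4 ring) and
#' high (5-6 ring) molecular-weight species, per calendar year.
#'
#' @param samples a \code{pah_samples} table
#' @param catalog species catalogue
#' @return data.frame with year, LMW, MMW, HMW (rows sum to 1)
#' @export
mw_proportions <- function(samples, catalog = default_catalog()) {
  validate_catalog(catalog)
  conc <- conc_matrix(samples)
  cls <- stats::setNames(catalog$mw_class, catalog$code)[colnames(conc)]
  years <- sample_year(samples)
  out <- do.call(rbind, lapply(sort(unique(years)), function(y) {
    m <- conc[years == y, , drop = FALSE]
    tot <- sum(m)
    data.frame(year = y,
               LMW = sum(m[, cls == "LMW"]) / tot,
               MMW = sum(m[, cls == "MMW"]) / tot,
               HMW = sum(m[, cls == "HMW"]) / tot)
  }))
  rownames(out) <- NULL
  out
}

#' Spearman rank-correlation matrix with significance flags
#'
#' Pairwise-complete Spearman correlations between the requested variables;
#' entries for constant variables are NA and flagged rather than raising an
#' error.
#'
#' @param samples a \code{pah_samples} table
#' @param variables character vector of fields (species codes, "pm25",
#'   "total_pah", meteorology columns)
#' @return list with matrices \code{rho}, \code{p}, \code{n} and logical
#'   \code{undefined}
#' @export
correlation_matrix <- function(samples,
                               variables = c("total_pah", "pm25", "temp",
                                             "pressure", "rh")) {
  dat <- sapply(variables, function(f) resolve_field(samples, f))
  k <- ncol(dat)
  rho <- p <- nmat <- matrix(NA_real_, k, k,
                             dimnames = list(variables, variables))
  undef <- matrix(FALSE, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(dat[, i], dat[, j])
    nmat[i, j] <- sum(ok)
    if (i == j) { rho[i, j] <- 1; p[i, j] <- 0; next }
    x <- dat[ok, i]; y <- dat[ok, j]
    if (sum(ok) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      undef[i, j] <- TRUE
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(rho = rho, p = p, n = nmat, undefined = undef)
}

#' Nonparametric comparison of a field between groups
#'
#' Two groups: Wilcoxon rank-sum (Mann-Whitney U) with mid-ranks and
#' tie-corrected variance, no continuity correction, exact enumeration when
#' the samples are small and tie-free.  More than two groups:
#' Kruskal-Wallis.
#'
#' @param samples a \code{pah_samples} table
#' @param grouping "site" or "year"
#' @param field field to compare
#' @return list with \code{method}, \code{statistic}, \code{p_value},
#'   \code{groups}
#' @export
compare_groups <- function(samples, grouping = c("site", "year"),
                           field = "pm25") {
  grouping <- match.arg(grouping)
  g <- if (grouping == "site") as.character(samples$site) else
    as.character(sample_year(samples))
  v <- resolve_field(samples, field)
  lev <- sort(unique(g))
  if (length(lev) < 2) stop("need at least 2 groups")
  rank_compare(v, g)
}

#' Rank test on a value vector with group labels
#'
#' The computational core of \code{compare_groups}, usable on raw vectors.
#'
#' @param values numeric vector
#' @param groups group label for each value
#' @return list with \code{method}, \code{statistic}, \code{p_value},
#'   \code{groups}
#' @export
rank_compare <- function(values, groups) {
  g <- as.character(groups)
  lev <- sort(unique(g))
  if (length(lev) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2))
    warning("group(s) with fewer than 2 observations: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
  if (length(lev) == 2) {
    ht <- suppressWarnings(
      stats::wilcox.test(values[g == lev[1]], values[g == lev[2]],
                         correct = FALSE))
    list(method = "wilcoxon-rank-sum", statistic = unname(ht$statistic),
         p_value = ht$p.value, groups = lev)
  } else {
    ht <- stats::kruskal.test(values, factor(g))
    list(method = "kruskal-wallis", statistic = unname(ht$statistic),
         p_value = ht$p.value, groups = lev)
  }
}
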