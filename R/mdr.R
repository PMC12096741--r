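# Molecular diagnostic ratios (MDR): isomer-pair ratios a/(a+b) whose value
# bands discriminate petrogenic from combustion-derived PAHs.

MDR_PAIRS <- list(
  AntPhe    = c("Ant",  "Phe"),
  FluaPyr   = c("Flua", "Pyr"),
  BaAChr    = c("BaA",  "Chr"),
  IcdPBghiP = c("IcdP", "BghiP")
)

#' Default diagnostic-ratio classification bands
#'
#' Band boundaries follow the usual convention: an exact lower cut-off
#' belongs to the higher class ("greater than" phrasing) and the middle
#' band, where present, is closed on both ends.
#'
#' @return named list; per ratio a data.frame with lower, upper, label, and
#'   logical flags marking boundary inclusion
#' @export
mdr_bands <- function() {
  band <- function(lower, upper, label, lower_closed, upper_closed)
    data.frame(lower = lower, upper = upper, label = label,
               lower_closed = lower_closed, upper_closed = upper_closed,
               stringsAsFactors = FALSE)
  list(
    AntPhe = rbind(
      band(0, 0.1, "petrogenic", TRUE, FALSE),
      band(0.1, 1, "combustion", TRUE, TRUE)),
    FluaPyr = rbind(
      band(0, 0.4, "petrogenic/unburned petroleum", TRUE, FALSE),
      band(0.4, 0.5, "fossil fuel combustion", TRUE, TRUE),
      band(0.5, 1, "biomass and coal combustion", FALSE, TRUE)),
    BaAChr = rbind(
      band(0, 0.2, "petrogenic", TRUE, FALSE),
      band(0.2, 0.35, "petroleum combustion", TRUE, TRUE),
      band(0.35, 1, "biomass and coal combustion", FALSE, TRUE)),
    IcdPBghiP = rbind(
      band(0, 0.2, "petrogenic", TRUE, FALSE),
      band(0.2, 0.5, "petroleum combustion", TRUE, TRUE),
      band(0.5, 1, "biomass and coal combustion", FALSE, TRUE))
  )
}

#' Compute the four diagnostic ratios for each sample
#'
#' ratio = a/(a+b) on censor-substituted concentrations; undefined (NA) when
#' a+b = 0 or both components are censored.  A low-confidence flag is raised
#' when either component is censored, since the substitution constant can
#' dominate the ratio.
#'
#' @param samples a \code{pah_samples} table
#' @return data.frame of class \code{mdr_ratios}: date, site, year, one
#'   column per ratio, and lowconf_* flags
#' @export
compute_ratios <- function(samples) {
  conc <- conc_matrix(samples)
  cens <- censored_matrix(samples)
  out <- data.frame(date = samples$date, site = samples$site,
                    year = sample_year(samples))
  for (nm in names(MDR_PAIRS)) {
    a <- conc[, MDR_PAIRS[[nm]][1]]
    b <- conc[, MDR_PAIRS[[nm]][2]]
    ca <- cens[, MDR_PAIRS[[nm]][1]]
    cb <- cens[, MDR_PAIRS[[nm]][2]]
    r <- ifelse(a + b > 0 & !(ca & cb), a / (a + b), NA_real_)
    out[[nm]] <- r
    out[[paste0("lowconf_", nm)]] <- (ca | cb) & !is.na(r)
  }
  class(out) <- c("mdr_ratios", "data.frame")
  out
}

#' Classify a vector of ratio values for one diagnostic ratio
#'
#' Total on [0,1] plus NA: every defined value receives exactly one label;
#' NA receives none (NA label).
#'
#' @param values numeric vector in [0,1] (NAs allowed)
#' @param ratio ratio name: "AntPhe", "FluaPyr", "BaAChr" or "IcdPBghiP"
#' @param bands band table, default \code{mdr_bands()}
#' @return character vector of source labels (NA where undefined)
#' @export
classify_ratio_values <- function(values, ratio, bands = mdr_bands()) {
  if (!ratio %in% names(bands)) stop("unknown ratio: ", ratio)
  tab <- bands[[ratio]]
  out <- rep(NA_character_, length(values))
  for (r in seq_len(nrow(tab))) {
    lo_ok <- if (tab$lower_closed[r]) values >= tab$lower[r] else
      values > tab$lower[r]
    hi_ok <- if (tab$upper_closed[r]) values <= tab$upper[r] else
      values < tab$upper[r]
    hit <- !is.na(values) & lo_ok & hi_ok
    if (any(hit & !is.na(out)))
      stop("overlapping bands for ratio ", ratio)
    out[hit] <- tab$label[r]
  }
  if (any(!is.na(values) & (values < 0 | values > 1)))
    stop("ratio values must lie in [0,1]")
  out
}

#' Attach source-class labels to a ratio table
#'
#' @param ratios an \code{mdr_ratios} data.frame from \code{compute_ratios}
#' @param bands band table, default \code{mdr_bands()}
#' @return the table with added class_* columns
#' @export
classify_ratios <- function(ratios, bands = mdr_bands()) {
  for (nm in names(MDR_PAIRS))
    ratios[[paste0("class_", nm)]] <-
      classify_ratio_values(ratios[[nm]], nm, bands)
  ratios
}

#' Per-year percentage of samples whose ratio satisfies a predicate
#'
#' The denominator counts only samples with the ratio defined; years where
#' the ratio is never defined are emitted with n = 0 and a blank (NA) rate.
#'
#' @param ratios an \code{mdr_ratios} data.frame
#' @param ratio ratio name
#' @param op comparison operator: ">", ">=", "<" or "<="
#' @param threshold cut-off value
#' @return data.frame with year, n (defined ratios), n_true, rate (percent,
#'   2 decimals)
#' @export
annual_fraction <- function(ratios, ratio, op = ">", threshold = 0.1) {
  cmp <- match.fun(op)
  v <- ratios[[ratio]]
  if (is.null(v)) stop("unknown ratio: ", ratio)
  out <- do.call(rbind, lapply(sort(unique(ratios$year)), function(y) {
    vy <- v[ratios$year == y]
    vy <- vy[!is.na(vy)]
    n <- length(vy)
    nt <- sum(cmp(vy, threshold))
    data.frame(year = y, n = n, n_true = nt,
               rate = if (n > 0) round(100 * nt / n, 2) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
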