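# Sample tables: one row per site-day with PM2.5 mass, the 16 PAH
# concentrations, optional meteorology, and per-species censoring flags
# (columns cens_<code>).  The object is a plain data.frame with class
# "pah_samples" so all base verbs keep working.

CENSOR_POLICIES <- c("substitute-mdl", "substitute-half-mdl", "leave-zero")

#' Substitution value for below-detection-limit observations
#'
#' @param policy one of "substitute-mdl", "substitute-half-mdl", "leave-zero"
#' @param mdl detection limit(s), ng/m3
#' @return the value stored in place of a censored observation
#' @keywords internal
censor_substitute <- function(policy, mdl) {
  switch(policy,
    "substitute-mdl" = mdl,
    "substitute-half-mdl" = 0.5 * mdl,
    "leave-zero" = 0 * mdl,
    stop("unknown censoring policy: ", policy))
}

#' Apply a censoring policy to a concentration matrix
#'
#' Values strictly below the species detection limit are replaced by the
#' policy's substitution value and flagged.  Already-censored cells are left
#' untouched, which makes the operation idempotent for every policy.
#'
#' @param conc numeric matrix, samples x species (columns named by code)
#' @param mdl named numeric vector of detection limits per species
#' @param policy censoring policy id
#' @param censored optional existing logical flag matrix
#' @return list(conc = substituted matrix, censored = logical flag matrix)
#' @export
apply_censoring <- function(conc, mdl, policy = "substitute-mdl",
                            censored = NULL) {
  policy <- match.arg(policy, CENSOR_POLICIES)
  mdl <- mdl[colnames(conc)]
  if (anyNA(mdl)) stop("missing detection limit for some species")
  if (is.null(censored))
    censored <- matrix(FALSE, nrow(conc), ncol(conc),
                       dimnames = dimnames(conc))
  below <- sweep(conc, 2, mdl, "<") & !censored
  sub <- matrix(censor_substitute(policy, mdl), nrow(conc), ncol(conc),
                byrow = TRUE)
  conc[below] <- sub[below]
  list(conc = conc, censored = censored | below)
}

#' Assemble a validated sample table
#'
#' @param df data.frame with columns date, site, pm25, the 16 species, and
#'   optionally temp, pressure, rh
#' @param catalog species catalogue (defaults to \code{default_catalog()})
#' @param censor_policy policy applied to below-MDL values
#' @return a \code{pah_samples} data.frame with added cens_* flag columns
#' @export
as_pah_samples <- function(df, catalog = default_catalog(),
                           censor_policy = "substitute-mdl") {
  validate_catalog(catalog)
  codes <- pah_codes()
  miss <- setdiff(c("date", "site", "pm25", codes), names(df))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)

  num_cols <- c("pm25", codes)
  bad <- which(is.na(df$date) |
                 Reduce(`|`, lapply(df[num_cols],
                                    function(v) is.na(suppressWarnings(as.numeric(v))))))
  if (length(bad)) {
    warning("rejecting ", length(bad), " malformed row(s): ",
            paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "")
    df <- df[-bad, , drop = FALSE]
  }
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])

  for (cc in num_cols) {
    neg <- which(df[[cc]] < 0)
    if (length(neg))
      stop("negative concentration in row ", neg[1], ", column ", cc)
  }

  conc <- as.matrix(df[, codes])
  mdl <- stats::setNames(catalog$mdl, catalog$code)
  cens <- apply_censoring(conc, mdl, censor_policy)
  df[, codes] <- cens$conc
  flag <- as.data.frame(cens$censored)
  names(flag) <- paste0("cens_", codes)
  keep <- intersect(c("date", "site", "pm25", codes, "temp", "pressure", "rh"),
                    names(df))
  out <- cbind(df[, keep, drop = FALSE], flag)
  rownames(out) <- NULL
  attr(out, "censor_policy") <- censor_policy
  class(out) <- c("pah_samples", "data.frame")
  out
}

#' Load a delimited sample table
#'
#' Expects one row per site-day with header
#' \code{date,site,pm25,Nap,...,IcdP[,temp,pressure,rh]}.  Values below the
#' species detection limit are substituted per \code{censor_policy} and
#' flagged; malformed rows are rejected with row-number diagnostics; negative
#' concentrations abort with the offending row and species named.
#'
#' @param path CSV/TSV file path (separator sniffed from the header line)
#' @param catalog species catalogue
#' @param censor_policy one of "substitute-mdl" (default),
#'   "substitute-half-mdl", "leave-zero"
#' @return a \code{pah_samples} data.frame
#' @export
load_samples <- function(path, catalog = default_catalog(),
                         censor_policy = "substitute-mdl") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_pah_samples(df, catalog = catalog, censor_policy = censor_policy)
}

#' Concentration matrix of a sample table
#'
#' @param samples a \code{pah_samples} data.frame
#' @return numeric matrix, samples x 16 species
#' @export
conc_matrix <- function(samples) {
  as.matrix(samples[, pah_codes()])
}

#' Censoring flag matrix of a sample table
#'
#' @param samples a \code{pah_samples} data.frame
#' @return logical matrix, samples x 16 species
#' @export
censored_matrix <- function(samples) {
  m <- as.matrix(samples[, paste0("cens_", pah_codes())])
  colnames(m) <- pah_codes()
  m
}

#' Total PAH concentration per sample
#'
#' @param samples a \code{pah_samples} data.frame
#' @return numeric vector of row sums over the 16 species, ng/m3
#' @export
total_pah <- function(samples) {
  rowSums(conc_matrix(samples))
}

#' Calendar year of each sample
#' @param samples a \code{pah_samples} data.frame
#' @return integer vector
#' @export
sample_year <- function(samples) {
  as.integer(format(samples$date, "%Y"))
}
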