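#' Codes of the 16 priority PAH species, in canonical column order
#'
#' Naphthalene through indeno(1,2,3-cd)pyrene, the 16 US-EPA priority
#' polycyclic aromatic hydrocarbons routinely quantified in PM2.5 filters.
#'
#' @export
pah_codes <- function() {
  c("Nap", "Acy", "Flu", "Ace", "Phe", "Ant", "Flua", "Pyr",
    "Chr", "BaA", "BbF", "BkF", "BaP", "DahA", "BghiP", "IcdP")
}

#' Molecular-weight class implied by aromatic ring count
#'
#' LMW: 2-3 rings, MMW: 4 rings, HMW: 5-6 rings.
#'
#' @param rings integer vector of ring counts in 2..6
#' @return character vector of "LMW", "MMW" or "HMW"
#' @export
mw_class_from_rings <- function(rings) {
  if (!all(rings %in% 2:6)) stop("ring counts must be in 2..6")
  ifelse(rings <= 3, "LMW", ifelse(rings == 4, "MMW", "HMW"))
}

#' Default species catalogue
#'
#' One row per PAH species: ring count, molecular-weight class, toxic
#' equivalency factor (TEF, relative to benzo[a]pyrene, Nisbet-LaGoy
#' assignment) and method detection limit (MDL, ng/m3).
#'
#' The MDLs are inferred defaults typical of HPLC filter analysis, chosen to
#' match the substitution constants that dominate low-concentration species
#' in long-term urban series; they are plain inputs and can be overridden via
#' \code{read_catalog()} or by editing the returned data frame.
#'
#' @return data.frame with columns code, rings, mw_class, tef, mdl
#' @export
default_catalog <- function() {
  cat <- data.frame(
    code = pah_codes(),
    rings = c(2L, 3L, 3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 5L, 5L, 5L, 6L, 6L, 6L),
    tef  = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.01, 0.001, 0.001,
             0.01, 0.1, 0.1, 0.1, 1, 1, 0.01, 0.1),
    mdl  = c(0.06, 0.01, 0.04, 0.15, 0.10, 0.04, 0.13, 0.08,
             0.05, 0.06, 0.07, 0.03, 0.10, 0.13, 0.06, 0.04),
    stringsAsFactors = FALSE
  )
  cat$mw_class <- mw_class_from_rings(cat$rings)
  cat <- cat[, c("code", "rings", "mw_class", "tef", "mdl")]
  validate_catalog(cat)
  cat
}

#' Validate a species catalogue
#'
#' Checks the structural invariants: exactly the 16 canonical species, ring
#' counts in 2..6 with the matching molecular-weight class, TEFs drawn from
#' {0.001, 0.01, 0.1, 1}, and strictly positive detection limits.
#'
#' @param cat a catalogue data frame
#' @return the catalogue, invisibly, if valid
#' @export
validate_catalog <- function(cat) {
  need <- c("code", "rings", "mw_class", "tef", "mdl")
  if (!all(need %in% names(cat)))
    stop("catalogue must have columns ", paste(need, collapse = ", "))
  if (nrow(cat) != 16L || !setequal(cat$code, pah_codes()))
    stop("catalogue must contain exactly the 16 canonical PAH species")
  if (anyDuplicated(cat$code)) stop("duplicated species code in catalogue")
  if (!all(cat$rings %in% 2:6)) stop("ring counts must be in 2..6")
  if (!identical(cat$mw_class, mw_class_from_rings(cat$rings)))
    stop("mw_class inconsistent with ring counts")
  if (!all(cat$tef %in% c(0.001, 0.01, 0.1, 1)))
    stop("TEF values must be one of 0.001, 0.01, 0.1, 1")
  if (!all(cat$mdl > 0)) stop("detection limits must be > 0")
  invisible(cat)
}

#' Read a species catalogue from CSV
#'
#' Expected header: \code{code,rings,tef,mdl}; the molecular-weight class is
#' derived from the ring count.
#'
#' @param path CSV file path
#' @return validated catalogue data frame
#' @export
read_catalog <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "rings", "tef", "mdl")
  miss <- setdiff(need, names(cat))
  if (length(miss))
    stop("catalogue file missing column(s): ", paste(miss, collapse = ", "))
  cat$rings <- as.integer(cat$rings)
  cat$mw_class <- mw_class_from_rings(cat$rings)
  cat <- cat[, c("code", "rings", "mw_class", "tef", "mdl")]
  validate_catalog(cat)
  cat
}
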