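# Writers for pipeline products.  All tabular outputs are CSV with a stable
# column order; numeric cells are printed with 17 significant digits so a
# write -> read round trip reproduces every double bit-for-bit.

write_table_precise <- function(df, path) {
  out <- df
  for (cc in names(out)) {
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

#' Read back a CSV written by \code{write_results}
#'
#' @param path CSV path
#' @return data.frame with numeric columns restored to full precision
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a pipeline product to a directory
#'
#' Dispatches on the product class and writes one or more delimited-text
#' tables with stable column order.  Numeric values round-trip exactly
#' through \code{read_result_table()}.
#'
#' @param obj a pipeline product (sample table, factor model, PSCF grid,
#'   risk result, trajectory set, or plain data.frame)
#' @param dir output directory, created if missing
#' @param name base file name for products written as a single table
#' @param ... passed to methods
#' @return character vector of files written, invisibly
#' @export
write_results <- function(obj, dir, ...) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  UseMethod("write_results")
}

#' @rdname write_results
#' @export
write_results.pah_samples <- function(obj, dir, name = "samples", ...) {
  df <- as.data.frame(obj)
  df <- df[, setdiff(names(df), paste0("cens_", pah_codes())), drop = FALSE]
  df$date <- format(df$date, "%Y-%m-%d")
  f <- file.path(dir, paste0(name, ".csv"))
  write_table_precise(df, f)
  invisible(f)
}

#' @rdname write_results
#' @export
write_results.factor_model <- function(obj, dir, ...) {
  fp <- file.path(dir, "profiles.csv")
  prof <- data.frame(factor = rownames(obj$f), obj$f, check.names = FALSE)
  write_table_precise(prof, fp)

  fc <- file.path(dir, "contributions.csv")
  contrib <- data.frame(sample = seq_len(nrow(obj$g)), obj$g,
                        check.names = FALSE)
  write_table_precise(contrib, fc)

  fs <- file.path(dir, "summary.csv")
  summ <- data.frame(
    factor = names(obj$contribution_pct),
    contribution_pct = as.numeric(obj$contribution_pct),
    q = obj$q, q_expected = obj$q_expected,
    n_starts = obj$n_starts, seed = obj$seed, converged = obj$converged)
  write_table_precise(summ, fs)
  invisible(c(fp, fc, fs))
}

#' @rdname write_results
#' @export
write_results.pscf_grid <- function(obj, dir, name = "pscf", ...) {
  f <- file.path(dir, paste0(name, ".csv"))
  write_table_precise(as.data.frame(obj), f)
  invisible(f)
}

#' @rdname write_results
#' @export
write_results.risk_result <- function(obj, dir, name = "risk", draws = FALSE,
                                      ...) {
  fp <- file.path(dir, paste0(name, "_percentiles.csv"))
  pct <- data.frame(statistic = names(obj$percentiles),
                    ilcr = as.numeric(obj$percentiles))
  write_table_precise(pct, fp)
  files <- fp
  if (!is.null(obj$sensitivity)) {
    fs <- file.path(dir, paste0(name, "_sensitivity.csv"))
    write_table_precise(obj$sensitivity, fs)
    files <- c(files, fs)
  }
  if (isTRUE(draws)) {
    fd <- file.path(dir, paste0(name, "_draws.csv"))
    write_table_precise(data.frame(iter = seq_along(obj$draws),
                                   ilcr = obj$draws), fd)
    files <- c(files, fd)
  }
  invisible(files)
}

#' @rdname write_results
#' @export
write_results.trajectory_set <- function(obj, dir, name = "trajectories",
                                         ...) {
  f <- file.path(dir, paste0(name, ".tdump"))
  s <- file.path(dir, paste0(name, "_arrivals.csv"))
  write_tdump(obj, f, sidecar = s)
  invisible(c(f, s))
}

#' @rdname write_results
#' @export
write_results.data.frame <- function(obj, dir, name = "table", ...) {
  f <- file.path(dir, paste0(name, ".csv"))
  write_table_precise(obj, f)
  invisible(f)
}
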