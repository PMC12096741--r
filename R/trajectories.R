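# Back-trajectory endpoint files in HYSPLIT tdump layout.
#
# Layout handled:
#   line 1                : <n_met_grids> <...>
#   next n_met_grids lines: met grid identification records
#   next line             : <n_traj> <direction> <vertical motion>
#   next n_traj lines     : trajectory start records
#                           (yr mo da hr lat lon height)
#   next line             : <n_vars> <var names...>
#   remaining lines       : endpoint records
#                           traj grid yr mo da hr mn fcast age lat lon height
#                           [+ n_vars diagnostic values]
#
# Arrival site/day is attached from a sidecar CSV (traj_id,date,site); absent
# a sidecar, the arrival date is taken from each trajectory's age-0 endpoint
# and the site is left as "all".

#' Construct a trajectory set
#'
#' @param endpoints data.frame with columns traj_id, date (arrival), site,
#'   step, lat, lon and optionally height
#' @param metadata list; run length (h), arrival height (m) if known
#' @return object of class \code{trajectory_set}
#' @export
trajectory_set <- function(endpoints, metadata = list()) {
  need <- c("traj_id", "date", "site", "step", "lat", "lon")
  miss <- setdiff(need, names(endpoints))
  if (length(miss))
    stop("endpoints missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(endpoints)) {
    if (any(endpoints$lat < -90 | endpoints$lat > 90))
      stop("latitude outside [-90, 90]")
    if (any(endpoints$lon < -180 | endpoints$lon > 180))
      stop("longitude outside [-180, 180]")
    by_traj <- split(endpoints$step, endpoints$traj_id)
    ok <- vapply(by_traj, function(s) all(diff(sort(s)) == 1), logical(1))
    if (!all(ok))
      stop("non-consecutive step indices in trajectory ",
           names(by_traj)[which(!ok)[1]])
  }
  structure(list(endpoints = endpoints, metadata = metadata),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", length(unique(x$endpoints$traj_id)),
      " trajectories, ", nrow(x$endpoints), " endpoints\n", sep = "")
  invisible(x)
}

#' Parse a HYSPLIT tdump endpoint file
#'
#' @param path tdump file
#' @param sidecar optional CSV path mapping \code{traj_id,date,site} to
#'   arrival site-days; when absent the arrival date is derived from the
#'   age-0 endpoint timestamp and the site is "all"
#' @return a \code{trajectory_set}
#' @export
load_trajectories <- function(path, sidecar = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty tdump file: ", path)
  fields <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]

  i <- 1L
  n_grids <- as.integer(fields(lines[i])[1]); i <- i + 1L
  if (is.na(n_grids) || n_grids < 0) stop("bad met-grid count on line 1")
  i <- i + n_grids
  hdr <- fields(lines[i])
  n_traj <- as.integer(hdr[1]); i <- i + 1L
  if (is.na(n_traj) || n_traj < 0) stop("bad trajectory count on line ", i - 1L)
  i <- i + n_traj
  n_vars <- as.integer(fields(lines[i])[1]); i <- i + 1L
  if (is.na(n_vars) || n_vars < 0) stop("bad variable count on line ", i - 1L)

  ep_lines <- lines[seq.int(i, length.out = max(0L, length(lines) - i + 1L))]
  ep_lines <- ep_lines[nzchar(trimws(ep_lines))]
  if (!length(ep_lines)) {
    warning("tdump file has an empty endpoint section: ", path)
    return(trajectory_set(data.frame(
      traj_id = integer(), date = as.Date(character()), site = character(),
      step = integer(), lat = numeric(), lon = numeric(),
      height = numeric())))
  }

  recs <- lapply(seq_along(ep_lines), function(k) {
    f <- suppressWarnings(as.numeric(fields(ep_lines[k])))
    if (length(f) < 12L || anyNA(f[1:12]))
      stop("truncated endpoint record on line ", i + k - 1L, " of ", path)
    f
  })
  m <- do.call(rbind, recs)
  yy <- m[, 3]
  yy <- ifelse(yy < 100, ifelse(yy >= 70, 1900 + yy, 2000 + yy), yy)
  ep <- data.frame(
    traj_id = as.integer(m[, 1]),
    year = as.integer(yy), month = as.integer(m[, 4]),
    day = as.integer(m[, 5]), hour = as.integer(m[, 6]),
    age = m[, 9], lat = m[, 10], lon = m[, 11], height = m[, 12]
  )
  ep$step <- as.integer(round(abs(ep$age)))

  if (!is.null(sidecar)) {
    map <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
    need <- c("traj_id", "date", "site")
    if (!all(need %in% names(map)))
      stop("sidecar must have columns traj_id,date,site")
    idx <- match(ep$traj_id, map$traj_id)
    if (anyNA(idx))
      stop("sidecar missing arrival mapping for trajectory ",
           ep$traj_id[which(is.na(idx))[1]])
    ep$date <- as.Date(map$date[idx])
    ep$site <- map$site[idx]
  } else {
    arr <- ep[ep$step == 0L, c("traj_id", "year", "month", "day")]
    arr <- arr[!duplicated(arr$traj_id), ]
    arr$date <- as.Date(sprintf("%04d-%02d-%02d",
                                arr$year, arr$month, arr$day))
    idx <- match(ep$traj_id, arr$traj_id)
    if (anyNA(idx)) stop("trajectory without age-0 endpoint; supply a sidecar")
    ep$date <- arr$date[idx]
    ep$site <- "all"
  }

  run_len <- max(ep$step)
  arrival_height <- if (any(ep$step == 0L)) ep$height[ep$step == 0L][1] else NA_real_
  trajectory_set(
    ep[, c("traj_id", "date", "site", "step", "lat", "lon", "height")],
    metadata = list(run_length_h = run_len, arrival_height_m = arrival_height,
                    n_traj = length(unique(ep$traj_id))))
}

#' Write a trajectory set as a tdump-layout file plus sidecar
#'
#' @param traj a \code{trajectory_set}
#' @param path output tdump path
#' @param sidecar output CSV path for the arrival site-day mapping; NULL to
#'   skip
#' @return \code{path}, invisibly
#' @export
write_tdump <- function(traj, path, sidecar = NULL) {
  ep <- traj$endpoints
  ids <- unique(ep$traj_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("     1     1", con)
  writeLines("    SYNT    17     1     1     0     0", con)
  writeLines(sprintf("%6d BACKWARD OMEGA", length(ids)), con)
  for (id in ids) {
    e0 <- ep[ep$traj_id == id & ep$step == 0L, ][1, ]
    d <- as.POSIXlt(e0$date)
    writeLines(sprintf("%6d%6d%6d%6d %8.3f %9.3f %8.1f",
                       d$year %% 100, d$mon + 1L, d$mday, 0L,
                       e0$lat, e0$lon,
                       ifelse(is.na(e0$height), 500, e0$height)), con)
  }
  writeLines("     1 PRESSURE", con)
  for (r in seq_len(nrow(ep))) {
    e <- ep[r, ]
    d <- as.POSIXlt(e$date)
    writeLines(sprintf(
      "%6d%6d%6d%6d%6d%6d%6d%6d %7.1f %8.3f %9.3f %8.1f %8.1f",
      e$traj_id, 1L, d$year %% 100, d$mon + 1L, d$mday,
      0L, 0L, 0L, -as.numeric(e$step), e$lat, e$lon,
      ifelse(is.na(e$height), 500, e$height), 850), con)
  }
  if (!is.null(sidecar)) {
    arr <- ep[!duplicated(ep$traj_id), c("traj_id", "date", "site")]
    utils::write.csv(arr, sidecar, row.names = FALSE)
  }
  invisible(path)
}
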