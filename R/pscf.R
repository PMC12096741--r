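# Potential Source Contribution Function: PSCF_ij = m_ij / n_ij on a
# latitude-longitude grid, where n counts trajectories with at least one
# endpoint in cell (i,j) and m counts the subset arriving on exceedance
# days.  A weighting function damps cells visited by few trajectories.

#' Flag pollution-exceedance arrival days
#'
#' @param samples a \code{pah_samples} table
#' @param threshold PM2.5 threshold, ug/m3 (strict ">")
#' @return data.frame with site, date, exceed
#' @export
flag_exceedance_days <- function(samples, threshold = 35) {
  if (threshold <= 0) stop("threshold must be > 0")
  data.frame(site = as.character(samples$site), date = samples$date,
             exceed = samples$pm25 > threshold)
}

#' Compute the PSCF grid from trajectories and exceedance flags
#'
#' Each trajectory increments n once in every grid cell containing at least
#' one of its endpoints (endpoint-count mode available via
#' \code{count = "endpoint"}); trajectories arriving on flagged days
#' likewise increment m.  PSCF = m/n where n > 0, undefined (NA) elsewhere.
#'
#' @param traj a \code{trajectory_set}
#' @param flags data.frame from \code{flag_exceedance_days}; every arrival
#'   site-day in \code{traj} must be present (trajectories with site "all"
#'   are matched on date alone)
#' @param resolution cell size in degrees (default 0.5)
#' @param domain optional list(lat = c(min, max), lon = c(min, max)); when
#'   NULL the grid auto-fits the endpoints with a one-cell margin; endpoints
#'   outside an explicit domain are dropped with a message
#' @param count "trajectory" (default) or "endpoint"
#' @return object of class \code{pscf_grid}; its \code{as.data.frame} method
#'   gives the long-format table (lat_idx, lon_idx, cell centers, n, m,
#'   pscf, wpscf)
#' @export
compute_pscf <- function(traj, flags, resolution = 0.5, domain = NULL,
                         count = c("trajectory", "endpoint")) {
  count <- match.arg(count)
  ep <- traj$endpoints
  if (!nrow(ep)) stop("trajectory set has no endpoints")

  key_ep <- if (all(ep$site == "all")) as.character(ep$date) else
    paste(ep$site, ep$date)
  key_fl <- if (all(ep$site == "all")) as.character(flags$date) else
    paste(flags$site, flags$date)
  # pooled across sites: a date is flagged if any site exceeded that day
  fl <- tapply(flags$exceed, key_fl, any)
  idx <- match(key_ep, names(fl))
  if (anyNA(idx))
    stop("no exceedance flag for arrival ", key_ep[which(is.na(idx))[1]])
  ep$exceed <- as.logical(fl[idx])

  if (is.null(domain)) {
    lat_lo <- floor(min(ep$lat) / resolution) * resolution - resolution
    lat_hi <- ceiling(max(ep$lat) / resolution) * resolution + resolution
    lon_lo <- floor(min(ep$lon) / resolution) * resolution - resolution
    lon_hi <- ceiling(max(ep$lon) / resolution) * resolution + resolution
  } else {
    lat_lo <- domain$lat[1]; lat_hi <- domain$lat[2]
    lon_lo <- domain$lon[1]; lon_hi <- domain$lon[2]
    out_dom <- ep$lat < lat_lo | ep$lat > lat_hi |
      ep$lon < lon_lo | ep$lon > lon_hi
    if (any(out_dom)) {
      message("dropping ", sum(out_dom), " endpoint(s) outside the domain")
      ep <- ep[!out_dom, , drop = FALSE]
      if (!nrow(ep)) stop("no endpoints left inside the domain")
    }
  }
  lat_edges <- seq(lat_lo, lat_hi, by = resolution)
  lon_edges <- seq(lon_lo, lon_hi, by = resolution)
  if (utils::tail(lat_edges, 1) < lat_hi)
    lat_edges <- c(lat_edges, utils::tail(lat_edges, 1) + resolution)
  if (utils::tail(lon_edges, 1) < lon_hi)
    lon_edges <- c(lon_edges, utils::tail(lon_edges, 1) + resolution)

  li <- findInterval(ep$lat, lat_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  lo <- findInterval(ep$lon, lon_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  nlat <- length(lat_edges) - 1L
  nlon <- length(lon_edges) - 1L
  cell <- (li - 1L) * nlon + lo

  if (count == "trajectory") {
    visits <- unique(data.frame(traj_id = ep$traj_id, cell = cell,
                                exceed = ep$exceed))
  } else {
    visits <- data.frame(traj_id = ep$traj_id, cell = cell,
                         exceed = ep$exceed)
  }
  tn <- table(visits$cell)
  tm <- table(visits$cell[visits$exceed])
  # cell = (li-1)*nlon + lo, decoded back into (lat_idx, lon_idx)
  nmat <- matrix(0L, nlat, nlon); mmat <- matrix(0L, nlat, nlon)
  nmat[cbind((as.integer(names(tn)) - 1L) %/% nlon + 1L,
             (as.integer(names(tn)) - 1L) %% nlon + 1L)] <- as.integer(tn)
  if (length(tm))
    mmat[cbind((as.integer(names(tm)) - 1L) %/% nlon + 1L,
               (as.integer(names(tm)) - 1L) %% nlon + 1L)] <- as.integer(tm)
  pscf <- ifelse(nmat > 0, mmat / nmat, NA_real_)

  structure(list(lat_edges = lat_edges, lon_edges = lon_edges,
                 n = nmat, m = mmat, pscf = pscf, wpscf = NULL,
                 threshold = attr(flags, "threshold"),
                 resolution = resolution, count = count),
            class = "pscf_grid")
}

#' Apply the low-count weighting to a PSCF grid
#'
#' WPSCF = W(n) * PSCF with W piecewise on n relative to the mean count over
#' nonempty cells: 1.0 above 3x the mean, 0.7 on (1.5x, 3x], 0.42 on
#' (1x, 1.5x], 0.05 at or below the mean.
#'
#' @param grid a \code{pscf_grid}
#' @param breaks multipliers of the mean nonempty-cell count
#' @param weights weights for the four bands, lowest band first
#' @return the grid with \code{wpscf} filled
#' @export
weight_pscf <- function(grid, breaks = c(1, 1.5, 3),
                        weights = c(0.05, 0.42, 0.7, 1.0)) {
  if (length(weights) != length(breaks) + 1L)
    stop("need one more weight than breaks")
  n <- grid$n
  nonempty <- n[n > 0]
  if (!length(nonempty)) { grid$wpscf <- grid$pscf; return(grid) }
  mu <- mean(nonempty)
  band <- findInterval(n, mu * breaks, left.open = TRUE) + 1L
  w <- matrix(weights[band], nrow(n), ncol(n))
  grid$wpscf <- w * grid$pscf
  grid
}

#' @export
as.data.frame.pscf_grid <- function(x, ...) {
  nlat <- nrow(x$n); nlon <- ncol(x$n)
  lat_c <- (x$lat_edges[-1] + x$lat_edges[-length(x$lat_edges)]) / 2
  lon_c <- (x$lon_edges[-1] + x$lon_edges[-length(x$lon_edges)]) / 2
  df <- expand.grid(lat_idx = seq_len(nlat), lon_idx = seq_len(nlon))
  df$lat <- lat_c[df$lat_idx]
  df$lon <- lon_c[df$lon_idx]
  df$n <- x$n[cbind(df$lat_idx, df$lon_idx)]
  df$m <- x$m[cbind(df$lat_idx, df$lon_idx)]
  df$pscf <- x$pscf[cbind(df$lat_idx, df$lon_idx)]
  df$wpscf <- if (is.null(x$wpscf)) NA_real_ else
    x$wpscf[cbind(df$lat_idx, df$lon_idx)]
  df
}

#' @export
print.pscf_grid <- function(x, ...) {
  cat("<pscf_grid> ", nrow(x$n), "x", ncol(x$n), " cells at ",
      x$resolution, " deg; ", sum(x$n > 0), " visited\n", sep = "")
  invisible(x)
}
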