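# Brute-force PSCF oracle: enumerate trajectories one by one on an explicit
# grid, counting cell visits per trajectory with de-duplication by hand.
pscf_oracle <- function(traj, flagged_ids, lat_edges, lon_edges) {
  nlat <- length(lat_edges) - 1L
  nlon <- length(lon_edges) - 1L
  n <- m <- matrix(0L, nlat, nlon)
  for (id in unique(traj$endpoints$traj_id)) {
    ep <- traj$endpoints[traj$endpoints$traj_id == id, ]
    seen <- matrix(FALSE, nlat, nlon)
    for (r in seq_len(nrow(ep))) {
      li <- max(1L, min(nlat, findInterval(ep$lat[r], lat_edges,
                                           rightmost.closed = TRUE)))
      lo <- max(1L, min(nlon, findInterval(ep$lon[r], lon_edges,
                                           rightmost.closed = TRUE)))
      seen[li, lo] <- TRUE
    }
    n <- n + seen
    if (id %in% flagged_ids) m <- m + seen
  }
  list(n = n, m = m, pscf = ifelse(n > 0, m / n, NA_real_))
}

# flags for a set of site-days, arbitrary pm25 backing
flags_for <- function(dates, exceed) {
  data.frame(site = "all", date = as.Date(dates), exceed = exceed)
}

test_that("pscf equals exhaustive enumeration on small configurations", {
  set.seed(101)
  for (rep in 1:4) {
    n_traj <- sample(3:5, 1)
    paths <- lapply(seq_len(n_traj), function(i)
      data.frame(lat = 40 + cumsum(runif(sample(4:10, 1), -0.8, 0.8)),
                 lon = 110 + cumsum(runif(1, -0.8, 0.8))))
    # re-draw lon with same length as lat
    paths <- lapply(paths, function(p)
      data.frame(lat = p$lat,
                 lon = 110 + cumsum(runif(nrow(p), -0.8, 0.8))))
    dates <- as.Date("2020-01-01") + seq_len(n_traj)
    tr <- make_traj(paths, dates)
    exceed <- runif(n_traj) < 0.5
    fl <- flags_for(dates, exceed)
    dom <- list(lat = c(28, 52), lon = c(98, 122))
    g <- compute_pscf(tr, fl, resolution = 3, domain = dom)
    oracle <- pscf_oracle(tr, which(exceed), g$lat_edges, g$lon_edges)
    expect_equal(unname(g$n), unname(oracle$n), ignore_attr = TRUE)
    expect_equal(unname(g$m), unname(oracle$m), ignore_attr = TRUE)
    expect_equal(g$pscf, oracle$pscf, ignore_attr = TRUE)
  }
})

test_that("pscf arithmetic, bounds and undefined cells follow the definition", {
  # 10 straight trajectories through one corridor, 4 flagged
  paths <- lapply(1:10, function(i)
    data.frame(lat = c(40.1, 40.2, 40.3), lon = c(110.1, 110.2, 110.3)))
  dates <- as.Date("2020-01-01") + 1:10
  tr <- make_traj(paths, dates)
  fl <- flags_for(dates, c(rep(TRUE, 4), rep(FALSE, 6)))
  g <- compute_pscf(tr, fl, resolution = 1)
  visited <- g$n > 0
  expect_equal(unique(g$pscf[visited]), 0.4)
  expect_true(all(is.na(g$pscf[!visited])))
  expect_true(all(g$m <= g$n))

  # all trajectories flagged -> pscf = 1 wherever defined
  fl1 <- flags_for(dates, rep(TRUE, 10))
  g1 <- compute_pscf(tr, fl1, resolution = 1)
  expect_true(all(g1$pscf[g1$n > 0] == 1))
})

test_that("exceedance flags use the strict threshold convention", {
  s <- tiny_samples(n = 3, pm25 = c(40, 35, 30))
  fl <- flag_exceedance_days(s, 35)
  expect_equal(fl$exceed, c(TRUE, FALSE, FALSE))
})

test_that("weighting damps low-count cells per the piecewise scheme", {
  # hand-built grid: counts 1, 2, 3, 12 over four cells; mean nonempty = 4.5
  g <- structure(list(
    lat_edges = c(0, 1, 2), lon_edges = c(0, 1, 2),
    n = matrix(c(1L, 2L, 3L, 12L), 2, 2),
    m = matrix(c(1L, 1L, 3L, 6L), 2, 2),
    pscf = matrix(c(1, 0.5, 1, 0.5), 2, 2),
    wpscf = NULL, threshold = 35, resolution = 1, count = "trajectory"),
    class = "pscf_grid")
  gw <- weight_pscf(g)
  # all n <= mean except 12 which is in (1.5*mean, 3*mean] -> 0.7
  expect_equal(gw$wpscf[1, 1], 0.05 * 1)
  expect_equal(gw$wpscf[2, 1], 0.05 * 0.5)
  expect_equal(gw$wpscf[1, 2], 0.05 * 1)
  expect_equal(gw$wpscf[2, 2], 0.7 * 0.5)
  expect_true(all(gw$wpscf <= gw$pscf, na.rm = TRUE))

  # uniform counts: every cell in the lowest band
  gu <- g
  gu$n <- matrix(4L, 2, 2)
  gu$pscf <- matrix(0.8, 2, 2)
  expect_true(all(weight_pscf(gu)$wpscf == 0.05 * 0.8))

  # a cell above 3x the mean keeps its full pscf
  gh <- g
  gh$n <- matrix(c(1L, 1L, 1L, 40L), 2, 2)
  gh$pscf <- matrix(0.6, 2, 2)
  expect_equal(weight_pscf(gh)$wpscf[2, 2], 0.6)
})

test_that("grid refinement can only grow the summed visit counts", {
  set.seed(55)
  paths <- lapply(1:6, function(i)
    data.frame(lat = 40 + cumsum(runif(12, -0.5, 0.5)),
               lon = 110 + cumsum(runif(12, -0.5, 0.5))))
  dates <- as.Date("2020-03-01") + 1:6
  tr <- make_traj(paths, dates)
  fl <- flags_for(dates, rep(TRUE, 6))
  dom <- list(lat = c(34, 46), lon = c(104, 116))
  coarse <- compute_pscf(tr, fl, resolution = 4, domain = dom)
  fine <- compute_pscf(tr, fl, resolution = 1, domain = dom)
  # a trajectory may enter several children of one parent cell, so the
  # summed fine counts dominate the coarse ones
  expect_gte(sum(fine$n), sum(coarse$n))
})

test_that("designated source sectors outscore background cells", {
  spec <- synthetic_spec(n_days = 150, n_sites = 1, seed = 106,
                         source_sectors = list(list(lat = c(47, 48),
                                                    lon = c(98, 99),
                                                    weight = 1)))
  gen <- generate_samples(spec)
  trj <- generate_trajectories(spec, gen$samples)
  fl <- flag_exceedance_days(gen$samples, spec$pm25_threshold)
  grid <- weight_pscf(compute_pscf(trj, fl, resolution = 0.5))
  df <- as.data.frame(grid)
  df <- df[df$n > 0, ]
  insec <- df$lat >= 47 & df$lat <= 48 & df$lon >= 98 & df$lon <= 99
  expect_gt(median(df$wpscf[insec]), median(df$wpscf[!insec]))
})

test_that("endpoints outside an explicit domain are dropped with a note", {
  paths <- list(data.frame(lat = c(40, 41, 60), lon = c(110, 111, 150)))
  tr <- make_traj(paths, as.Date("2020-01-02"))
  fl <- flags_for(as.Date("2020-01-02"), TRUE)
  expect_message(
    g <- compute_pscf(tr, fl, resolution = 1,
                      domain = list(lat = c(38, 44), lon = c(108, 114))),
    "dropping 1")
  expect_equal(sum(g$n > 0), 2)
})

test_that("missing arrival flags are an error", {
  paths <- list(data.frame(lat = c(40, 41), lon = c(110, 111)))
  tr <- make_traj(paths, as.Date("2020-01-02"))
  fl <- flags_for(as.Date("2020-01-03"), TRUE)
  expect_error(compute_pscf(tr, fl, resolution = 1), "no exceedance flag")
})
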