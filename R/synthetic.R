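# Synthetic site-day PAH series with known latent source structure.
#
# Forward model: x = G F, elementwise-multiplied by lognormal measurement
# noise.  Contributions g >= 0 carry a winter-peaking seasonal cycle for
# combustion-type factors and a flat cycle for traffic-type factors;
# temperature follows a summer-peaking sinusoid so that the rank correlation
# between temperature and total PAHs is negative; PM2.5 is total PAHs
# divided by a fixed PAH:PM2.5 mass ratio plus additive noise.  Trajectories
# are schematic straight lines from a sampled origin to the receptor with
# Gaussian jitter; exceedance-day origins are drawn inside designated source
# sectors.

#' Default ground-truth source profiles
#'
#' A 5 x 16 nonnegative matrix (rows sum to 1) mimicking the marker structure
#' of the five urban source types: biomass burning (Chr, BaA, BaP), gasoline
#' traffic (Flu, BkF, BaP, BghiP, IcdP), steel industry (Ace, DahA, IcdP),
#' coal combustion (Phe, Flua, Pyr, Chr) and diesel traffic (Ant, BaA,
#' BghiP).
#'
#' @return numeric matrix, factors x species
#' @export
default_true_profiles <- function() {
  codes <- pah_codes()
  f <- matrix(0.01, 5, 16, dimnames = list(
    c("biomass", "gasoline", "steel", "coal", "diesel"), codes))
  put <- function(row, sp, w) { f[row, sp] <<- w; invisible() }
  put("biomass", c("Chr", "BaA", "BaP"), c(0.30, 0.28, 0.22))
  put("gasoline", c("Flu", "BkF", "BaP", "BghiP", "IcdP"),
      c(0.12, 0.18, 0.14, 0.22, 0.20))
  put("steel", c("Ace", "DahA", "IcdP"), c(0.25, 0.38, 0.20))
  put("coal", c("Phe", "Flua", "Pyr", "Chr"), c(0.18, 0.28, 0.24, 0.18))
  put("diesel", c("Ant", "BaA", "BghiP"), c(0.28, 0.26, 0.28))
  sweep(f, 1, rowSums(f), "/")
}

#' Specification for the synthetic generator
#'
#' Defaults emulate a six-year (2017-2022) urban monitoring campaign: 446
#' sampling days at 2 sites (892 site-day records), 5 latent source factors
#' whose combustion members peak in winter, multiplicative lognormal noise
#' with CV 0.3, below-detection-limit censoring, and back trajectories whose
#' exceedance-day origins concentrate in two designated source sectors
#' north/west of the receptor.
#'
#' @param n_days number of sampling days
#' @param n_sites number of sites (labelled "A", "B", ...)
#' @param n_factors number of latent factors (rows of true_profiles used)
#' @param true_profiles factor x species nonnegative matrix
#' @param factor_means mean contribution of each factor (ng/m3 of total PAH
#'   per factor at season multiplier 1)
#' @param seasonal vector flagging factors that carry the winter-peaking
#'   seasonal cycle
#' @param seasonal_amplitude relative amplitude of the winter cycle in [0,1)
#' @param seasonal_phase per-factor day-of-year of the winter peak (heating
#'   onset differs between source types)
#' @param contrib_sdlog log-sd of the independent day-to-day lognormal
#'   variation of factor contributions; the default 1.0 reproduces the
#'   strong right skew (75th percentile several times the median) typical
#'   of daily urban PAH series
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise
#' @param censor apply below-MDL censoring to the generated series?
#' @param censor_policy substitution policy when \code{censor} is TRUE
#' @param pm_ratio total-PAH to PM2.5 mass ratio (ng PAH per ug PM2.5)
#' @param pm25_threshold PM2.5 exceedance threshold used to steer trajectory
#'   origins (ug/m3)
#' @param receptor c(lat, lon) of the monitoring site
#' @param domain list(lat = c(min, max), lon = c(min, max)) trajectory domain
#' @param source_sectors list of sectors, each
#'   list(lat = c(min,max), lon = c(min,max), weight); weights sum to 1
#' @param n_steps endpoints per trajectory (hourly, arrival = step 0)
#' @param jitter_sd endpoint jitter standard deviation, degrees
#' @param start_date first calendar day of the campaign
#' @param end_date last calendar day of the campaign
#' @param seed integer seed
#' @return object of class \code{synthetic_spec}
#' @export
synthetic_spec <- function(n_days = 446, n_sites = 2, n_factors = 5,
                           true_profiles = default_true_profiles(),
                           factor_means = c(1.4, 1.5, 0.45, 2.6, 1.1),
                           seasonal = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                           seasonal_amplitude = 0.8,
                           seasonal_phase = c(5, 0, 30, 15, 0),
                           contrib_sdlog = 1.0,
                           noise_cv = 0.3,
                           censor = TRUE,
                           censor_policy = "substitute-mdl",
                           pm_ratio = 0.25,
                           pm25_threshold = 35,
                           receptor = c(40.8, 111.7),
                           domain = list(lat = c(35, 50), lon = c(95, 120)),
                           source_sectors = list(
                             list(lat = c(44, 49), lon = c(100, 110),
                                  weight = 0.6),
                             list(lat = c(37, 41), lon = c(104, 110),
                                  weight = 0.4)),
                           n_steps = 24, jitter_sd = 0.3,
                           start_date = as.Date("2017-01-01"),
                           end_date = as.Date("2022-12-31"),
                           seed = 20170101) {
  true_profiles <- as.matrix(true_profiles)
  if (n_factors > ncol(true_profiles))
    stop("n_factors exceeds the number of species")
  if (n_factors > nrow(true_profiles))
    stop("true_profiles has fewer rows than n_factors")
  true_profiles <- true_profiles[seq_len(n_factors), , drop = FALSE]
  if (any(true_profiles < 0)) stop("true_profiles must be nonnegative")
  if (any(rowSums(true_profiles > 0) == 0))
    stop("every factor needs at least one strictly positive species")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  w <- vapply(source_sectors, function(s) s$weight, numeric(1))
  if (length(w) && abs(sum(w) - 1) > 1e-9)
    stop("source sector weights must sum to 1")
  spec <- list(n_days = n_days, n_sites = n_sites, n_factors = n_factors,
               true_profiles = true_profiles,
               factor_means = rep_len(factor_means, n_factors),
               seasonal = rep_len(seasonal, n_factors),
               seasonal_amplitude = seasonal_amplitude,
               seasonal_phase = rep_len(seasonal_phase, n_factors),
               contrib_sdlog = contrib_sdlog,
               noise_cv = noise_cv, censor = censor,
               censor_policy = censor_policy, pm_ratio = pm_ratio,
               pm25_threshold = pm25_threshold, receptor = receptor,
               domain = domain, source_sectors = source_sectors,
               n_steps = n_steps, jitter_sd = jitter_sd,
               start_date = as.Date(start_date), end_date = as.Date(end_date),
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

# Winter-peaking multiplier in [1-A, 1+A]; peak near the given day-of-year.
season_multiplier <- function(dates, amplitude, peak_doy = 15) {
  doy <- as.numeric(format(dates, "%j"))
  1 + amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
}

#' Generate a synthetic sample series with ground truth
#'
#' @param spec a \code{synthetic_spec}
#' @param catalog species catalogue used for censoring
#' @return list with elements \code{samples} (a \code{pah_samples} table),
#'   \code{g} (true sample x factor contributions), \code{f} (true factor x
#'   species profiles), \code{conc_true} (noise-free, uncensored G F) and
#'   \code{spec}
#' @export
generate_samples <- function(spec, catalog = default_catalog()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  k <- spec$n_factors
  f <- spec$true_profiles

  span <- seq(spec$start_date, spec$end_date, by = "day")
  days <- sort(sample(span, min(spec$n_days, length(span))))
  sites <- LETTERS[seq_len(spec$n_sites)]
  grid <- expand.grid(site = sites, date = days, stringsAsFactors = FALSE)
  grid <- grid[order(grid$date, grid$site), ]
  n <- nrow(grid)

  sdlog_g <- spec$contrib_sdlog
  g <- matrix(0, n, k, dimnames = list(NULL, rownames(f)))
  for (j in seq_len(k)) {
    mult <- if (spec$seasonal[j])
      season_multiplier(grid$date, spec$seasonal_amplitude,
                        spec$seasonal_phase[j])
    else rep(1, n)
    g[, j] <- spec$factor_means[j] * mult *
      stats::rlnorm(n, meanlog = -sdlog_g^2 / 2, sdlog = sdlog_g)
  }

  conc_true <- g %*% f
  colnames(conc_true) <- colnames(f)
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    noise <- matrix(stats::rlnorm(n * ncol(f), meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog), n, ncol(f))
    conc <- conc_true * noise
  } else {
    conc <- conc_true
  }

  doy <- as.numeric(format(grid$date, "%j"))
  temp <- 6 + 17 * cos(2 * pi * (doy - 196) / 365.25) + stats::rnorm(n, 0, 3)
  pressure <- 890 + 6 * cos(2 * pi * (doy - 15) / 365.25) +
    stats::rnorm(n, 0, 3)
  rh <- pmin(98, pmax(5, 48 + 15 * cos(2 * pi * (doy - 210) / 365.25) +
                        stats::rnorm(n, 0, 8)))
  pm25 <- pmax(1, rowSums(conc) / spec$pm_ratio + stats::rnorm(n, 0, 5))

  df <- data.frame(date = grid$date, site = grid$site, pm25 = pm25,
                   as.data.frame(conc), temp = temp, pressure = pressure,
                   rh = rh, check.names = FALSE)
  policy <- if (spec$censor) spec$censor_policy else "leave-zero"
  samples <- if (spec$censor) {
    as_pah_samples(df, catalog = catalog, censor_policy = spec$censor_policy)
  } else {
    # bypass censoring entirely: keep raw values, flags all FALSE
    out <- as_pah_samples(df, catalog = catalog, censor_policy = "leave-zero")
    out[, pah_codes()] <- conc
    out[, paste0("cens_", pah_codes())] <- FALSE
    out
  }
  list(samples = samples, g = g, f = f, conc_true = conc_true, spec = spec)
}

runif_in <- function(n, rng) stats::runif(n, rng[1], rng[2])

#' Generate schematic back trajectories for a sample series
#'
#' One trajectory per site-day.  On days whose PM2.5 exceeds the spec
#' threshold the origin is drawn inside one of the designated source sectors
#' (chosen by emission weight); otherwise the origin is uniform over the
#' domain.  Endpoints interpolate linearly from origin (oldest step) to the
#' receptor (step 0) with Gaussian jitter everywhere except the arrival
#' point.
#'
#' @param spec a \code{synthetic_spec}
#' @param samples a \code{pah_samples} table generated from \code{spec}
#' @return a \code{trajectory_set}
#' @export
generate_trajectories <- function(spec, samples) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!length(spec$source_sectors))
    stop("source_sectors must be non-empty")
  set.seed(spec$seed + 1L)
  n <- nrow(samples)
  exceed <- samples$pm25 > spec$pm25_threshold
  wts <- vapply(spec$source_sectors, function(s) s$weight, numeric(1))

  steps <- seq.int(0L, spec$n_steps - 1L)
  frac <- steps / max(1L, spec$n_steps - 1L)
  eps <- list()
  for (i in seq_len(n)) {
    if (exceed[i]) {
      sec <- spec$source_sectors[[sample.int(length(wts), 1, prob = wts)]]
      origin <- c(runif_in(1, sec$lat), runif_in(1, sec$lon))
    } else {
      origin <- c(runif_in(1, spec$domain$lat), runif_in(1, spec$domain$lon))
    }
    lat <- spec$receptor[1] + frac * (origin[1] - spec$receptor[1])
    lon <- spec$receptor[2] + frac * (origin[2] - spec$receptor[2])
    if (spec$jitter_sd > 0) {
      # receptor and origin anchor the interpolation; only the transit
      # points meander
      jit <- ifelse(steps == 0L | steps == max(steps), 0, 1)
      lat <- lat + jit * stats::rnorm(length(steps), 0, spec$jitter_sd)
      lon <- lon + jit * stats::rnorm(length(steps), 0, spec$jitter_sd)
    }
    eps[[i]] <- data.frame(
      traj_id = i, date = samples$date[i], site = samples$site[i],
      step = steps, lat = pmin(90, pmax(-90, lat)),
      lon = pmin(180, pmax(-180, lon)), height = 500)
  }
  trajectory_set(do.call(rbind, eps),
                 metadata = list(run_length_h = spec$n_steps - 1L,
                                 arrival_height_m = 500,
                                 n_traj = n))
}
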