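# Shared fixtures: tiny in-memory sample tables and trajectory sets.

# A data.frame in the standard sample-table layout.  `conc` is a single
# value recycled over all 16 species, or a named list of per-species
# overrides on top of `fill`.
make_sample_df <- function(n = 3, pm25 = 30, conc = NULL, fill = 5,
                           dates = NULL, site = "A", met = FALSE) {
  codes <- pah_codes()
  if (is.null(dates))
    dates <- seq(as.Date("2020-01-01"), by = "day", length.out = n)
  df <- data.frame(date = dates, site = rep_len(site, n),
                   pm25 = rep_len(pm25, n))
  vals <- stats::setNames(rep(fill, 16), codes)
  if (!is.null(conc)) vals[names(conc)] <- unlist(conc)
  for (cc in codes) df[[cc]] <- rep_len(vals[[cc]], n)
  if (met) {
    df$temp <- seq(-10, 20, length.out = n)
    df$pressure <- 890
    df$rh <- 50
  }
  df
}

tiny_samples <- function(..., censor_policy = "substitute-mdl") {
  as_pah_samples(make_sample_df(...), censor_policy = censor_policy)
}

# A hand-built trajectory set: `paths` is a list of data.frames with lat,
# lon per step; arrival metadata supplied alongside.
make_traj <- function(paths, dates, sites = "all") {
  sites <- rep_len(sites, length(paths))
  eps <- do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    data.frame(traj_id = i, date = as.Date(dates[[i]]), site = sites[i],
               step = seq_len(nrow(p)) - 1L, lat = p$lat, lon = p$lon,
               height = 500)
  }))
  trajectory_set(eps)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Best-match cosine similarity of each true profile row against any
# recovered row (maximum-similarity assignment).
profile_recovery <- function(f_true, f_hat) {
  vapply(seq_len(nrow(f_true)), function(i)
    max(vapply(seq_len(nrow(f_hat)), function(k)
      cosine_sim(f_true[i, ], f_hat[k, ]), numeric(1))), numeric(1))
}
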