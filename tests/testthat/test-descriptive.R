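test_that("median and quartiles use linear interpolation", {
  s <- tiny_samples(n = 5, pm25 = c(1, 2, 3, 4, 5))
  out <- pah_summary(s, fields = "pm25", by = "all")
  expect_equal(out$median, 3)
  expect_equal(out$p25, 2)
  expect_equal(out$p75, 4)

  s1 <- tiny_samples(n = 1, pm25 = 7)
  out1 <- pah_summary(s1, fields = "pm25", by = "all")
  expect_equal(unlist(out1[, c("median", "p25", "p75")]),
               c(median = 7, p25 = 7, p75 = 7))

  sc <- tiny_samples(n = 10, conc = list(Phe = 3.60))
  outc <- pah_summary(sc, fields = "Phe", by = "all")
  expect_equal(outc$median, 3.60)
})

test_that("quantiles agree with a sort-based oracle on all sizes <= 8", {
  # oracle: type-7 linear interpolation between order statistics, by hand
  oracle_q <- function(v, p) {
    v <- sort(v)
    h <- (length(v) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  set.seed(42)
  for (n in 1:8) {
    for (rep in 1:5) {
      v <- round(runif(n, 0, 10), 2)
      s <- tiny_samples(n = n, pm25 = v)
      out <- pah_summary(s, fields = "pm25", by = "all")
      expect_equal(out$median, oracle_q(v, 0.5))
      expect_equal(out$p25, oracle_q(v, 0.25))
      expect_equal(out$p75, oracle_q(v, 0.75))
    }
  }
})

test_that("exceedance counting is strict and rounds to 2 decimals", {
  s <- tiny_samples(n = 3, pm25 = c(36, 35, 34))
  rep <- exceedance(s, 35)
  expect_equal(rep$n_exceed, 1)

  # 213 of 892 -> 23.88%
  s2 <- tiny_samples(n = 892, pm25 = c(rep(40, 213), rep(30, 679)))
  rep2 <- exceedance(s2, 35)
  expect_equal(rep2$n_exceed, 213)
  expect_equal(rep2$rate, 23.88)

  s3 <- tiny_samples(n = 100, pm25 = 10)
  expect_equal(exceedance(s3, 35)$rate, 0)
})

test_that("exceedance is order-invariant and strata sum to the pooled count", {
  set.seed(7)
  df <- make_sample_df(n = 60, pm25 = runif(60, 20, 60),
                       dates = sample(seq(as.Date("2019-01-01"),
                                          as.Date("2021-12-31"), by = "day"),
                                      60))
  s <- as_pah_samples(df)
  pooled <- exceedance(s, 35, by = "all")
  by_year <- exceedance(s, 35, by = "year")
  expect_equal(sum(by_year$n_exceed), pooled$n_exceed)

  shuf <- as_pah_samples(df[sample(nrow(df)), ])
  expect_equal(exceedance(shuf, 35, by = "all")$n_exceed, pooled$n_exceed)
})

test_that("molecular-weight fractions are mass-weighted and sum to one", {
  s <- tiny_samples(n = 2, fill = 0, conc = list(BaP = 4),
                    censor_policy = "leave-zero")
  out <- mw_proportions(s)
  expect_equal(out$HMW, 1)

  s2 <- tiny_samples(n = 2, fill = 0, conc = list(Nap = 3, Pyr = 3),
                     censor_policy = "leave-zero")
  out2 <- mw_proportions(s2)
  expect_equal(out2$LMW, 0.5)
  expect_equal(out2$MMW, 0.5)
  expect_equal(out2$HMW, 0)

  set.seed(1)
  df <- make_sample_df(n = 40, fill = 2,
                       dates = c(seq(as.Date("2019-06-01"), by = "day",
                                     length.out = 20),
                                 seq(as.Date("2020-06-01"), by = "day",
                                     length.out = 20)))
  s3 <- as_pah_samples(df)
  out3 <- mw_proportions(s3)
  expect_equal(out3$LMW + out3$MMW + out3$HMW, rep(1, 2), tolerance = 1e-9)
})

test_that("doubling MMW profile mass doubles the MMW-fraction ratio", {
  base <- synthetic_spec(n_days = 200, n_sites = 1, seed = 14, censor = FALSE,
                         noise_cv = 0.1)
  gen <- generate_samples(base)
  mmw_codes <- c("Flua", "Pyr", "Chr", "BaA")
  f2 <- base$true_profiles
  f2[, mmw_codes] <- 2 * f2[, mmw_codes]
  spec2 <- synthetic_spec(n_days = 200, n_sites = 1, seed = 14,
                          censor = FALSE, noise_cv = 0.1, true_profiles = f2)
  gen2 <- generate_samples(spec2)
  # same seed -> identical contributions; only the MMW block is doubled
  m1 <- colSums(conc_matrix(gen$samples))
  m2 <- colSums(conc_matrix(gen2$samples))
  expect_equal(sum(m2[mmw_codes]) / sum(m1[mmw_codes]), 2, tolerance = 0.05)
})

test_that("rank correlations behave on monotone and null cases", {
  s <- tiny_samples(n = 30, pm25 = 1:30, met = TRUE)
  s$temp <- 2 * s$pm25
  cm <- correlation_matrix(s, c("pm25", "temp"))
  expect_equal(cm$rho["pm25", "temp"], 1)
  expect_true(isSymmetric(cm$rho))
  expect_equal(diag(cm$rho), c(pm25 = 1, temp = 1))

  s$temp <- -s$pm25
  cm2 <- correlation_matrix(s, c("pm25", "temp"))
  expect_equal(cm2$rho["pm25", "temp"], -1)

  set.seed(99)
  n <- 400
  s3 <- tiny_samples(n = n, pm25 = runif(n), met = TRUE)
  s3$temp <- sample(s3$pm25)
  cm3 <- correlation_matrix(s3, c("pm25", "temp"))
  expect_lt(abs(cm3$rho["pm25", "temp"]), 2 / sqrt(n))

  s3$rh <- rep(50, n)
  cm4 <- correlation_matrix(s3, c("pm25", "rh"))
  expect_true(cm4$undefined["pm25", "rh"])
  expect_true(is.na(cm4$rho["pm25", "rh"]))
})

test_that("two-group comparison uses mid-ranks and matches exact enumeration", {
  # identical groups: no shift, p = 1 without continuity correction
  r <- suppressWarnings(rank_compare(c(1, 2, 3, 1, 2, 3),
                                     rep(c("a", "b"), each = 3)))
  expect_equal(r$method, "wilcoxon-rank-sum")
  expect_equal(r$p_value, 1)

  # fully separated n=3,3: exact p equals the enumeration over C(6,3)
  # assignments: 2 of 20 orderings are at least as extreme (two-sided)
  combs <- combn(6, 3)
  w_obs <- sum(rank(c(1, 2, 3, 101, 102, 103))[1:3]) - 6
  ws <- apply(combs, 2, function(idx) sum(rank(1:6)[idx]) - 6)
  p_exact <- mean(abs(ws - 4.5) >= abs(w_obs - 4.5))
  r2 <- rank_compare(c(1, 2, 3, 101, 102, 103), rep(c("a", "b"), each = 3))
  expect_equal(r2$p_value, p_exact)
  expect_equal(r2$p_value, 0.1)
})

test_that("three identical groups give H = 0 via Kruskal-Wallis", {
  r <- rank_compare(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(r$method, "kruskal-wallis")
  expect_equal(r$statistic, 0)
})

test_that("rank tests agree with exact enumeration for group sizes <= 5", {
  set.seed(31)
  for (rep in 1:5) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    # distinct values keep the exact (tie-free) path comparable
    v <- sample(1:1000, nx + ny)
    rk <- rank(v)
    w_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    combs <- combn(nx + ny, nx)
    ws <- apply(combs, 2, function(idx) sum(rk[idx]) - nx * (nx + 1) / 2)
    p_exact <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
    r <- rank_compare(v, rep(c("a", "b"), c(nx, ny)))
    expect_equal(r$p_value, p_exact, tolerance = 1e-10)
  }
})
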