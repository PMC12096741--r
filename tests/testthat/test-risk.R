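test_that("TEQ is the TEF-weighted concentration sum", {
  s0 <- tiny_samples(n = 1, fill = 0, censor_policy = "leave-zero")
  expect_equal(teq(s0), 0)

  s1 <- tiny_samples(n = 1, fill = 0, conc = list(BaP = 2, DahA = 1),
                     censor_policy = "leave-zero")
  expect_equal(teq(s1), 3)  # 2*1 + 1*1

  s2 <- tiny_samples(n = 1, fill = 0, conc = list(Nap = 1000),
                     censor_policy = "leave-zero")
  expect_equal(teq(s2), 1)  # 1000 * 0.001
})

test_that("TEQ is linear in concentrations", {
  set.seed(2)
  a <- tiny_samples(n = 4, fill = 0,
                    conc = as.list(setNames(runif(16, 1, 5), pah_codes())),
                    censor_policy = "leave-zero")
  b <- tiny_samples(n = 4, fill = 0,
                    conc = as.list(setNames(runif(16, 1, 5), pah_codes())),
                    censor_policy = "leave-zero")
  mix <- a
  mix[, pah_codes()] <- 2 * conc_matrix(a) + 3 * conc_matrix(b)
  expect_equal(teq(mix), 2 * teq(a) + 3 * teq(b), tolerance = 1e-12)
})

test_that("point ILCR matches the closed-form hand oracle", {
  prof <- exposure_profile("adult", ir = 15, bw = 60, ef = 350, ed = 24)
  expect_equal(ilcr_point(0, prof), 0)
  # 1 * 3.14 * 15 * 350 * 24 * 1e-6 / (60 * 25550)
  oracle <- 1 * 3.14 * 15 * 350 * 24 * 1e-6 / (60 * 25550)
  expect_equal(ilcr_point(1, prof), oracle)
  expect_equal(signif(ilcr_point(1, prof), 4), 2.581e-7)

  # homogeneity: degree 1 in TEQ, degree -1 in BW
  expect_equal(ilcr_point(2, prof), 2 * ilcr_point(1, prof))
  prof2 <- exposure_profile("adult", ir = 15, bw = 120, ef = 350, ed = 24)
  expect_equal(ilcr_point(1, prof2), ilcr_point(1, prof) / 2)
})

test_that("ILCR is homogeneous in every multiplicative input", {
  set.seed(3)
  for (rep in 1:5) {
    sc <- runif(1, 0.5, 3)
    p0 <- exposure_profile("adult")
    up <- function(...) {
      args <- utils::modifyList(list(receptor = "adult"), list(...))
      do.call(exposure_profile, args)
    }
    base <- ilcr_point(1.7, p0)
    expect_equal(ilcr_point(1.7, up(ir = p0$ir * sc)), base * sc)
    expect_equal(ilcr_point(1.7, up(ef = p0$ef * sc)), base * sc)
    expect_equal(ilcr_point(1.7, up(ed = p0$ed * sc)), base * sc)
    expect_equal(ilcr_point(1.7, up(csf = p0$csf * sc)), base * sc)
    expect_equal(ilcr_point(1.7, up(bw = p0$bw * sc)), base / sc)
    expect_equal(ilcr_point(1.7, up(at = p0$at * sc)), base / sc)
  }
})

test_that("point-mass Monte Carlo collapses to the closed form", {
  prof <- exposure_profile("adult", cv = 0)
  res <- ilcr_mc(teq_samples = 2.5, profile = prof, n_iter = 1000, seed = 1)
  expect_equal(length(res$draws), 1000)
  expect_true(all(abs(res$draws - ilcr_point(2.5, prof)) < 1e-12))
  expect_equal(unname(res$percentiles["P5"]),
               unname(res$percentiles["P95"]))
  expect_true(all(diff(res$percentiles) >= 0))
})

test_that("Monte Carlo is seed-deterministic with stable medians", {
  set.seed(10)
  tq <- rlnorm(300, 0, 0.5)
  prof <- exposure_profile("adult")
  a <- ilcr_mc(tq, prof, n_iter = 10000, seed = 4)
  b <- ilcr_mc(tq, prof, n_iter = 10000, seed = 4)
  expect_identical(a$draws, b$draws)

  c <- ilcr_mc(tq, prof, n_iter = 10000, seed = 5)
  rel <- abs(median(a$draws) - median(c$draws)) / median(a$draws)
  expect_lt(rel, 0.02)
  expect_equal(length(a$draws), 10000)
  expect_true(all(a$draws >= 0))
})

test_that("sensitivity isolates the varying input with the right sign", {
  prof <- exposure_profile("adult", cv = 0)
  # only TEQ varies
  set.seed(6)
  res <- ilcr_mc(rlnorm(200), prof, n_iter = 2000, seed = 2)
  res <- suppressMessages(risk_sensitivity(res))
  expect_equal(res$sensitivity$input, "teq")
  expect_equal(res$sensitivity$rho, 1)
  expect_equal(res$sensitivity$contribution_pct, 100)

  # only IR varies: rho = +1; only BW varies: rho = -1
  prof_ir <- exposure_profile("adult", cv = 0.2)
  res2 <- ilcr_mc(1, prof_ir, n_iter = 2000, seed = 3)
  res2$inputs$bw <- prof_ir$bw  # freeze BW ex post to isolate IR
  res2$draws <- with(res2$inputs,
                     teq * prof_ir$csf * ir * ef * ed * prof_ir$cf /
                       (bw * prof_ir$at))
  res2 <- suppressMessages(risk_sensitivity(res2))
  expect_equal(res2$sensitivity$rho[res2$sensitivity$input == "ir"], 1)

  res3 <- ilcr_mc(1, prof_ir, n_iter = 2000, seed = 3)
  res3$inputs$ir <- prof_ir$ir
  res3$draws <- with(res3$inputs,
                     teq * prof_ir$csf * ir * ef * ed * prof_ir$cf /
                       (bw * prof_ir$at))
  res3 <- suppressMessages(risk_sensitivity(res3))
  expect_equal(res3$sensitivity$rho[res3$sensitivity$input == "bw"], -1)
})

test_that("independent equal-CV inputs split the variance contribution", {
  prof <- exposure_profile("adult", cv = 0.2)
  res <- ilcr_mc(1, prof, n_iter = 10000, seed = 8)
  res <- suppressMessages(risk_sensitivity(res))
  sens <- res$sensitivity
  ir_c <- sens$contribution_pct[sens$input == "ir"]
  bw_c <- sens$contribution_pct[sens$input == "bw"]
  expect_equal(ir_c, 50, tolerance = 0.1)
  expect_equal(bw_c, 50, tolerance = 0.1)
  expect_lte(sum(sens$contribution_pct), 100 + 1e-9)
})

test_that("species shares sum to 100 and isolate dominant species", {
  s <- tiny_samples(n = 3, fill = 0, conc = list(BaP = 2),
                    censor_policy = "leave-zero")
  sh <- species_risk_shares(s)
  expect_equal(unname(sh["BaP"]), 100)

  s2 <- tiny_samples(n = 3, fill = 0, conc = list(BaP = 5, DahA = 5),
                     censor_policy = "leave-zero")
  sh2 <- species_risk_shares(s2)
  expect_equal(unname(sh2["BaP"]), 50)
  expect_equal(unname(sh2["DahA"]), 50)

  spec <- synthetic_spec(n_days = 40, n_sites = 1, noise_cv = 0,
                         censor = FALSE, seed = 13)
  gen <- generate_samples(spec)
  sh3 <- species_risk_shares(gen$samples)
  expect_equal(sum(sh3), 100, tolerance = 1e-9)
  tef <- setNames(default_catalog()$tef, default_catalog()$code)
  manual <- 100 * colSums(gen$g %*% gen$f) * tef[colnames(gen$f)] /
    sum(colSums(gen$g %*% gen$f) * tef[colnames(gen$f)])
  expect_equal(sh3, manual[names(sh3)], tolerance = 1e-9)

  s0 <- tiny_samples(n = 2, fill = 0, censor_policy = "leave-zero")
  expect_error(species_risk_shares(s0), "zero")
})

test_that("degenerate all-zero TEQ warns and yields zero risk", {
  prof <- exposure_profile("child")
  expect_warning(res <- ilcr_mc(rep(0, 5), prof, n_iter = 1000, seed = 1),
                 "zero")
  expect_true(all(res$draws == 0))
})
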