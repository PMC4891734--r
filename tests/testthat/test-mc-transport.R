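test_that("elementary samplers follow their closed forms", {
  expect_equal(sample_step(1, exp(-1)), 1)
  u <- c(0.1, 0.5, 0.9)
  expect_equal(sample_step(2, u), sample_step(1, u) / 2)
  expect_error(sample_step(1, 0), "u")
  expect_error(sample_step(1, 1.2), "u")

  set.seed(1)
  u <- runif(2e5)
  # law of large numbers: sample mean of the step within 3 sigma
  expect_lt(abs(mean(sample_step(0.5, u)) - 2), 3 * 2 / sqrt(2e5))

  expect_equal(sample_hg_deflection(0, c(0.25, 0.5, 1 - 1e-9)),
               c(-0.5, 0, 1), tolerance = 1e-6)
  ct <- sample_hg_deflection(0.9, u)
  expect_true(all(ct >= -1 & ct <= 1))
  # defining property of g: mean deflection cosine (sd of HG(0.9) ~ 0.17)
  expect_lt(abs(mean(ct) - 0.9), 3 * stats::sd(ct) / sqrt(length(ct)))
  expect_error(sample_hg_deflection(1, 0.5), "g")
})

test_that("HG inverse transform matches the analytic distribution", {
  g <- 0.9
  set.seed(42)
  ct <- sample_hg_deflection(g, runif(1e4))
  hg_cdf <- function(x) {
    (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * x) - 1 / (1 + g))
  }
  ks <- suppressWarnings(stats::ks.test(ct, hg_cdf))
  expect_gt(ks$p.value, 0.001)
})

test_that("boundary interactions reproduce the Fresnel limits", {
  # matched index: every hit exits
  expect_true(all(boundary_interaction(c(0.1, 0.6, 1), 1, runif(3)) == "exit"))
  # normal incidence on n_rel = 1.4: R_F = (0.4/2.4)^2 ~ 0.0278
  expect_equal(fresnel_unpolarized(1, 1.4), (0.4 / 2.4)^2)
  expect_identical(boundary_interaction(1, 1.4, 0.01), "reflect")
  expect_identical(boundary_interaction(1, 1.4, 0.5), "exit")
  # beyond the critical angle: total internal reflection, any variate
  ct_tir <- 0.5 * sqrt(1 - 1 / 1.4^2)
  expect_identical(boundary_interaction(ct_tir, 1.4, 1 - 1e-12), "reflect")
})

test_that("tallies are internally consistent and seed-reproducible", {
  med <- tissue_matched(0)
  cfg <- mc_config(2e4, seed = 5, dt = 20, n_time_bins = 100,
                   max_path_mm = 700)
  tal <- mc_simulate(med, semi_inf(), cfg)
  # the z_max histogram partitions every binned photon
  expect_identical(as.integer(rowSums(tal$M)), as.integer(tal$N))
  # energy bookkeeping: every launched photon is accounted for
  expect_identical(tal$detected + tal$transmitted + tal$discarded,
                   cfg$n_photons)
  # mean depth cannot exceed maximum depth, bin by bin
  expect_true(all(tal$sum_zbar <= tal$sum_zmax + 1e-12))
  # byte-exact reproducibility from the seed
  tal2 <- mc_simulate(med, semi_inf(), cfg)
  expect_identical(tal[c("N", "sum_zmax", "sum_zbar", "M", "detected",
                         "transmitted", "discarded")],
                   tal2[c("N", "sum_zmax", "sum_zbar", "M", "detected",
                          "transmitted", "discarded")])

  # slab: transmission occurs and partitioning still holds
  tal_s <- mc_simulate(med, slab20(), mc_config(1e4, seed = 2, dt = 20,
                                                n_time_bins = 60,
                                                max_path_mm = 500))
  expect_gt(tal_s$transmitted, 0)
  expect_identical(as.integer(rowSums(tal_s$M)), as.integer(tal_s$N))
})

test_that("compiled kernel reproduces the pure-R reference trajectory by trajectory", {
  # mismatched index and finite slab exercise every boundary branch
  med <- tissue_mismatched(0)
  cfg <- mc_config(300, seed = 11, dt = 20, n_time_bins = 80,
                   max_path_mm = 500)
  tal <- mc_simulate(med, semi_inf(), cfg)
  set.seed(11)
  ref <- mc_reference(300, 1, 0, 1.4, Inf, med$v, 20, 80, 50, 100, 500)
  expect_identical(as.integer(tal$N), ref$N)
  expect_identical(matrix(as.integer(tal$M), nrow = 80), ref$M)
  expect_equal(tal$sum_zmax, ref$sum_zmax, tolerance = 1e-12)
  expect_equal(tal$sum_zbar, ref$sum_zbar, tolerance = 1e-12)
  expect_identical(tal$detected, ref$detected)
  expect_identical(tal$discarded, ref$discarded)

  med9 <- optical_medium(0, 1, g = 0.9, n_in = 1.4, n_out = 1.0)
  cfg9 <- mc_config(150, seed = 3, dt = 20, n_time_bins = 50,
                    max_path_mm = 400)
  tal9 <- mc_simulate(med9, slab20(), cfg9)
  set.seed(3)
  ref9 <- mc_reference(150, 10, 0.9, 1.4, 20, med9$v, 20, 50, 50, 20, 400)
  expect_identical(as.integer(tal9$N), ref9$N)
  expect_identical(matrix(as.integer(tal9$M), nrow = 50), ref9$M)
  expect_equal(tal9$sum_zmax, ref9$sum_zmax, tolerance = 1e-12)
  expect_identical(tal9$transmitted, ref9$transmitted)
})

test_that("estimators apply absorption as post-hoc weights", {
  med <- tissue_matched(0)
  cfg <- mc_config(5e4, seed = 9, dt = 20, n_time_bins = 100,
                   max_path_mm = 700)
  tal <- mc_simulate(med, semi_inf(), cfg)
  e0 <- mc_estimators(tal, 0)
  e1 <- mc_estimators(tal, 0.01)
  # per-bin depth moments are mu_a-invariant by construction
  expect_identical(e0$td$mean_zmax, e1$td$mean_zmax)
  expect_identical(e0$td$mean_zbar, e1$td$mean_zbar)
  # TPSF rescales by exactly the bin-center weight
  nz <- e0$td$N > 0
  expect_equal(e1$td$tpsf[nz] / e0$td$tpsf[nz],
               exp(-0.01 * med$v * e0$td$t[nz]), tolerance = 1e-12)
  # every non-empty row of the conditional density integrates to one
  rows <- which(nz)
  sums <- rowSums(e0$f_zt$density[rows, , drop = FALSE]) * e0$f_zt$dz
  expect_equal(sums, rep(1, length(rows)), tolerance = 1e-12)
  # the CW density integrates to one as well
  expect_equal(sum(e1$cw$f_z) * e0$f_zt$dz, 1, tolerance = 1e-12)
  # CW aggregates shrink with absorption (deep late light is down-weighted)
  e2 <- mc_estimators(tal, 0.1)
  expect_lt(e2$cw$mean_zmax, e1$cw$mean_zmax)
})

test_that("isotropic and g = 0.9 transport agree on late-time depth statistics", {
  cfg <- function(seed) mc_config(6e4, seed = seed, dt = 50, n_time_bins = 24,
                                  max_path_mm = 260)
  tal0 <- mc_simulate(tissue_matched(0), semi_inf(), cfg(21))
  tal9 <- mc_simulate(optical_medium(0, 1, g = 0.9, n_in = 1.4, n_out = 1.4),
                      semi_inf(), cfg(22))
  e0 <- mc_estimators(tal0, 0)$td
  e9 <- mc_estimators(tal9, 0)$td
  sel <- e0$t > 400 & e0$t < 1100 & e0$N > 100 & e9$N > 100
  expect_gt(sum(sel), 5)
  diff_sigma <- abs(e0$mean_zmax[sel] - e9$mean_zmax[sel]) /
    sqrt(e0$se_zmax[sel]^2 + e9$se_zmax[sel]^2)
  # similarity relation: identical mu_s' gives identical diffusion-level
  # statistics; allow 4 sigma on each paired bin
  expect_true(all(diff_sigma < 4))
})
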