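test_that("depth densities are normalized in the diffusive regime", {
  med <- tissue_matched(0)
  dd <- f_td(med, slab20(), 1000)
  expect_lt(normalization_report(dd)$deficiency, 1e-4)
  dd_semi <- f_td(med, semi_inf(), 1000)
  expect_lt(normalization_report(dd_semi)$deficiency, 1e-4)

  med_abs <- tissue_matched(0.01)
  expect_lt(normalization_report(f_cw_rho(med_abs, semi_inf(), 20))$deficiency, 1e-3)
  # zero absorption handled through the small-mu_a substitute
  expect_lt(normalization_report(f_cw_rho(med, semi_inf(), 20))$deficiency, 1e-3)
})

test_that("the total-CW density's normalization excess matches its closed form", {
  # the total-CW construction inherits a genuine normalization excess: the
  # zero-thickness sub-slab reflectance R(0) is the (negative) analytic
  # continuation below s = z_s - z_e0, not zero, so the density integrates
  # to 1 - R(0)/R(s0) rather than 1.  The quadrature must reproduce the
  # closed-form excess rather than hide it.
  med <- tissue_matched(0.01)
  rep <- normalization_report(f_cw_total(med, semi_inf()))
  dd <- f_cw_total(med, semi_inf())
  expected <- 1 - dd$cdf(1e-12)          # 1 - R(0)/R(s0)
  expect_equal(rep$integral, expected, tolerance = 1e-6)
  expect_gt(rep$deficiency, 0.1)         # large, and reported as such
  # the excess disappears once the sub-slab contains the source: the mass
  # above the zero crossing s* = z_s - z_e0 integrates to one exactly
  s_star <- 1 - 2 / 3
  mass_above <- integrate(dd$fun, s_star, Inf, rel.tol = 1e-9)$value
  expect_equal(mass_above, 1, tolerance = 1e-6)
})

test_that("normalization deficiency is reported, not hidden, outside the DA", {
  med <- optical_medium(mu_a = 1, mu_s_prime = 1, n_in = 1.4, n_out = 1.4)
  rep <- normalization_report(f_cw_total(med, slab_geometry(5)))
  expect_true(is.finite(rep$deficiency))
  # the density integral is what it is; nothing renormalizes it silently
  expect_equal(rep$deficiency, abs(1 - rep$integral))
})

test_that("closed-form densities match the finite-difference oracle", {
  z <- c(2, 5, 10, 15, 25, 40)
  med <- tissue_mismatched(0)      # mismatch exercises the R' correction
  semi <- semi_inf()

  dd <- f_td(med, semi, 1000)
  denom_td <- td_total_reflectance(tissue_mismatched(0), semi, 1000)
  oracle <- fd_density(function(s)
    td_total_reflectance(med, semi, 1000, s = s, internal_bottom = TRUE),
    denom_td, z)
  expect_equal(dd$fun(z), oracle, tolerance = 1e-6)
  # Richardson check: halving h converges to the same values
  oracle2 <- fd_density(function(s)
    td_total_reflectance(med, semi, 1000, s = s, internal_bottom = TRUE),
    denom_td, z, h = 5e-4)
  expect_equal(oracle2, oracle, tolerance = 1e-7)

  med_abs <- tissue_mismatched(0.01)
  ddr <- f_cw_rho(med_abs, semi, 20)
  denom_cw <- cw_reflectance(med_abs, semi, 20)
  oracle_cw <- fd_density(function(s)
    cw_reflectance(med_abs, semi, 20, s = s, internal_bottom = TRUE),
    denom_cw, z)
  expect_equal(ddr$fun(z), oracle_cw, tolerance = 1e-6)

  ddt <- f_cw_total(med_abs, semi)
  denom_tot <- cw_total_reflectance(med_abs, semi)
  oracle_tot <- fd_density(function(s)
    cw_total_reflectance(med_abs, semi, s = s, internal_bottom = TRUE),
    denom_tot, z)
  expect_equal(ddt$fun(z), oracle_tot, tolerance = 1e-6)
})

test_that("TD depth statistics are exactly invariant to mu_a and rho", {
  z <- seq(0.5, 35, by = 0.5)
  geom <- semi_inf()
  f0 <- f_td(tissue_matched(0), geom, 800)$fun(z)
  f5 <- f_td(tissue_matched(0.05), geom, 800)$fun(z)
  expect_identical(f0, f5)                 # bit-identical
  expect_identical(mean_zmax_td(tissue_matched(0), geom, c(300, 900)),
                   mean_zmax_td(tissue_matched(0.05), geom, c(300, 900)))

  # rho-resolved and total reflectance yield the same density: the
  # multiplicative rho factor cancels in the finite-difference ratio
  med <- tissue_matched(0)
  slab <- slab20()
  h <- 1e-3
  zz <- c(3, 8, 14)
  for (rho in c(5, 25)) {
    f_rho <- (td_reflectance(med, slab, rho, 700, s = zz + h, internal_bottom = TRUE) -
              td_reflectance(med, slab, rho, 700, s = zz - h, internal_bottom = TRUE)) /
      (2 * h) / td_reflectance(med, slab, rho, 700)
    f_tot <- (td_total_reflectance(med, slab, 700, s = zz + h, internal_bottom = TRUE) -
              td_total_reflectance(med, slab, 700, s = zz - h, internal_bottom = TRUE)) /
      (2 * h) / td_total_reflectance(med, slab, 700)
    expect_equal(f_rho, f_tot, tolerance = 1e-12)
  }
})

test_that("moments agree between the two quadrature schemes", {
  med <- tissue_matched(0)
  dd <- f_td(med, semi_inf(), 1500)
  direct <- integrate(function(z) z * dd$fun(z), 0, Inf, rel.tol = 1e-9)$value
  expect_equal(mean_zmax_td(med, semi_inf(), 1500), direct, tolerance = 1e-6)

  med_abs <- tissue_matched(0.01)
  ddt <- f_cw_total(med_abs, semi_inf())
  direct_t <- integrate(function(z) z * ddt$fun(z), 0, Inf, rel.tol = 1e-9)$value
  expect_equal(mean_zmax_cw_total(med_abs, semi_inf()), direct_t, tolerance = 1e-6)
})

test_that("depth statistics obey the expected monotonicities and limits", {
  med <- tissue_matched(0)
  ts <- c(100, 300, 700, 1500, 3000, 6000)
  zt <- mean_zmax_td(med, semi_inf(), ts)
  expect_true(all(diff(zt) > 0))

  # the density mode moves deeper with time
  mode_of <- function(t) {
    dd <- f_td(med, semi_inf(), t)
    zg <- seq(0.5, 80, by = 0.25)
    zg[which.max(dd$fun(zg))]
  }
  modes <- vapply(c(300, 1000, 3000), mode_of, numeric(1))
  expect_true(all(diff(modes) > 0))

  # CW: deeper with distance, shallower with absorption
  med_abs <- tissue_matched(0.01)
  rhos <- c(5, 10, 20, 40, 70)
  zr <- mean_zmax_cw_rho(med_abs, semi_inf(), rhos)
  expect_true(all(diff(zr) > 0))
  z_mu <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(m)
    mean_zmax_cw_rho(tissue_matched(m), semi_inf(), 30), numeric(1))
  expect_true(all(diff(z_mu) < 0))
  z_mu_tot <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(m)
    mean_zmax_cw_total(tissue_matched(m), semi_inf()), numeric(1))
  expect_true(all(diff(z_mu_tot) < 0))

  # slab moments approach (and never exceed) the slab thickness
  expect_true(all(mean_zmax_td(med, slab20(), c(1000, 1e4, 1e5)) < 20))
  expect_equal(mean_zmax_td(med, slab20(), 1e5), 20, tolerance = 0.02)
  z_far <- mean_zmax_cw_rho(med_abs, slab20(), 150)
  expect_lt(z_far, 20)
  expect_gt(z_far, 18)

  # CW density peak moves deeper as rho grows (long right tail)
  peak_of <- function(rho) {
    dd <- f_cw_rho(med, semi_inf(), rho)
    zg <- seq(0.5, 120, by = 0.25)
    zg[which.max(dd$fun(zg))]
  }
  expect_true(all(diff(vapply(c(10, 30, 60), peak_of, numeric(1))) > 0))
})

test_that("the heuristic mean depth is half the mean maximum depth", {
  expect_equal(mean_depth_heuristic(30), 15)
  expect_equal(mean_depth_heuristic(c(0, 4)), c(0, 2))
  expect_error(mean_depth_heuristic(-1))
})

test_that("both source placements are available and differ only at high mu_a", {
  med_lo <- tissue_matched(0.01)
  z1 <- mean_zmax_cw_total(med_lo, semi_inf())
  z2 <- mean_zmax_cw_total(med_lo, semi_inf(z_s_mode = "inv_mut"))
  expect_equal(z2, z1, tolerance = 0.02)   # diffusive regime: near-equivalent
  med_hi <- optical_medium(1, 1, n_in = 1.4, n_out = 1.4)
  z1h <- mean_zmax_cw_total(med_hi, semi_inf())
  z2h <- mean_zmax_cw_total(med_hi, semi_inf(z_s_mode = "inv_mut"))
  expect_gt(abs(z2h - z1h) / z1h, 0.05)    # placement becomes critical
})
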