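# Reproduction harness: power-law exponent fits, paired DE/MC comparison
# experiments and fixture generation for the fast test suite.

#' Least-squares power-law exponent on a log-log grid
#'
#' Fits `log(y) = intercept + exponent * log(x)` by ordinary least squares
#' over the points whose abscissa falls inside `window`.
#'
#' @param xs,ys positive numeric vectors of equal length.
#' @param window numeric length-2 abscissa window (inclusive).
#' @return A list with `exponent`, `intercept`, `residual_sd`, `n_points`.
#' @examples
#' fit_power_exponent(1:20, (1:20)^2)$exponent  # 2
#' @export
fit_power_exponent <- function(xs, ys, window = range(xs)) {
  stopifnot(length(xs) == length(ys), length(window) == 2L)
  keep <- xs >= window[1] & xs <= window[2]
  if (sum(keep) < 5L) stop("need at least 5 points inside the fit window")
  if (any(xs[keep] <= 0) || any(ys[keep] <= 0))
    stop("power-law fits require positive data")
  fit <- stats::lm(log(ys[keep]) ~ log(xs[keep]))
  rdf <- fit$df.residual
  list(exponent = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residual_sd = if (rdf > 0) sqrt(sum(stats::resid(fit)^2) / rdf) else NA_real_,
       n_points = sum(keep))
}

#' Paired diffusion/Monte Carlo comparison experiment
#'
#' Runs both the diffusion closed form and the Monte Carlo estimator for a
#' named quantity on a common abscissa grid, and summarises their relative
#' difference over a stated validity window.  A point passes when the
#' relative difference is below `rel_tol` plus a `sigma_allowance`-sigma
#' statistical allowance from the MC standard error.  Deterministic given
#' the MC seed.
#'
#' @param quantity one of `"zmax_td"` (mean maximum depth vs time),
#'   `"zbar_td"` (heuristic mean depth vs time), `"tpsf"` (time-resolved
#'   total reflectance), `"f_td"` (depth density at time `t_fixed`),
#'   `"zmax_cw_total"` (scalar CW mean maximum depth).
#' @param medium,geometry the medium and geometry under test.
#' @param config an [mc_config()] describing the MC budget.
#' @param mu_a absorption (mm^-1) applied in the estimators (defaults to
#'   the medium's); the TD depth quantities are invariant to it.
#' @param window validity window on the abscissa (ps for TD quantities).
#' @param t_fixed arrival time (ps) at which `"f_td"` is compared.
#' @param rel_tol relative tolerance of the comparison.
#' @param sigma_allowance multiple of the MC standard error added to the
#'   tolerance.
#' @param tallies optional pre-computed `"mc_tallies"` to reuse.
#' @return An object of class `"comparison_report"`: a list with the paired
#'   `curves` data frame (abscissa, DE, MC, MC standard error, relative
#'   difference), the `window`, summary statistics and a `pass` flag.
#' @export
run_comparison <- function(quantity = c("zmax_td", "zbar_td", "tpsf", "f_td",
                                        "zmax_cw_total"),
                           medium, geometry, config,
                           mu_a = medium$mu_a, window = c(300, 2000),
                           t_fixed = 1000, rel_tol = 0.05,
                           sigma_allowance = 3, tallies = NULL) {
  quantity <- match.arg(quantity)
  if (is.null(tallies)) tallies <- mc_simulate(medium, geometry, config)
  est <- mc_estimators(tallies, mu_a)

  if (quantity == "zmax_cw_total") {
    de <- mean_zmax_cw_total(
      if (medium$mu_a == mu_a) medium else
        optical_medium(mu_a, medium$mu_s_prime, medium$g, medium$n_in, medium$n_out),
      geometry)
    mc <- est$cw$mean_zmax
    curves <- data.frame(x = NA_real_, de = de, mc = mc, se = NA_real_,
                         rel_diff = (mc - de) / de)
    pass <- abs(curves$rel_diff) <= rel_tol
  } else if (quantity == "f_td") {
    jc <- tallies$t_centers
    j <- which.min(abs(jc - t_fixed))
    if (est$td$N[j] == 0)
      stop("no MC photons in the time bin used for the density comparison")
    zc <- est$f_zt$z_centers
    k <- which(!is.na(zc))
    mc <- est$f_zt$density[j, k]
    dd <- f_td(medium, geometry, jc[j])
    # bin-average the DE density for a like-for-like comparison
    dz <- est$f_zt$dz
    de <- vapply(zc[k], function(z0)
      stats::integrate(dd$fun, z0 - dz / 2, z0 + dz / 2,
                       rel.tol = 1e-8)$value / dz, numeric(1))
    se <- sqrt(pmax(mc, 1 / (est$td$N[j] * dz))) /
      sqrt(est$td$N[j] * dz)              # Poisson error on a bin density
    # compare on the density's support: bins carrying < 0.1% of the peak
    # density say nothing at finite MC budgets
    keep <- zc[k] >= window[1] & zc[k] <= window[2] & de > 1e-3 * max(de)
    curves <- data.frame(x = zc[k], de = de, mc = mc, se = se,
                         rel_diff = (mc - de) / de)[keep, ]
    pass <- all(abs(curves$rel_diff) <=
                  rel_tol + sigma_allowance * curves$se / curves$de)
  } else {
    de_fun <- switch(quantity,
      zmax_td = function(t) mean_zmax_td(medium, geometry, t),
      zbar_td = function(t) mean_depth_heuristic(mean_zmax_td(medium, geometry, t)),
      tpsf    = function(t) {
        m <- if (medium$mu_a == mu_a) medium else
          optical_medium(mu_a, medium$mu_s_prime, medium$g, medium$n_in, medium$n_out)
        td_total_reflectance(m, geometry, t)
      })
    mc_col <- switch(quantity, zmax_td = "mean_zmax", zbar_td = "mean_zbar",
                     tpsf = "tpsf")
    se_col <- switch(quantity, zmax_td = "se_zmax", zbar_td = "se_zbar",
                     tpsf = "se_tpsf")
    td <- est$td
    keep <- td$t >= window[1] & td$t <= window[2]
    if (any(keep & td$N == 0))
      stop("empty MC time bins inside the validity window; increase the photon budget")
    td <- td[keep, ]
    de <- de_fun(td$t)
    curves <- data.frame(x = td$t, de = de, mc = td[[mc_col]],
                         se = td[[se_col]],
                         rel_diff = (td[[mc_col]] - de) / de)
    pass <- all(abs(curves$rel_diff) <=
                  rel_tol + sigma_allowance * curves$se / curves$de)
  }

  structure(list(quantity = quantity, curves = curves, window = window,
                 rel_tol = rel_tol, sigma_allowance = sigma_allowance,
                 max_abs_rel_diff = max(abs(curves$rel_diff)),
                 seed = tallies$config$seed,
                 n_photons = tallies$config$n_photons,
                 pass = pass),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("DE vs MC comparison: %s (%d photons, seed %d)\n",
              x$quantity, x$n_photons, x$seed))
  cat(sprintf("  validity window [%g, %g], %d paired points\n",
              x$window[1], x$window[2], nrow(x$curves)))
  cat(sprintf("  max |relative difference| = %.3g (tolerance %g + %g sigma)\n",
              x$max_abs_rel_diff, x$rel_tol, x$sigma_allowance))
  cat(sprintf("  %s\n", if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Generate small plain-text reference fixtures
#'
#' Writes coarse-grid diffusion curves and one small Monte Carlo tally to
#' CSV files under `dir`, for use by fast regression tests.  Byte-identical
#' given the same seed.
#'
#' @param seed RNG seed for the MC tally.
#' @param dir output directory (created if needed).
#' @param n_photons MC photon budget for the fixture tally.
#' @return Invisibly, the vector of file paths written.
#' @export
generate_fixtures <- function(seed = 1L, dir = tempfile("fixtures"),
                              n_photons = 1e5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  med <- optical_medium(mu_a = 0, mu_s_prime = 1, n_in = 1.4, n_out = 1.4)
  semi <- slab_geometry(Inf)

  t_grid <- seq(200, 3000, by = 200)
  de1 <- data.frame(t_ps = t_grid,
                    zmax_mm = mean_zmax_td(med, semi, t_grid))
  p1 <- file.path(dir, "de_mean_zmax_td.csv")
  utils::write.csv(format(de1, digits = 15), p1, row.names = FALSE, quote = FALSE)

  z_grid <- seq(0.5, 40, by = 0.5)
  dd <- f_td(med, semi, 1000)
  de2 <- data.frame(z_mm = z_grid, density_per_mm = dd$fun(z_grid))
  p2 <- file.path(dir, "de_f_td_t1000.csv")
  utils::write.csv(format(de2, digits = 15), p2, row.names = FALSE, quote = FALSE)

  cfg <- mc_config(n_photons = n_photons, seed = seed, dt = 20,
                   n_time_bins = 100, max_path_mm = med$v * 2000)
  tal <- mc_simulate(med, semi, cfg)
  p3 <- file.path(dir, "mc_td_tallies.csv")
  utils::write.csv(data.frame(t_ps = tal$t_centers, N = tal$N,
                              sum_zmax = tal$sum_zmax,
                              sum_zbar = tal$sum_zbar),
                   p3, row.names = FALSE, quote = FALSE)
  p4 <- file.path(dir, "mc_zmax_matrix.csv")
  utils::write.csv(as.data.frame(tal$M), p4, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2, p3, p4))
}
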