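# Monte Carlo photon transport: configuration, elementary samplers, the
# simulation wrapper around the compiled kernel, and the estimators that
# turn time-binned tallies into TPSF, depth moments and depth densities.

#' Monte Carlo simulation configuration
#'
#' @param n_photons number of launched photons.
#' @param seed RNG seed; the simulation is bit-reproducible given the seed.
#' @param dt time-bin width (ps).
#' @param n_time_bins number of time bins; bin `j` covers
#'   `((j-1) dt, j dt]` and is represented by its center.
#' @param n_z_bins number of `z_max` histogram bins dividing `[0, z_cap]`;
#'   an extra overflow bin collects deeper trajectories.
#' @param z_cap depth covered by the `z_max` histogram (mm); defaults to
#'   the slab thickness, or 100 mm for a semi-infinite medium.
#' @param max_path_mm maximum trajectory path length (mm); longer
#'   trajectories are discarded and counted.  This truncation biases CW
#'   estimates for weakly absorbing semi-infinite media at large `rho`.
#' @param rho_rings optional annular-detector center radii (mm) for
#'   rho-resolved tallies.
#' @param ring_halfwidth annulus half-width (mm).
#' @return An object of class `"mc_config"`.
#' @export
mc_config <- function(n_photons, seed = 1L, dt = 5, n_time_bins = 1000L,
                      n_z_bins = 50L, z_cap = NULL, max_path_mm = 43000,
                      rho_rings = NULL, ring_halfwidth = 1) {
  stopifnot(n_photons > 0, dt > 0, n_time_bins > 0, n_z_bins > 0,
            max_path_mm > 0, ring_halfwidth > 0)
  structure(list(n_photons = as.integer(n_photons), seed = as.integer(seed),
                 dt = dt, n_time_bins = as.integer(n_time_bins),
                 n_z_bins = as.integer(n_z_bins), z_cap = z_cap,
                 max_path_mm = max_path_mm,
                 rho_rings = if (is.null(rho_rings)) numeric(0) else as.numeric(rho_rings),
                 ring_halfwidth = ring_halfwidth),
            class = "mc_config")
}

#' Elementary Monte Carlo samplers
#'
#' `sample_step()` maps a uniform variate to an exponential free path
#' `-log(u)/mu_s` (mean `1/mu_s`).  `sample_hg_deflection()` maps a uniform
#' variate to the cosine of the Henyey-Greenstein deflection angle (mean
#' cosine `g`; `g = 0` gives the isotropic `2u - 1`).
#' `boundary_interaction()` decides the fate of a photon hitting a face
#' with incidence cosine `cos_theta`: it exits unless the uniform variate
#' falls below the unpolarized Fresnel reflectance (total internal
#' reflection reflects always).
#'
#' @param mu_s scattering coefficient (mm^-1), `> 0`.
#' @param u uniform variate(s) in the open interval (0, 1).
#' @return `sample_step()`: step length(s) in mm.
#' @export
sample_step <- function(mu_s, u) {
  stopifnot(mu_s > 0)
  if (any(u <= 0 | u >= 1)) stop("'u' must lie in the open interval (0, 1)")
  -log(u) / mu_s
}

#' @rdname sample_step
#' @param g anisotropy factor, `|g| < 1`.
#' @return `sample_hg_deflection()`: cosine(s) of the deflection angle.
#' @export
sample_hg_deflection <- function(g, u) {
  if (abs(g) >= 1) stop("'g' must satisfy |g| < 1")
  if (any(u <= 0 | u >= 1)) stop("'u' must lie in the open interval (0, 1)")
  if (g == 0) return(2 * u - 1)
  tmp <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(pmax((1 + g^2 - tmp^2) / (2 * g), -1), 1)
}

#' @rdname sample_step
#' @param cos_theta incidence cosine(s) at the face, in `[0, 1]`.
#' @param n_rel relative refractive index `n_in/n_out`.
#' @return `boundary_interaction()`: `"exit"` or `"reflect"` per variate.
#' @export
boundary_interaction <- function(cos_theta, n_rel, u) {
  RF <- fresnel_unpolarized(cos_theta, n_rel)
  ifelse(u < RF, "reflect", "exit")
}

#' Run the Monte Carlo photon transport
#'
#' Simulates scattering-only trajectories (absorption is applied later by
#' [mc_estimators()] as time-bin weights, so one simulation serves every
#' `mu_a`) and accumulates time-binned tallies: per-bin counts `N_j`, sums
#' of per-trajectory `z_max` and `zbar`, and the count matrix `M[j, k]`
#' over `z_max` bins (last column = overflow).  The scattering coefficient
#' is `mu_s = mu_s'/(1 - g)`.
#'
#' @param medium an [optical_medium()]; its `mu_a` is ignored here.
#' @param geometry a [slab_geometry()].
#' @param config an [mc_config()].
#' @return An object of class `"mc_tallies"`.
#' @export
mc_simulate <- function(medium, geometry, config) {
  stopifnot(inherits(medium, "optical_medium"),
            inherits(geometry, "slab_geometry"),
            inherits(config, "mc_config"))
  g <- medium$g
  mu_s <- if (g == 0) medium$mu_s_prime else medium$mu_s_prime / (1 - g)
  z_cap <- config$z_cap
  if (is.null(z_cap)) z_cap <- if (is.finite(geometry$s0)) geometry$s0 else 100
  set.seed(config$seed)
  raw <- .mc_kernel(config$n_photons, mu_s, g, medium$n_rel, geometry$s0,
                    medium$v, config$dt, config$n_time_bins,
                    config$n_z_bins, z_cap, config$max_path_mm,
                    config$rho_rings, config$ring_halfwidth)
  structure(c(raw, list(
    config = config, mu_s = mu_s, v = medium$v, z_cap = z_cap,
    dz = z_cap / config$n_z_bins,
    t_centers = (seq_len(config$n_time_bins) - 0.5) * config$dt,
    s0 = geometry$s0, n_rel = medium$n_rel, g = g,
    mu_s_prime = medium$mu_s_prime
  )), class = "mc_tallies")
}

#' @export
print.mc_tallies <- function(x, ...) {
  cat(sprintf("MC tallies: %d photons (seed %d), mu_s = %g mm^-1, g = %g, n_rel = %g\n",
              x$config$n_photons, x$config$seed, x$mu_s, x$g, x$n_rel))
  cat(sprintf("  detected %d (of which %d beyond the time window), transmitted %d, discarded %d\n",
              x$detected, x$detected_late, x$transmitted, x$discarded))
  cat(sprintf("  %d time bins of %g ps; z_max histogram: %d bins over [0, %g] mm + overflow\n",
              x$config$n_time_bins, x$config$dt, x$config$n_z_bins, x$z_cap))
  invisible(x)
}

#' Estimators from Monte Carlo tallies
#'
#' Applies the absorption weights `w_j = exp(-mu_a v t_j)` (bin centers
#' `t_j`) to scattering-only tallies.  Per-bin depth moments are unweighted
#' within a bin (the weight is constant across a bin to the stated
#' approximation), so the time-domain moments are identical for every
#' `mu_a`.  Continuous-wave aggregates weight the bins by `w_j N_j`; bins
#' with no photons are reported as `NA` and excluded from CW sums.
#'
#' @param tallies an `"mc_tallies"` object from [mc_simulate()].
#' @param mu_a absorption coefficient (mm^-1) to apply, `>= 0`.
#' @return A list with components
#'   `td`: data frame `t`, `N`, `tpsf` (ps^-1), `mean_zmax`, `mean_zbar` (mm);
#'   `f_zt`: matrix of densities `M[j,k]/(N_j dz)` (mm^-1), rows = time
#'     bins, columns = `z_max` bins (incl. overflow), with `z_centers`;
#'   `cw`: list `total_reflectance`, `mean_zmax`, `mean_zbar`, `f_z`;
#'   `rings`: per-ring list of `td` data frames (if rings were tallied).
#' @export
mc_estimators <- function(tallies, mu_a) {
  stopifnot(inherits(tallies, "mc_tallies"), mu_a >= 0)
  cfg <- tallies$config
  tj <- tallies$t_centers
  w <- exp(-mu_a * tallies$v * tj)
  N <- as.numeric(tallies$N)
  nonempty <- N > 0
  mean_zmax <- ifelse(nonempty, tallies$sum_zmax / N, NA_real_)
  mean_zbar <- ifelse(nonempty, tallies$sum_zbar / N, NA_real_)
  # per-bin standard errors of the mean (and Poisson error for the TPSF)
  se_of_mean <- function(s, s2) {
    varhat <- pmax(s2 / N - (s / N)^2, 0)
    ifelse(N > 1, sqrt(varhat / N), NA_real_)
  }
  tpsf <- w * N / (cfg$n_photons * cfg$dt)
  td <- data.frame(t = tj, N = N, tpsf = tpsf,
                   se_tpsf = w * sqrt(N) / (cfg$n_photons * cfg$dt),
                   mean_zmax = mean_zmax, mean_zbar = mean_zbar,
                   se_zmax = se_of_mean(tallies$sum_zmax, tallies$sum_zmax2),
                   se_zbar = se_of_mean(tallies$sum_zbar, tallies$sum_zbar2))

  dz <- tallies$dz
  f_zt <- tallies$M / ifelse(N > 0, N, NA_real_) / dz
  z_centers <- c((seq_len(cfg$n_z_bins) - 0.5) * dz, NA_real_)

  wN <- w * N
  Wtot <- sum(wN[nonempty])
  cw <- list(
    total_reflectance = sum(wN) / cfg$n_photons,
    mean_zmax = sum(wN[nonempty] * mean_zmax[nonempty]) / Wtot,
    mean_zbar = sum(wN[nonempty] * mean_zbar[nonempty]) / Wtot,
    f_z = colSums(w * tallies$M) / (dz * Wtot)
  )

  rings <- NULL
  if (length(cfg$rho_rings)) {
    rings <- lapply(seq_along(cfg$rho_rings), function(r) {
      Nr <- as.numeric(tallies$ringN[, r])
      ner <- Nr > 0
      data.frame(
        t = tj, N = Nr,
        tpsf = w * Nr / (cfg$n_photons * cfg$dt),
        mean_zmax = ifelse(ner, tallies$ring_sum_zmax[, r] / Nr, NA_real_),
        mean_zbar = ifelse(ner, tallies$ring_sum_zbar[, r] / Nr, NA_real_))
    })
    names(rings) <- sprintf("rho=%g", cfg$rho_rings)
  }

  list(td = td, f_zt = list(density = f_zt, z_centers = z_centers, dz = dz),
       cw = cw, rings = rings)
}
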