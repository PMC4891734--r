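# Slow pure-R reference implementation of the Monte Carlo kernel.
#
# Defines correctness for the compiled kernel: it reproduces the same
# trajectory logic and, crucially, the same RNG draw order (step u, then
# boundary u's only when n_rel != 1, then deflection u, then azimuth u),
# so with the same seed both implementations must produce identical
# tallies, photon by photon.

mc_reference <- function(n_photons, mu_s, g, n_rel, s0, v, dt,
                         n_time_bins, n_z_bins, z_cap, max_path) {
  finite_slab <- is.finite(s0)
  dz <- z_cap / n_z_bins
  KZ <- n_z_bins + 1L
  N <- integer(n_time_bins)
  sum_zmax <- numeric(n_time_bins); sum_zbar <- numeric(n_time_bins)
  M <- matrix(0L, n_time_bins, KZ)
  detected <- 0L; detected_late <- 0L; transmitted <- 0L; discarded <- 0L

  draw <- function() {
    repeat { u <- stats::runif(1); if (u > 0 && u < 1) return(u) }
  }
  fresnel <- function(ci) {
    st2 <- 1 - ci^2
    sin_t2 <- n_rel^2 * st2
    if (sin_t2 >= 1) return(1)
    ctt <- sqrt(1 - sin_t2)
    Rs <- ((n_rel * ci - ctt) / (n_rel * ci + ctt))^2
    Rp <- ((n_rel * ctt - ci) / (n_rel * ctt + ci))^2
    (Rs + Rp) / 2
  }

  for (i in seq_len(n_photons)) {
    x <- 0; y <- 0; z <- 0
    ux <- 0; uy <- 0; uz <- 1
    path <- 0; zmax <- 0; zsum <- 0; nscat <- 0L
    alive <- TRUE
    while (alive) {
      step <- -log(draw()) / mu_s
      repeat {
        if (uz < 0) {
          t_hit <- -z / uz
          if (t_hit <= step) {
            x <- x + ux * t_hit; y <- y + uy * t_hit; z <- 0
            path <- path + t_hit; step <- step - t_hit
            exit_now <- TRUE
            if (n_rel != 1) {
              RF <- fresnel(-uz)
              if (stats::runif(1) < RF) exit_now <- FALSE
            }
            if (exit_now) {
              t <- path / v
              j <- as.integer(t %/% dt)
              detected <- detected + 1L
              if (j >= n_time_bins) detected_late <- detected_late + 1L
              else {
                zbar <- zsum / nscat
                k <- min(as.integer(zmax %/% dz), n_z_bins)
                N[j + 1L] <- N[j + 1L] + 1L
                sum_zmax[j + 1L] <- sum_zmax[j + 1L] + zmax
                sum_zbar[j + 1L] <- sum_zbar[j + 1L] + zbar
                M[j + 1L, k + 1L] <- M[j + 1L, k + 1L] + 1L
              }
              alive <- FALSE
              break
            }
            uz <- -uz
            next
          }
        } else if (finite_slab && uz > 0) {
          t_hit <- (s0 - z) / uz
          if (t_hit <= step) {
            x <- x + ux * t_hit; y <- y + uy * t_hit; z <- s0
            if (z > zmax) zmax <- z
            path <- path + t_hit; step <- step - t_hit
            exit_now <- TRUE
            if (n_rel != 1) {
              RF <- fresnel(uz)
              if (stats::runif(1) < RF) exit_now <- FALSE
            }
            if (exit_now) { transmitted <- transmitted + 1L; alive <- FALSE; break }
            uz <- -uz
            next
          }
        }
        x <- x + ux * step; y <- y + uy * step; z <- z + uz * step
        path <- path + step
        break
      }
      if (!alive) break
      nscat <- nscat + 1L; zsum <- zsum + z
      if (z > zmax) zmax <- z
      if (path > max_path) { discarded <- discarded + 1L; break }
      u1 <- stats::runif(1)
      if (g == 0) cost <- 2 * u1 - 1
      else {
        tmp <- (1 - g^2) / (1 - g + 2 * g * u1)
        cost <- min(max((1 + g^2 - tmp^2) / (2 * g), -1), 1)
      }
      phi <- 2 * pi * stats::runif(1)
      sint <- sqrt(1 - cost^2)
      cosp <- cos(phi); sinp <- sin(phi)
      if (abs(uz) > 0.99999) {
        ux <- sint * cosp; uy <- sint * sinp
        uz <- if (uz >= 0) cost else -cost
      } else {
        den <- sqrt(1 - uz^2)
        nux <- sint * (ux * uz * cosp - uy * sinp) / den + ux * cost
        nuy <- sint * (uy * uz * cosp + ux * sinp) / den + uy * cost
        nuz <- -den * sint * cosp + uz * cost
        ux <- nux; uy <- nuy; uz <- nuz
      }
    }
  }
  list(N = N, sum_zmax = sum_zmax, sum_zbar = sum_zbar, M = M,
       detected = detected, detected_late = detected_late,
       transmitted = transmitted, discarded = discarded)
}
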