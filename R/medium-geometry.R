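# Optical properties, slab geometry and derived diffusion quantities.
#
# Unit conventions used throughout the package: lengths in mm, times in ps,
# so the vacuum speed of light is c0 = 0.299792458 mm/ps.

C0_MM_PER_PS <- 0.299792458

#' Optical properties of a homogeneous turbid medium
#'
#' Bundles the absorption coefficient, the reduced scattering coefficient,
#' the scattering anisotropy and the refractive indices of a homogeneous
#' scattering medium, together with the quantities derived from them in the
#' diffusion approximation: the diffusion coefficient `D = 1/(3 mu_s')`
#' (mm), the energy speed `v = c0/n_in` (mm/ps), the relative refractive
#' index `n_rel = n_in/n_out`, the effective attenuation coefficient
#' `mu_eff = sqrt(mu_a/D)` (mm^-1) and the extrapolated-boundary coefficient
#' `A` (see [fresnel_A()]).
#'
#' @param mu_a absorption coefficient (mm^-1), `>= 0`.
#' @param mu_s_prime reduced scattering coefficient (mm^-1), `> 0`.
#' @param g scattering anisotropy factor (mean cosine of the single
#'   scattering deflection), `-1 < g < 1`.  Only the Monte Carlo transport
#'   uses `g`; diffusion-level quantities depend on `mu_s_prime` alone.
#' @param n_in refractive index of the medium.
#' @param n_out refractive index of the external space.
#' @return An object of class `"optical_medium"`.
#' @examples
#' med <- optical_medium(mu_a = 0.01, mu_s_prime = 1, n_in = 1.4, n_out = 1.4)
#' med$D       # 1/3 mm
#' med$mu_eff  # sqrt(0.03) mm^-1
#' @export
optical_medium <- function(mu_a, mu_s_prime, g = 0, n_in = 1.4, n_out = 1.4) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(mu_s_prime), length(mu_s_prime) == 1L)
  if (mu_a < 0) stop("'mu_a' must be >= 0")
  if (mu_s_prime <= 0) stop("'mu_s_prime' must be > 0")
  if (abs(g) >= 1) stop("'g' must satisfy -1 < g < 1")
  if (n_in <= 0 || n_out <= 0) stop("refractive indices must be > 0")
  n_rel <- n_in / n_out
  D <- 1 / (3 * mu_s_prime)
  m <- list(
    mu_a = mu_a, mu_s_prime = mu_s_prime, g = g,
    n_in = n_in, n_out = n_out, n_rel = n_rel,
    D = D,
    v = C0_MM_PER_PS / n_in,
    mu_eff = sqrt(mu_a / D),
    A = fresnel_A(n_rel)
  )
  class(m) <- "optical_medium"
  m
}

#' @export
print.optical_medium <- function(x, ...) {
  cat("Optical medium (mm, ps units)\n")
  cat(sprintf("  mu_a = %g mm^-1, mu_s' = %g mm^-1, g = %g\n",
              x$mu_a, x$mu_s_prime, x$g))
  cat(sprintf("  n_in = %g, n_out = %g (n_rel = %g, A = %.6f)\n",
              x$n_in, x$n_out, x$n_rel, x$A))
  cat(sprintf("  D = %g mm, v = %g mm/ps, mu_eff = %g mm^-1\n",
              x$D, x$v, x$mu_eff))
  invisible(x)
}

#' Slab geometry for reflectance calculations
#'
#' Describes an infinite slab of thickness `s0` (mm) illuminated on its top
#' face by a pencil beam, or the semi-infinite half-space (`s0 = Inf`).  The
#' pencil beam is modelled as an isotropic point source buried at depth
#' `z_s`; by default `z_s = 1/mu_s_prime` (one transport mean free path).
#' The alternative placement `z_s = 1/(mu_a + mu_s_prime)` shrinks with
#' absorption and agrees better with transport at very high `mu_a`.
#'
#' @param s0 slab thickness in mm, or `Inf` for a semi-infinite medium.
#' @param z_s explicit source depth (mm) overriding `z_s_mode`, or `NULL`.
#' @param z_s_mode `"inv_musp"` for `z_s = 1/mu_s'` (default) or `"inv_mut"`
#'   for `z_s = 1/(mu_a + mu_s')`.
#' @return An object of class `"slab_geometry"`.
#' @export
slab_geometry <- function(s0 = Inf, z_s = NULL, z_s_mode = c("inv_musp", "inv_mut")) {
  z_s_mode <- match.arg(z_s_mode)
  stopifnot(is.numeric(s0), length(s0) == 1L)
  if (s0 <= 0) stop("'s0' must be > 0 (use Inf for a semi-infinite medium)")
  if (!is.null(z_s)) {
    stopifnot(is.numeric(z_s), length(z_s) == 1L, z_s > 0)
  }
  g <- list(s0 = s0, z_s = z_s, z_s_mode = z_s_mode)
  class(g) <- "slab_geometry"
  g
}

#' @export
print.slab_geometry <- function(x, ...) {
  if (is.finite(x$s0)) cat(sprintf("Slab, s0 = %g mm", x$s0))
  else cat("Semi-infinite medium")
  if (!is.null(x$z_s)) cat(sprintf(", z_s = %g mm (explicit)\n", x$z_s))
  else cat(sprintf(", z_s mode '%s'\n", x$z_s_mode))
  invisible(x)
}

# cache for the Fresnel boundary coefficient; keyed by formatted n_rel
.A_cache <- new.env(parent = emptyenv())

#' Extrapolated-boundary coefficient A for Fresnel reflections
#'
#' Coefficient entering the extrapolated distance `z_e = 2 A D` of the
#' zero-fluence plane in the extrapolated boundary condition.  It is
#' computed from the angular moments of the unpolarized Fresnel reflection
#' coefficient `R_F` for internal incidence at a planar interface,
#'
#' `A = (1 + 3 I2) / (1 - 2 I1)`,
#'
#' `I1 = integral of R_F(theta) sin(theta) cos(theta)`,
#' `I2 = integral of R_F(theta) sin(theta) cos^2(theta)` over `[0, pi/2]`,
#'
#' including total internal reflection beyond the critical angle.  `A = 1`
#' exactly for a matched interface (`n_rel = 1`).  Values are cached.
#'
#' @param n_rel relative refractive index `n_in/n_out`, `> 0`.
#' @return The dimensionless coefficient `A`.
#' @examples
#' fresnel_A(1)    # exactly 1
#' fresnel_A(1.4)  # approximately 2.9485
#' @export
fresnel_A <- function(n_rel) {
  stopifnot(is.numeric(n_rel), length(n_rel) == 1L, is.finite(n_rel))
  if (n_rel <= 0) stop("'n_rel' must be > 0")
  if (n_rel == 1) return(1)
  key <- sprintf("%.15g", n_rel)
  if (!is.null(.A_cache[[key]])) return(.A_cache[[key]])
  I1 <- stats::integrate(function(th) fresnel_unpolarized(cos(th), n_rel) * sin(th) * cos(th),
                         0, pi / 2, rel.tol = 1e-12)$value
  I2 <- stats::integrate(function(th) fresnel_unpolarized(cos(th), n_rel) * sin(th) * cos(th)^2,
                         0, pi / 2, rel.tol = 1e-12)$value
  A <- (1 + 3 * I2) / (1 - 2 * I1)
  .A_cache[[key]] <- A
  A
}

#' Unpolarized Fresnel reflection coefficient for internal incidence
#'
#' Reflectance of an unpolarized plane wave hitting the boundary from inside
#' the medium at incidence cosine `cos_theta`, for relative index
#' `n_rel = n_in/n_out`.  Returns 1 beyond the critical angle (total
#' internal reflection).
#'
#' @param cos_theta cosine(s) of the internal incidence angle, in `[0, 1]`.
#' @param n_rel relative refractive index, `> 0`.
#' @return Vector of reflectances in `[0, 1]`.
#' @export
fresnel_unpolarized <- function(cos_theta, n_rel) {
  stopifnot(n_rel > 0)
  ct <- pmin(pmax(cos_theta, 0), 1)
  st2 <- 1 - ct^2
  sin_t2 <- n_rel^2 * st2            # sin^2 of the transmitted angle
  R <- rep(1, length(ct))            # total internal reflection default
  ok <- sin_t2 <= 1
  if (any(ok)) {
    ctt <- sqrt(1 - sin_t2[ok])
    Rs <- ((n_rel * ct[ok] - ctt) / (n_rel * ct[ok] + ctt))^2
    Rp <- ((n_rel * ctt - ct[ok]) / (n_rel * ctt + ct[ok]))^2
    R[ok] <- (Rs + Rp) / 2
  }
  R
}

#' Derived diffusion-level scalars for a medium/geometry pair
#'
#' Resolves every derived quantity the reflectance and depth-statistics
#' routines need: diffusion coefficient `D`, energy speed `v`, source depth
#' `z_s`, extrapolated distances at the two slab faces and the effective
#' attenuation coefficient `mu_eff`.  The top (illuminated) face always
#' carries the Fresnel extrapolation `z_e = 2 A D`; a physical bottom face
#' carries the same, while an *internal cut* (the sub-slab used by the depth
#' densities) carries `z_e0 = 2 D`, free of Fresnel reflections.
#'
#' @param medium an [optical_medium()].
#' @param geometry a [slab_geometry()].
#' @return A list with elements `D`, `v`, `z_s`, `z_e_top`, `z_e_bottom`,
#'   `z_e_internal`, `mu_eff`, `A`, `n_rel`, `s0`.
#' @export
derived_quantities <- function(medium, geometry) {
  stopifnot(inherits(medium, "optical_medium"), inherits(geometry, "slab_geometry"))
  z_s <- geometry$z_s
  if (is.null(z_s)) {
    z_s <- switch(geometry$z_s_mode,
                  inv_musp = 1 / medium$mu_s_prime,
                  inv_mut  = 1 / (medium$mu_a + medium$mu_s_prime))
  }
  if (is.finite(geometry$s0) && geometry$s0 <= z_s)
    stop("slab thickness s0 must be larger than the source depth z_s")
  list(
    D = medium$D, v = medium$v, z_s = z_s,
    z_e_top = 2 * medium$A * medium$D,
    z_e_bottom = 2 * medium$A * medium$D,   # physical deep face
    z_e_internal = 2 * medium$D,            # internal cut, no Fresnel
    mu_eff = medium$mu_eff, A = medium$A, n_rel = medium$n_rel,
    s0 = geometry$s0
  )
}

#' Read a medium/geometry/grid configuration from a YAML file
#'
#' Accepts keys `mu_a`, `mu_s_prime`, `g`, `n_in`, `n_out`, `s0` (number or
#' `"inf"`), `z_s`, `z_s_mode`, `rho`, `t_grid`, `z_grid`.  Grid keys may be
#' either explicit numeric vectors or `list(from, to, length)` blocks.
#'
#' @param path path to a YAML configuration file.
#' @return A list with elements `medium`, `geometry`, `rho`, `t_grid`, `z_grid`.
#' @export
read_optical_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)
  s0 <- cfg$s0
  if (is.null(s0)) s0 <- Inf
  else if (is.character(s0) && tolower(s0) %in% c("inf", "infinite", "semi-infinite")) s0 <- Inf
  else s0 <- as.numeric(s0)
  grid <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) seq(as.numeric(x$from), as.numeric(x$to),
                        length.out = as.integer(x$length))
    else as.numeric(x)
  }
  medium <- optical_medium(
    mu_a = num(cfg$mu_a, 0), mu_s_prime = num(cfg$mu_s_prime, 1),
    g = num(cfg$g, 0), n_in = num(cfg$n_in, 1.4), n_out = num(cfg$n_out, 1.4)
  )
  geometry <- slab_geometry(
    s0 = s0, z_s = if (is.null(cfg$z_s)) NULL else as.numeric(cfg$z_s),
    z_s_mode = if (is.null(cfg$z_s_mode)) "inv_musp" else cfg$z_s_mode
  )
  list(medium = medium, geometry = geometry,
       rho = grid(cfg$rho), t_grid = grid(cfg$t_grid), z_grid = grid(cfg$z_grid))
}
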