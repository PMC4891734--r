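# Diffusion-equation reflectance of an infinite slab / semi-infinite medium
# by the method of images with extrapolated boundary conditions.
#
# The slab occupies 0 <= z <= s.  Zero-fluence planes sit at z = -a (top,
# a = z_e_top) and z = s + b (bottom, b = z_e_bottom); successive mirror
# reflections about the two planes generate, with L = s + a + b,
#   positive image sources  z_plus(m)  =  z_s + 2 m L
#   negative image sources  z_minus(m) = -2 a - z_s + 2 m L,   m in Z.
# The m = 0 pair is the semi-infinite dipole.  Unequal a and b support the
# "internal cut" sub-slab whose deep face carries no Fresnel reflection
# (b = 2D instead of 2AD), which the depth densities require.

# maximum image order per side before the series is declared non-convergent
.M_CAP <- 1e5
# beyond this order the tail-estimate correction is applied unconditionally
.M_SOFT_CAP <- 2e4
.SERIES_TOL <- 1e-12

# Eigenmode (long-time) representation of the slab TD total reflectance
# and its thickness derivative: with zero-fluence planes at -a and s + b,
# L = s + a + b and tau = pi^2 D v t / L^2,
#   R(s, t) = (2 D v / L^2) sum_n n pi cos(n pi a / L)
#             sin(n pi (a + z_s) / L) exp(-n^2 tau).
# The image (short-time) representation is its Poisson dual; at late times
# the image sum cancels catastrophically (an O(exp(-tau)) result from O(1)
# terms), while here a handful of modes suffice.  `s` may be a vector,
# `t` must be scalar here.
.td_eigen <- function(s, t, zs, a, b, D, v, deriv = FALSE) {
  n_rows <- max(length(s), length(t))
  s <- rep_len(s, n_rows); t <- rep_len(t, n_rows)
  L <- s + a + b
  tau <- pi^2 * D * v * t / L^2
  N <- max(ceiling(sqrt(46 / min(tau) + 1)), 2L) + 1L
  n <- seq_len(N)
  Tau <- outer(tau, n^2)                   # rows: s, cols: n
  Np <- matrix(n * pi, nrow = length(L), ncol = N, byrow = TRUE)
  Ca <- cos(Np * a / L)                    # cos(n pi a / L)
  Ss <- sin(Np * (a + zs) / L)             # sin(n pi (a+zs) / L)
  E <- exp(-Tau)
  pref <- 2 * D * v / L^2
  if (!deriv) {
    return(pref * rowSums(Np * Ca * Ss * E))
  }
  Sa <- sin(Np * a / L)
  Cs <- cos(Np * (a + zs) / L)
  inner <- Ca * Ss * (2 * Tau - 2) / L +
    Sa * (Np * a / L^2) * Ss -
    Ca * Cs * (Np * (a + zs) / L^2)
  pref * rowSums(Np * E * inner)
}

# Time-domain total reflectance core and its thickness derivative.
# Exactly one of `s`, `t` may be a vector.  Returns the series value
# without the absorption factor exp(-mu_a v t) unless `absorption = TRUE`.
# Rows (s, t combinations) with 4 D v t > L^2 are evaluated in the
# eigenmode representation, the rest through the image series.
.td_core <- function(s, t, zs, a, b, D, v, mu_a = 0,
                     absorption = TRUE, deriv = FALSE) {
  if (any(t <= 0)) stop("photon arrival time 't' must be > 0")
  if (length(s) > 1L && length(t) > 1L)
    stop("internal error: only one of 's','t' may be vectorized")
  if (any(!is.finite(s))) {
    if (deriv) stop("internal error: derivative undefined for s = Inf")
    # semi-infinite dipole
    w <- 4 * D * v * t
    S <- zs * exp(-zs^2 / w) + (2 * a + zs) * exp(-(2 * a + zs)^2 / w)
    out <- S / (2 * sqrt(4 * pi * D * v) * t^1.5)
    if (absorption) out <- out * exp(-mu_a * v * t)
    return(out)
  }
  n_rows <- max(length(s), length(t))
  sv <- rep_len(s, n_rows); tv <- rep_len(t, n_rows)
  L <- sv + a + b
  w <- 4 * D * v * tv                      # Gaussian width^2 per row
  late <- w > L^2
  out <- numeric(n_rows)
  if (any(late))
    out[late] <- .td_eigen(sv[late], tv[late], zs, a, b, D, v, deriv = deriv)
  if (any(!late)) {
    Li <- L[!late]; wi <- w[!late]; ti <- tv[!late]
    # image order needed for the Gaussian tails to fall below ~1e-20
    M <- ceiling((sqrt(max(wi) * 46) + 2 * (a + b) + 2 * zs) / (2 * min(Li))) + 2L
    if (M > .M_CAP) stop("image series did not converge within the order cap")
    m <- -M:M
    # rows pair (s, t); matrix/vector ops recycle the row vectors wi, ti
    Zp <- zs + 2 * outer(Li, m)
    Zm <- -2 * a - zs + 2 * outer(Li, m)
    if (deriv) {
      Mm <- matrix(m, nrow = nrow(Zp), ncol = length(m), byrow = TRUE)
      S <- rowSums(2 * Mm * ((1 - 2 * Zp^2 / wi) * exp(-Zp^2 / wi) -
                             (1 - 2 * Zm^2 / wi) * exp(-Zm^2 / wi)))
    } else {
      S <- rowSums(Zp * exp(-Zp^2 / wi) - Zm * exp(-Zm^2 / wi))
    }
    out[!late] <- S / (2 * sqrt(4 * pi * D * v) * ti^1.5)
  }
  if (absorption) out <- out * exp(-mu_a * v * tv)
  out
}

# Adaptive shell summation for the CW series: term_fun(m_vec) must return a
# matrix (n_rows x length(m_vec)) of per-image contributions.
#
# The summand at order m is the difference of a nearly cancelling image
# pair: asymptotically it decays like the product of a power law ~ 1/m^3
# (from the 1/r^3 dipole fall-off) and the exponential exp(-2 L mu_eff m).
# After each doubling block the remaining tail is estimated from the last
# single-order term h(M) as |h| * min(M/2, r/(1-r)) with r = exp(-q),
# q = 2 L mu_eff -- the exact tails of the two limiting behaviours -- and
# the signed estimate is *added* as a truncation correction, which removes
# the leading-order truncation error.  Convergence is judged against the
# largest row magnitude: rows where the series nearly cancels (density
# zeros, depths above the source) would otherwise demand image orders that
# double precision cannot resolve anyway.
.sum_shells_cw <- function(term_fun, n_rows, q) {
  q <- rep_len(q, n_rows)
  geo <- exp(-q) / (1 - exp(-q))          # geometric tail factor r/(1-r)
  total <- term_fun(0L)
  if (is.null(dim(total))) total <- matrix(total, nrow = n_rows)
  total <- rowSums(total)
  lo <- 1L
  width <- 2L
  repeat {
    hi <- lo + width - 1L
    if (hi > .M_CAP) stop("image series did not converge within the order cap")
    m <- c(-(hi:lo), lo:hi)
    shell <- rowSums(term_fun(m))
    total <- total + shell
    h <- rowSums(term_fun(c(-hi, hi)))    # last single-order pair term
    tail_est <- h * pmin(hi / 2, geo)
    scale <- max(abs(total))
    if (max(abs(tail_est)) < .SERIES_TOL * scale + 1e-300 || hi >= .M_SOFT_CAP) {
      total <- total + tail_est
      break
    }
    lo <- hi + 1L
    width <- width * 2L
  }
  total
}

# CW rho-resolved reflectance core (single dipole term and derivative).
.cw_dipole <- function(z0, rho, mu) {
  r <- sqrt(rho^2 + z0^2)
  z0 * (mu + 1 / r) * exp(-mu * r) / (4 * pi * r^2)
}

.cw_dipole_ds <- function(z0, rho, mu) {
  r <- sqrt(rho^2 + z0^2)
  exp(-mu * r) * ((mu * r + 1) / r^3 -
                  z0^2 * (mu^2 * r^2 + 3 * mu * r + 3) / r^5) / (4 * pi)
}

# CW reflectance at distance rho; `s` may be a vector, `rho` scalar (or the
# reverse).  mu is the effective attenuation coefficient.
.cw_core <- function(s, rho, zs, a, b, mu, deriv = FALSE) {
  if (any(rho < 0)) stop("'rho' must be >= 0")
  if (length(s) > 1L && length(rho) > 1L)
    stop("internal error: only one of 's','rho' may be vectorized")
  if (any(!is.finite(s))) {
    if (deriv) stop("internal error: derivative undefined for s = Inf")
    return(.cw_dipole(zs, rho, mu) - .cw_dipole(-2 * a - zs, rho, mu))
  }
  L <- s + a + b
  n_rows <- max(length(s), length(rho))
  term_fun <- function(m) {
    Zp <- zs + 2 * outer(L, m)
    Zm <- -2 * a - zs + 2 * outer(L, m)
    R <- matrix(rho, nrow = n_rows, ncol = length(m))
    if (deriv) {
      Mm <- matrix(m, nrow = n_rows, ncol = length(m), byrow = TRUE)
      2 * Mm * (.cw_dipole_ds(Zp, R, mu) - .cw_dipole_ds(Zm, R, mu))
    } else {
      .cw_dipole(Zp, R, mu) - .cw_dipole(Zm, R, mu)
    }
  }
  .sum_shells_cw(term_fun, n_rows, q = 2 * L * mu)
}

# CW total reflectance (dimensionless) and derivative in s.  The image
# series resums in closed form to the 1D CW Green's-function expression
#   R(s) = cosh(mu a) sinh(mu (s + b - z_s)) / sinh(mu L),  L = s + a + b,
#   dR/ds = mu cosh(mu a) sinh(mu (a + z_s)) / sinh(mu L)^2,
# (checked to agree with the shell-summed series to full precision), which
# is evaluated in overflow-safe exponential form.  R vanishes exactly at
# s = z_s - b and is the analytic continuation (negative) below; its
# s -> Inf limit is the semi-infinite dipole value.
.cw_total_core <- function(s, zs, a, b, mu, deriv = FALSE) {
  if (any(!is.finite(s))) {
    if (deriv) stop("internal error: derivative undefined for s = Inf")
    return(0.5 * (exp(-mu * zs) + exp(-mu * (2 * a + zs))))
  }
  y <- mu * (s + a + b)
  if (deriv) {
    # 4 mu cosh(mu a) sinh(mu (a + zs)) e^{-2y} / (1 - e^{-2y})^2
    4 * mu * cosh(mu * a) * sinh(mu * (a + zs)) *
      exp(-2 * y) / (1 - exp(-2 * y))^2
  } else {
    x <- mu * (s + b - zs)
    cosh(mu * a) * sign(x) * exp(abs(x) - y) *
      (1 - exp(-2 * abs(x))) / (1 - exp(-2 * y))
  }
}

# resolve boundary extrapolation lengths for a (possibly overridden) slab
.resolve_faces <- function(medium, geometry, internal_bottom) {
  dq <- derived_quantities(medium, geometry)
  b <- if (internal_bottom) dq$z_e_internal else dq$z_e_bottom
  list(dq = dq, a = dq$z_e_top, b = b)
}

#' Time-domain total reflectance of a slab
#'
#' Total (spatially integrated) time-resolved diffuse reflectance of an
#' infinite slab or semi-infinite medium, in ps^-1 per launched photon,
#' from the image-source series under extrapolated boundary conditions.
#' Absorption enters only through the factor `exp(-mu_a v t)`.
#'
#' @param medium an [optical_medium()].
#' @param geometry a [slab_geometry()].
#' @param t photon arrival times (ps), vectorized; must be `> 0`.
#' @param s optional slab thickness override (mm); defaults to the
#'   geometry's `s0`.  Must exceed the source depth `z_s`.
#' @param internal_bottom if `TRUE` the deep face is treated as an internal
#'   cut free of Fresnel reflections (`z_e0 = 2D` instead of `2AD`): the
#'   `R'` variant used by the depth densities.
#' @return Reflectance values (ps^-1), same length as `t`.
#' @export
td_total_reflectance <- function(medium, geometry, t, s = NULL,
                                 internal_bottom = FALSE) {
  f <- .resolve_faces(medium, geometry, internal_bottom)
  if (is.null(s)) s <- f$dq$s0
  if (any(is.finite(s) & s <= f$dq$z_s))
    stop("slab thickness must exceed the source depth z_s")
  .td_core(s, t, zs = f$dq$z_s, a = f$a, b = f$b, D = f$dq$D, v = f$dq$v,
           mu_a = medium$mu_a, absorption = TRUE)
}

#' Time-domain reflectance at a source-detector distance
#'
#' Time-resolved reflectance density (mm^-2 ps^-1) at radial distance `rho`
#' from the injection point.  In the diffusion solution for laterally
#' unbounded geometries the whole rho dependence is the multiplicative
#' factor `exp(-rho^2/(4 D v t)) / (4 pi D v t)` times the total
#' reflectance, and the identity is used verbatim here: the factorization
#' is exact to machine precision.
#'
#' @inheritParams td_total_reflectance
#' @param rho source-detector distance (mm), `>= 0`; scalar if `t` is a
#'   vector (and vice versa).
#' @return Reflectance density values (mm^-2 ps^-1).
#' @export
td_reflectance <- function(medium, geometry, rho, t, s = NULL,
                           internal_bottom = FALSE) {
  if (any(rho < 0)) stop("'rho' must be >= 0")
  tot <- td_total_reflectance(medium, geometry, t, s = s,
                              internal_bottom = internal_bottom)
  Dv <- medium$D * medium$v
  tot * exp(-rho^2 / (4 * Dv * t)) / (4 * pi * Dv * t)
}

#' Continuous-wave reflectance at a source-detector distance
#'
#' Steady-state diffuse reflectance density (mm^-2) at distance `rho`, as
#' the image-source sum of dipole terms
#' `z_im (mu_eff + 1/r) exp(-mu_eff r) / (4 pi r^2)`, `r = sqrt(rho^2 +
#' z_im^2)`.  Equals the time integral of [td_reflectance()].  A vanishing
#' `mu_a` is evaluated at the small-absorption substitute `1e-9` mm^-1,
#' where the expression is otherwise indeterminate.
#'
#' @inheritParams td_reflectance
#' @return Reflectance density values (mm^-2), same length as `rho`.
#' @export
cw_reflectance <- function(medium, geometry, rho, s = NULL,
                           internal_bottom = FALSE) {
  f <- .resolve_faces(medium, geometry, internal_bottom)
  if (is.null(s)) s <- f$dq$s0
  if (any(is.finite(s) & s <= f$dq$z_s))
    stop("slab thickness must exceed the source depth z_s")
  mu <- .mu_eff_substitute(medium)
  .cw_core(s, rho, zs = f$dq$z_s, a = f$a, b = f$b, mu = mu)
}

#' Continuous-wave total reflectance of a slab
#'
#' Dimensionless steady-state total reflectance: the closed-form
#' exponential series `(1/2) sum sign(z_im) exp(-mu_eff |z_im|)` over the
#' image sources.  Equals `2 pi` times the radial integral of
#' [cw_reflectance()] and the time integral of [td_total_reflectance()].
#' For a matched, non-absorbing semi-infinite medium it equals 1 (photon
#' conservation).
#'
#' @inheritParams td_total_reflectance
#' @return A scalar (or vector along `s`) total reflectance.
#' @export
cw_total_reflectance <- function(medium, geometry, s = NULL,
                                 internal_bottom = FALSE) {
  f <- .resolve_faces(medium, geometry, internal_bottom)
  if (is.null(s)) s <- f$dq$s0
  if (any(is.finite(s) & s <= f$dq$z_s))
    stop("slab thickness must exceed the source depth z_s")
  mu <- .mu_eff_substitute(medium)
  .cw_total_core(s, zs = f$dq$z_s, a = f$a, b = f$b, mu = mu)
}

# small-absorption substitute for CW formulas indeterminate at mu_a = 0
.MU_A_SUBSTITUTE <- 1e-9

.mu_eff_substitute <- function(medium) {
  mu_a <- if (medium$mu_a > 0) medium$mu_a else .MU_A_SUBSTITUTE
  sqrt(3 * mu_a * medium$mu_s_prime)
}
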