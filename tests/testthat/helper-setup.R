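# Shared fixtures: tissue-like media and geometries used across the suite.

tissue_matched <- function(mu_a = 0)
  optical_medium(mu_a = mu_a, mu_s_prime = 1, n_in = 1.4, n_out = 1.4)

tissue_mismatched <- function(mu_a = 0)
  optical_medium(mu_a = mu_a, mu_s_prime = 1, n_in = 1.4, n_out = 1.0)

semi_inf <- function(...) slab_geometry(Inf, ...)
slab20 <- function(...) slab_geometry(20, ...)

# central finite difference in slab thickness of a reflectance function:
# the in-repo numerical oracle for the closed-form densities
fd_density <- function(refl_fun, denom, z, h = 1e-3) {
  (refl_fun(z + h) - refl_fun(z - h)) / (2 * h) / denom
}
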