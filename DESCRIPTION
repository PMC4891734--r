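Package: photondepth
Title: Statistics of Photon Penetration Depth in Turbid Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Diffusion-approximation statistics of the maximum depth reached
    by photons that are re-emitted from the surface of a scattering slab or
    semi-infinite medium: probability densities of the maximum penetration
    depth conditioned on arrival time or source-detector distance, their
    means in the time domain and the continuous-wave domain, extrapolated
    boundary conditions with Fresnel index mismatch, and a Monte Carlo
    photon-transport oracle (Henyey-Greenstein scattering) implementing
    time-binned tallies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
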