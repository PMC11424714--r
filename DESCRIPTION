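Package: nemadisk
Title: Rotational Hydrodynamics of a Disk in a Thin Weakly Nematic Film
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-analytical solution for a disk-shaped inclusion (a model
    membrane protein) rotating at low Reynolds number in a thin, uniaxially
    anisotropic (weakly nematic) two-dimensional fluid film coupled to a
    substrate by linear friction.  Provides the anisotropic Fourier-space
    Green's function machinery (modified-Bessel products with Laurent
    principal-part subtraction), the exact zero-friction solution in
    terminating Gauss hypergeometric form, second-order perturbative
    resistance and mobility coefficients generalising the Saffman-Delbrueck
    and Evans-Sackmann results, and a boundary-Galerkin spectral solver for
    arbitrary anisotropy that serves as a numerical reference solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
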