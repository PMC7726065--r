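Package: neurofield
Title: Spectral and Hopf Bifurcation Analysis of Neural Fields with
    Transmission Delays and Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic machinery for one-dimensional neural field models with
    distance-dependent transmission delays and gap-junction diffusion under
    no-flux boundary conditions. Eigenvalues of the linearisation are computed
    from determinant conditions on small complex matrices built from the roots
    of an explicit characteristic polynomial; eigenvectors are hyperbolic-cosine
    or -sine expansions. The resolvent of the characteristic operator is
    evaluated in closed form via a variation-of-constants construction, which
    feeds a residue formula for the spectral projection and hence the Hopf
    normal-form coefficient c1 and first Lyapunov coefficient l1. A Newton
    locator finds Hopf points in any model parameter. A method-of-steps
    delay-differential simulator on the trapezoid/ghost-point spatial
    discretisation doubles as a brute-force validation oracle for the
    analytic spectrum and resolvent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
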