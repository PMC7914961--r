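Package: mdea
Title: Diffusion Entropy Analysis with Stripes for Crucial-Event Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generators and estimators for anomalous-diffusion scaling in
    single time series. Synthesizes renewal event trains with hyperbolic
    (inverse-power-law) waiting times ("crucial events"), fractional Gaussian
    noise by exact circulant embedding, Mandelbrot-van Ness summation or
    spectral superposition, and their subordinated combination. Analyzes a
    series with Diffusion Entropy Analysis (DEA): the Shannon entropy S(l) of
    the mobile-window displacement distribution grows as A + delta*log(l), and
    the fitted slope delta is the scaling index. The stripe-augmented variant
    (MDEA) counts crossings between equal-width amplitude stripes and runs DEA
    on the event-count walker, which filters fractional-Brownian-motion memory
    and exposes the crucial-event scaling delta = mu - 1 (1 < mu < 2) or
    1/(mu - 1) (2 < mu < 3).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
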