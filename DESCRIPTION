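Package: cxsteer
Title: Rule-Based Construction, Fitting and Simulation of Insect
    Central-Complex Steering Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Construct, validate, fit, and simulate firing-rate models of
    the insect central-complex steering circuit, in which compass neurons
    encoding heading and goal neurons encoding a desired direction
    converge on left/right steering populations whose activity difference
    is the turn command.  Provides positive-basis tests and
    population-vector decoding for angular population codes, constructors
    for uniform, fly-like, and irregular ("unintuitive") circuits plus
    deliberate rule-breaking variants, inference of goal-neuron
    associated directions from connectivity, differential-evolution
    fitting of sparse circuits against a reference steering surface, and
    closed-loop heading-control protocols (von Mises random walk, smooth
    turn, step change) with gain tuning, angular error metrics, and
    stable-heading detection.  Data-frame-first: simulation traces,
    steering surfaces, and inference results are tibbles with ggplot2
    autoplot() methods and broom-style tidy()/glance() summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
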