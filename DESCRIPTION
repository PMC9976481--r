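Package: spiralspread
Title: Population Spread, Behavioural Switching and Dispersal Kernels in
    Linear-Tunnel Arenas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the spatial spread of groups of walking insects
    released at the centre of a long linear tunnel folded into a double-spiral
    arena, and to connect movement to parasitism. Provides arena geometry and
    orthogonal projection onto the tunnel skeleton, an agent-based simulator of
    a switching heterogeneous-diffusion process with resident and explorer
    movement modes, host encounter and saturating parasitism, mean squared
    displacement and population-quantile propagation statistics with
    replicate-level bootstrap confidence intervals, diffusion-coefficient and
    piecewise (changepoint) regression, zero-mean Gaussian mixture and Student
    distribution fits with AIC model selection, time-resolved decomposition of
    the population into resident and explorer components, dispersal-kernel
    estimation, discoverer-type assignment and gain-function analysis. All
    user-facing functions take data frames and return tibbles so that analyses
    compose with the pipe.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    segmented,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
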