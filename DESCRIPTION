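Package: photoroutes
Title: Leaf-to-Crop Simulation of Photosynthesis-Enhancing Routes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of biochemical leaf photosynthesis (C3,
    C4 and a cyanobacterial CO2-concentrating-mechanism variant of the C4
    model) coupled to stomatal conductance and leaf energy balance, scaled
    to sun/shade canopies and to whole growing seasons with a simplified
    daily crop simulator. The package builds the ten model configurations
    (a default C3 crop plus nine photosynthesis-enhancing engineering
    routes), generates synthetic site weather for tropical, subtropical and
    temperate rice environments with a 2050 climate transform, and runs
    factorial scenario experiments that decompose crop mass differences
    into intercepted radiation, light-use efficiency, respiration, root
    fraction and senescence components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
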