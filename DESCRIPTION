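Package: mlcedge
Title: Rounded Leaf-End Penumbra and Radiation Field Offsets for
    Multileaf Collimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytical and numerical evaluation of the rounded
    (circular-arc) leaf-end effect of single-focused multileaf collimators
    on penumbra characteristics. Implements the tangent-line (light-field)
    and half-value-layer (radiation-field) leaf-edge constructions with
    leaf-position, radiation-field and physical-nominal offset bookkeeping;
    a deterministic primary-fluence ray tracer with exact analytic in-leaf
    path lengths for extended Gaussian focal spots; multi-peak Gaussian
    edge fitting with 50% field-edge and 20-80% penumbra-width extraction;
    and sweep orchestration over leaf-end radii, focal-spot sizes and
    nominal leaf positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
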