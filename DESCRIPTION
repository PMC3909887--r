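Package: countnet
Title: Embodied Number Learning with Recurrent Counting Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a neural cognitive architecture in which number
    knowledge is grounded in finger counting and spoken number words. Two
    small recurrent sequence memories (a lateralized finger-motor
    controller and an auditory memory) learn the 1-10 counting sequences
    from in-package tables of finger joint angles and mel-frequency
    cepstral coefficients, trained by a from-scratch Levenberg-Marquardt
    optimizer with derivatives propagated through the unrolled recurrence.
    Their hidden activations serve as internal number representations,
    which a softmax competitive classifier maps to the ten number classes;
    a switch/associative layer learns linear cross-modal mappings between
    the two hidden layers and orchestrates two-operand addition. Includes
    the repeated-run classification evaluation protocol, representation
    clustering, and an end-to-end addition demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
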