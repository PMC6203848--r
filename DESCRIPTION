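Package: oligostore
Title: Digital Data Storage on Sequence-Defined Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for writing digital information into collections of
    sequence-defined oligomers and reading it back from tandem mass
    spectra. Binary data are converted with a positional numeral system
    into short index-tagged monomer sequences (with a length record and
    non-coding spacer padding), and monomer sequences are reconstructed
    de novo from MS/MS peak lists by walking the complementary
    start-containing and stop-containing fragment-mass ladders produced
    by backbone urethane cleavage. Includes the mass/fragmentation model
    linking the two codecs, a seeded synthetic-spectrum generator with
    controllable peak dropout, noise and m/z jitter, readers and writers
    for MGF, peak-list CSV, PBM bitmaps and fragment manifests, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
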