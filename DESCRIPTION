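Package: chromkit
Title: Vendor-Neutral Processing of Nominal-Mass GC/MS Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in-memory object model and scriptable toolkit for editing and
    analyzing nominal-mass GC/MS chromatographic data. Provides converters for
    mzXML, ANDI-MS NetCDF and a documented native XML format with content-based
    format probing; quality-enhancing filters (Savitzky-Golay smoothing,
    background removal, mean normalization) operating on retention-time
    selections; pluggable baseline detectors; peak detection decoupled from
    peak integration so that peaks from any detector can be integrated by a
    single integrator; peak geometry (flank tangents, width at half height);
    mass-spectrum comparison and identification against MSP libraries;
    reversible editing sessions with undo/redo; a deterministic synthetic
    chromatogram generator for testing; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    xml2
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
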