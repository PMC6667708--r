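Package: zoomsid
Title: Taxonomic Identification of Bone Collagen by ZooMS Peptide Mass Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Zooarchaeology by Mass Spectrometry (ZooMS): reading
    MALDI-ToF collagen peptide-mass-fingerprint spectra (mzML or two-column
    text), replicate averaging, Savitzky-Golay smoothing, SNIP baseline
    estimation, robust noise estimation and signal-to-noise based peak
    picking, linear mass recalibration against calibrant peptides, flagging
    of keratin contaminant peaks and equally spaced polymer peak series,
    matching of picked peaks against collagen m/z marker panels (including a
    built-in five-species cervid panel), and tiered taxonomic assignment
    (species / probable / higher rank / unidentified). A synthetic spectrum
    generator with planted ground truth, contaminant injection and
    mass-dependent attenuation of high molecular weight peptides supports
    validation of every pipeline stage, including the degraded spectra
    typical of non-destructive (storage-bag or eraser) collagen recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    mzR,
    signal,
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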