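Package: hydromelt
Title: Protein Hydration Melting Diagrams from Wide-Line 1H NMR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and analyses protein-hydration melting diagrams from
    two-component wide-line 1H NMR free-induction-decay (FID) signals
    recorded across temperature. Decomposes each FID into a fast
    (immobile-proton) and a slow (mobile-water) component, extrapolates the
    slow amplitude across the spectrometer dead time, applies the Curie-law
    1/T correction, and assembles mobile-water fractions on a normalized
    fundamental-temperature scale. Fits the onset-step + plateau +
    power-series melting-diagram model, derives the differential melting
    diagram (the distribution of potential-energy barriers to bound-water
    motion), and computes heterogeneity order parameters (HeR, HeRn, HeM)
    and bound-water counts per protein molecule that distinguish globular
    from intrinsically disordered proteins. Includes a synthetic-data
    generator with ubiquitin-like, ERD10-like and bulk-water presets, and a
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
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
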