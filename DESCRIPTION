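Package: shootpheno
Title: Multi-View Shoot Segmentation, Growth Analytics and PSII Quenching Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative shoot phenotyping for multi-view RGB plant imaging
    and pulse-amplitude-modulation (PAM) chlorophyll fluorescence. Segments
    green shoot masks by fusing hue thresholding with Canny edge tracking so
    that 1-2 pixel tendrils survive segmentation, calibrates projected areas
    to square millimetres, combines top/front/side projections into a total
    green area, and derives normalized green area and relative growth rate.
    A quenching analyser extracts the four fluorescence levels (F0, FM, Ft,
    FM') from a timed induction recording and computes the minimal
    light-adapted fluorescence F0' and the six PSII quantum-yield and
    quenching parameters, per region or per pixel. Nonparametric group
    statistics (Mann-Whitney U, Spearman correlation) and a fully seeded
    synthetic-data generator make the whole pipeline testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    pracma,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
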