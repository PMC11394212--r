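Package: binbat
Title: Automated Bin-Based Basophil Activation Test Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of basophil activation test (BAT) flow
    cytometry data using a bin-based (pattern recognition of immune
    cells) approach. Reads FCS 3.0/3.1 or CSV event tables, pregates
    singlets and removes debris and thrombocytes, identifies basophils
    automatically via SSC/FcERIa thresholds with CD32 as an auxiliary
    purity marker, calibrates the CD63 activation threshold with the
    one-percent-in-unstimulated convention and the CD32 threshold with
    the seventy-percent red-percentage rule, quantifies CD63+
    activation, attaches quality-control flags, computes cohort
    statistics (Wilcoxon matched-pairs signed rank, Pearson agreement,
    IQR outlier flagging), and renders bin plots and violin summaries
    as SVG. Includes a synthetic whole-blood cytometry generator with
    retained ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
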