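Package: snlipid
Title: Sn-Positional and Compositional Lipid Isomer Deconvolution for
    Targeted prm-PASEF Lipidomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deconvolves coeluting phospholipid isomers in targeted
    (parallel reaction monitoring) lipidomics. Implements an exponential
    "SN regression" calibration linking the sn2/sn1 carboxylate fragment
    peak-area ratio to the fraction of an sn-positional isomer, with
    fitting, inversion, purity flagging and a phospholipase-A2 orthogonal
    purity calculation; summed-fragment apportionment of MS1 precursor
    signal among fatty-acyl compositional isomers; a triacylglycerol
    quantifier-ion selection rule for shared neutral-loss fragments;
    internal-standard based quantification with CV, IQR-outlier, LOD/LOQ,
    linearity, MS1/MS2 concordance and spike-recovery statistics;
    scheduled target-list construction for ion-mobility PRM acquisition;
    and seeded simulators generating every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
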