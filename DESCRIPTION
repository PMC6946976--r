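Package: founderTrace
Title: Forward Simulation of Conserved Livestock Populations with
    Founder-Labeled Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time gene-dropping simulator for closed livestock
    conservation populations in which every allele copy carries two labels:
    its allelic state and the founder individual it descends from.  The
    double label makes identity-by-descent, founder genomic contributions
    and family survival exactly observable rather than inferred.  The
    package builds a base population at mutation-drift equilibrium,
    manages it under the equal-family-contribution replacement scheme used
    by Chinese pig conservation herds, and reports gene-frequency diversity
    measures (He, Ho, Ao, Ae, PIC, Pp, rare alleles), label-based IBD and
    state-based IBS probabilities, genealogical inbreeding, VanRaden
    genomic relationships, linkage-disequilibrium effective population
    size, and parental genomic components with their relative change and
    family-survival curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
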