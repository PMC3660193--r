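Package: linkscape
Title: Linkage Maps, Segregation Distortion and Recombination Landscapes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of genetic linkage maps from
    full-sib mapping populations of outcrossing species. Implements a
    forward meiosis simulator for outbred two-way pseudo-testcross (CP)
    and selfed F2 designs with embryo-viability selection and local
    recombination-rate modifiers; per-marker Mendelian segregation tests
    and detection of segregation distortion regions (SDRs) with an
    inbred/outbred contrast to localize deleterious alleles revealed by
    inbreeding; two-point recombination-fraction and LOD estimation with
    Kosambi distances, marker grouping, ordering and accessory-marker
    placement; genome length and map coverage estimators; kernel-bandwidth
    sliding-window marker-density tracks with Poisson thresholds for
    recombination hotspot and coldspot calling; and statistical comparison
    of recombination rates between maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
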