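Package: olivosim
Title: Mesoscale Spiking Simulation of Olivocerebellar Eyeblink Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scale-configurable spiking simulator of the olivocerebellar
    circuit during classical eyeblink conditioning (CEBC). Builds a
    two-micromodule (downbound/upbound) network of extended generalized
    leaky integrate-and-fire point neurons spanning the cerebellar cortex,
    deep cerebellar nuclei and inferior olive, equips it with two climbing
    fibre supervised plasticity rules (parallel fibre to Purkinje cell and
    parallel fibre to molecular layer interneuron), runs the full CS/US
    trial protocol including the conditioned olivary response, decodes the
    nuclear output into an analog eyelid signal with conditioned-response
    detection, and provides spike density function analysis of suppression,
    facilitation, recruitment and plasticity development. Knock-out lesion
    configurations emulate mutant-mouse phenotypes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
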