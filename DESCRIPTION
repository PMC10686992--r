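Package: groupmix
Title: Group Mixing, Adjusted Assortativity and Homophily Estimation in Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring group mixing in node-attributed networks.
    Computes nominal (discrete) assortativity from mixing matrices, edge
    lists or aggregate edge counts, and the group-size adjusted nominal
    assortativity that removes the bias introduced by unequal group sizes.
    Provides closed-form expectations of both coefficients under a random
    network model with tunable group-mixing tendencies, an analytical
    estimator of asymmetric intra-group mixing (separate minority and
    majority homophily), seeded generative models (Erdos-Renyi and
    Barabasi-Albert variants with homophily) for validation and
    calibration, and aggregate gender-mixing counts for nine published
    collaboration and face-to-face contact networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
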