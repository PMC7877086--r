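Package: ecvtask
Title: Free-Breathing, ECG-Less Myocardial T1 and ECV Mapping by Low-Rank
    Tensor Image Reconstruction
Version: 0.1.0
Authors@R:
    person("ecvtask", "developers", email = "ecvtask@example.com",
           role = c("aut", "cre"))
Description: Quantitative cardiac MRI toolbox for extracellular volume
    fraction (ECV) mapping in small animals at high heart rates, without
    ECG triggering or respiratory gating.  Implements joint pre/post
    contrast inversion-recovery FLASH Bloch simulation and dictionary
    subspace modeling, a beating/breathing digital rat-heart phantom with
    a Cartesian line-by-line k-space acquisition simulator, self-gated
    respiratory/cardiac binning by modified k-means, Bloch-constrained
    low-rank tensor completion with HOSVD factor extraction,
    wavelet-regularized spatial-basis recovery, joint five-parameter
    pixel-wise T1 fitting, and ECV computation with septal statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    graphics,
    jsonlite,
    rhdf5,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
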