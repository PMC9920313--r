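Package: freqgan
Title: Unpaired 3D CBCT-to-CT Translation with a Frequency-Domain Structure Loss
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for unpaired 3D volume-to-volume translation of cone-beam CT
    (CBCT) to CT-like images with a CycleGAN whose training objective is
    augmented by a generalized frequency-domain structure loss: the L1 or L2
    distance between tanh-compressed, zero-centred magnitude spectra of the
    orthonormal 3D discrete Fourier transform of a generator's input and its
    translation. Includes volume I/O (NIfTI, NRRD, MetaImage) with spatial
    metadata, deterministic preprocessing (resampling, body masking,
    field-of-view truncation, Hounsfield-unit windowing), a 3D VNet generator
    and 3D PatchGAN discriminator with a self-contained CPU training engine,
    dataset-level procedures (modal-spacing selection, weak-pair formation),
    an image-quality metric suite (MAE, MSE, NMSE, PSNR, SSIM, Dice, HU
    histograms, line profiles), and a synthetic anthropomorphic phantom
    generator producing paired CT-like and CBCT-like volumes for testing.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
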