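Package: neuroinpaint
Title: Diffusion-Based Lesion Inpainting for 3D Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mask-constrained inpainting of lesions, tumors, and resection
    cavities in 3D structural brain MRI with a denoising diffusion
    probabilistic model (DDPM). A 2D slab denoiser with voxel-size-independent
    (VINN) resampling layers serves isotropic inputs from 0.7 to 1.0 mm with a
    single set of weights; inference rotates among axial, coronal, and sagittal
    views with shifted slab offsets so 2D models assemble a coherent 3D volume,
    restricts network calls to lesion-intersecting slabs, and guarantees that
    voxels outside the lesion mask are returned bit-identical to the input.
    Includes a seeded synthetic-phantom module (labeled brain-like volumes,
    tumor insertion with a mass-effect deformation, multifocal white-matter
    lesions), evaluation metrics (SSIM, PSNR, Dice, 95th-percentile Hausdorff
    distance, absolute-agreement ICC), and lesion-to-surface projection for
    excluding affected vertices from group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
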