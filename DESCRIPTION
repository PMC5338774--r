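Package: cranioplan
Title: Headless Planning of Patient-Specific Cranial Implants from
    Mirrored Skull Templates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scriptable planning of cranial implants for cranioplasty from
    CT-derived STL surface meshes. The healthy side of the skull is mirrored
    across the midsagittal plane to serve as a curvature template for the
    defect; typed landmarks (outer/inner edge and outer/inner surface
    markers) are placed on the defect rim and the template, regularised by a
    radius-limited, layer-respecting Laplacian smoother with fixed,
    optionally up-weighted border markers, and tetrahedralized by a 3D
    Delaunay triangulation with circumradius (alpha) filtering to yield a
    watertight implant surface for STL export and 3D printing. Includes STL
    read/write (ASCII and binary), voxel-based Dice/Hausdorff/volume
    agreement metrics, a synthetic skull-shell phantom generator with
    ground-truth defect patches, Likert questionnaire summaries, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
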