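Package: chromaglint
Title: Gloss, Relief and the Perception of Surface Color
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for psychophysical studies of how surface
    gloss, mesoscopic relief and viewing orientation bias perceived color
    saturation (C*/L*) and lightness. Provides CIE LCH <-> sRGB colorimetry
    with explicit gamut handling and per-hue chroma/saturation gamut
    boundaries; stimulus-design helpers for asymmetric-matching grids and
    paired-comparison trial lists; a simplified direct-illumination renderer
    (Lambertian diffuse plus Beckmann microfacet specular) with a physical
    specular-coverage statistic; aggregation of matching and two-alternative
    forced-choice responses including balanced repeated-measures ANOVA; a
    weighted linear gloss/coverage cue-combination model fit by grid sweep;
    and a synthetic-observer generator with known ground truth for
    end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
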