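Package: costim
Title: Co-Stimulation Phosphoproteomics and Logic-ODE Modelling of MAPK
    Crosstalk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for double time-course (co-stimulation)
    phosphoproteomics of the budding yeast high-osmolarity glycerol (HOG)
    and mating pheromone MAPK pathways. Generates synthetic replicate-level
    phosphopeptide intensity datasets over a 6x6 NaCl-by-pheromone
    stimulation matrix with planted dynamic archetypes; normalises by total
    ion current, filters, averages replicates and imputes by cubic splines;
    classifies per-peptide Shape and Intensity effects by K-means curve
    clustering; computes stimulus-specificity matrices and vectors and an
    automated pattern-match screen; builds phosphopeptide-level logic
    networks from a protein-level prior with combinatorial edge expansion
    and mechanistic variants; and transforms networks into logic ordinary
    differential equations fitted to MIDAS-format data by seeded multistart
    optimisation with mean-squared-error and Akaike information criterion
    model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
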