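Package: ms2pfas
Title: Latent-Space Annotation of PFAS from Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nontargeted screening of per- and polyfluoroalkyl substances
    (PFAS) from MS2 spectra by projecting spectra into a chemical latent
    space. A recurrent SMILES autoencoder learns molecular embeddings; a
    spectral encoder with intensity-modulated rotary attention and a
    convolutional feature bank is aligned to those embeddings by mean
    squared error. Candidate structures are retrieved as nearest
    neighbours in the latent space and scored for PFAS annotation
    confidence under the revised OECD structural definition. Includes
    MGF/MSP spectral I/O with validity filtering, neutral-loss feature
    augmentation, 0.01-Da peak tokenization, compound-level dataset
    splitting and balancing, maximum-common-substructure and fingerprint
    evaluation metrics, and a synthetic in-silico fragmentation generator
    so the whole pipeline is trainable at desk scale without licensed
    spectral libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
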