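---
title: "Latent-space annotation of PFAS from MS2 spectra: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space annotation of PFAS from MS2 spectra: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Per- and polyfluoroalkyl substances (PFAS) are a large, open-ended class of
fluorinated chemicals; nontargeted screening of environmental samples by
LC-HRMS produces thousands of MS2 spectra of which only a tiny fraction match
spectral libraries. `ms2pfas` implements a spectrum-to-structure retrieval
approach: instead of predicting a structure directly from a spectrum, both
molecules and spectra are projected into one *chemical latent space*, and
candidates are retrieved as nearest neighbours of the spectrum embedding.
The key advantage is that the molecular side of the space can be learned from
cheap unlabeled structure libraries, while only the (scarce) spectra are
needed to train the spectral projection.

The pipeline has two trainable components:

1. **A SMILES autoencoder** (GRU encoder/decoder). It is pretrained
   unsupervised to translate *randomized* SMILES serializations of a molecule
   into the *canonical* serialization. The encoder's final hidden state is
   mapped linearly to a latent code `E_a`; because arbitrary serializations
   of one molecule must decode to the same canonical string, the code is
   forced to represent the molecule, not the string.
2. **A spectral encoder** (self-attention with intensity-modulated rotary
   encoding, followed by a convolutional feature bank). It maps a tokenized
   spectrum to `E_s` in the same space, trained by minimizing the mean
   squared error to the frozen `E_a` of the known parent molecule.

At inference, a query spectrum is embedded and the `k = 20` nearest library
structures (mean squared error distance) are returned. The per-spectrum
**confidence score** is the percentage of those candidates that satisfy the
revised OECD structural definition of PFAS — a perfluorinated −CF3 or −CF2−
group, i.e. a carbon with at least two fluorine neighbours and no H, Cl, Br
or I attached to that carbon. Because the score only asks *how PFAS-like the
latent neighbourhood is*, it degrades gracefully: a spectrum of a PFAS absent
from the library still lands among fluorinated homologues.

## Data contracts and filters

Spectra enter the pipeline from MGF or MSP files and must pass three
validity criteria: precursor m/z < 1000; negative ionization with an
\[M−H\]⁻ adduct; collision energy in \[10, 50\] eV (inclusive at both ends —
the bounds are stated as a range, and boundary energies are routinely
reported in library spectra). Ramped collision energies ("20-40") are
rejected as missing metadata. Molecules are stripped of stereochemistry and
salts, restricted to C, N, H, O, P, S, Cl, Br, F, I, B, capped at 1000 Da
monoisotopic mass and 110 SMILES tokens. Compound identity everywhere is the
first 14 characters of the standard InChIKey (InChIKey2D), so stereoisomers
are one compound for splitting and scoring purposes.

Dataset partitioning is compound-level: InChIKey2D keys are randomly split
90/10 (train/test) and all spectra of a compound travel together; a
validation subset, when requested, is carved from the training compounds by
the same keyed mechanism. Training spectra are balanced to exactly 50
spectra per compound: under-represented compounds are replicated
`floor(50/n)` times with the remainder drawn without replacement;
over-represented ones keep a uniform random subset. The replicate-then-
sample order is a documented choice; the balancing goal (a perfectly flat
histogram at the threshold) is what the tests pin down.

## Peak tokenization and loss features

Each peak's m/z is rounded to two decimals (half away from zero) and mapped
to the integer token `round(100 * mz)`, a vocabulary of 100001 ids covering
(0, 1000\] Da at 0.01-Da resolution. One more decimal would multiply the
vocabulary tenfold for no benefit at typical HRMS mass accuracy. Intensities
are normalized to the base peak.

For every fragment peak a *neutral loss* feature is appended at
`precursor_mz − mz` carrying the fragment's intensity: the uncharged
counterpart of the detected ion, invisible in the raw spectrum but highly
diagnostic (e.g. losses of HF or CO2 from perfluoro acids). The token
sequence is ordered fragments-then-losses, each ascending in m/z, with a
per-token segment flag; a shared vocabulary with a segment flag (rather than
a second vocabulary) is an implementation assumption, recorded here. The
sequence order carries no meaning to the model — relative information enters
through intensities, not positions — so a deterministic canonical order was
chosen purely for reproducibility.

## Intensity-modulated rotary attention

Standard rotary positional encoding rotates query/key vectors by angles
proportional to a token's *position*. Here the position index is replaced by
`intensity × rope_scale`, so the pre-softmax interaction between two peaks
depends only on their *intensity difference*: the attention mechanism sees
"how much stronger is this peak than that one" rather than "how far apart
they sit in the sequence". Rotations are norm-preserving per 2-D feature
pair and reduce to the identity at zero intensity; both properties are
tested. `rope_scale` defaults to 100, mapping the intensity interval \[0, 1\]
onto the angular range that integer positions 0–100 would occupy in ordinary
rotary encoding — an uninformative default chosen once, not tuned.

The attention outputs of all layers are stacked into a 2-D map (sequence ×
layer-features) that feeds a bank of 11 convolutional kernels with lengths
1, 3, ..., 21 along the sequence axis, each followed by ReLU and global max
pooling; pooled features are linearly mapped to the latent dimension. The
parallel multi-kernel layout (rather than a serial 11-deep stack) is the
package's reading of "multiple kernel sizes aggregating local information";
it is the standard multi-scale text-CNN construction and trains stably at
desk scale.

## Networks, optimization, determinism

No deep-learning framework is used: the GRU seq2seq model, the attention
blocks, the convolutional bank, backpropagation and the Adam optimizer are
implemented in vectorized double-precision base R, with gradients verified
against central finite differences in the development tests. Desk-scale
defaults: latent 64, GRU hidden 128–160, 2 attention layers × 4 heads,
spectral embedding 64, Adam at 2–2.5 × 10⁻³ with cosine decay to 1/20 of the
peak rate, batch 32. Teacher forcing during decoder training; greedy
decoding at inference, capped at 110 tokens. Every stochastic step
(initialization, augmentation, batch order, simulated spectra, splits) is
driven by explicit seeds through a save/restore RNG discipline, so any run
is bit-reproducible; the pipeline writes per-stage manifests (MD5 of inputs,
config, seed) to make that checkable.

The spectrum-token embedding table (100003 × 64) is updated sparsely: only
rows touched by a batch receive Adam updates. The SMILES autoencoder
additionally sees each molecule's canonical→canonical identity pair every
epoch alongside the fresh randomized serialization; whether the identity
pair is included is genuinely open, and including it measurably stabilizes
exact-reconstruction at small library sizes.

## Retrieval, confidence, clustering

The retrieval index stores one embedding per unique canonical structure.
`retrieve_topk()` is an exhaustive scan returning the k smallest mean
squared errors with ties broken lexicographically by canonical SMILES —
exact, deterministic, and fast up to the library sizes this package targets
(the reference contract an approximate index would have to match).
Annotation thresholds are configuration, with the screening protocol's
values as defaults: annotate-as-PFAS at ≥ 90% confidence, a relaxed 80%
mode for cluster-level exploration.

Unannotated spectra are grouped by precursor mass: two spectra are related
iff `|pm1 − pm2| / max(pm1, pm2) × 1e6 ≤ 5` ppm, and clusters are connected
components of that relation. The transitive (single-linkage) closure is the
package's reading of the pairwise rule; a chain of 4-ppm steps therefore
merges spectra whose ends differ by more than 5 ppm — the caveat is
deliberate and tested. Precursor-to-library matching uses the asymmetric
variant (denominator = theoretical mass), also tested.

## Evaluation metrics

* **MA / FA** — percentage of unique compounds with at least one spectrum
  whose top-20 contains the correct molecule (InChIKey2D match) / formula
  (Hill string match).
* **MAS / FAS** — the same at the level of individual spectra.
* **Annotation accuracy** — per compound, correct spectra / total spectra.
* **Dataset confidence level** — percentage of spectra whose *entire*
  candidate list is PFAS (strict-all semantics).
* **MCS metrics** — the maximum common induced substructure under
  atom-type, bond-order, aromaticity and ring-membership matching, reported
  as ratio `a_MCS/a_r`, overlap `a_MCS/min(a_r, a_p)` and Tanimoto
  `a_MCS/(a_r + a_p − a_MCS)` over heavy atoms (hydrogens are implicit in
  the structures and excluded). The implementation is a maximum clique on
  the modular product graph; the common substructure may be disconnected,
  and induced-substructure semantics are used — both choices are pinned by
  an independent exhaustive-enumeration oracle in the test suite. Exact MCS
  is exponential in the worst case; long homologous perfluoro chains are
  exactly the pathological input, so MCS is an evaluation-time metric for
  small-to-medium structures, not an inference-time operation.
* **Fingerprint similarity** — mean/max/min Tanimoto between the reference
  and all candidates over a 2048-bit path fingerprint (simple paths up to 8
  atoms, direction-canonicalized labels, polynomial hashing).

## The synthetic benchmark: what it does and does not show

Licensed spectral libraries cannot ship with the package, so all training
and testing runs on synthetic fixtures with exact ground truth:

* **Library**: perfluoroalkyl carboxylic/sulfonic acids, fluorotelomer
  variants, perfluoroether acids, diacids and sulfonamides (chain lengths
  1–12) as the PFAS classes, plus random small organics (C/N/O/S trees with
  carbonyl, hydroxyl, amine, halogen decorations, valence-checked) as
  background. Labels are exact by construction and re-verified through the
  OECD predicate. The default benchmark is 500 molecules (100 PFAS / 400
  background), 3 spectra per compound, seed 42.
* **Spectra**: \[M−H\]⁻ precursor at M − 1.007276 Da; fragments from
  cleaving each acyclic single bond, charge retained on the heavier side;
  intensities proportional to heavy-atom count; Gaussian m/z jitter
  (default sd 0.003 Da, i.e. a few ppm at typical masses); collision energy
  uniform in \[10, 50\] eV. Mass conservation is exact before jitter, so
  neutral-loss features recover the complementary fragment — the structural
  signal the loss-feature augmentation is designed to exploit.

The simulator is deliberately simple and stated: deterministic
substructure-to-peak relations with controllable noise. Passing the
acceptance gates on this benchmark demonstrates that the machinery learns
and retrieves *when such a relation exists*; it does not demonstrate
performance on experimental spectra, where fragmentation depends on
collision energy, rearrangements, isotopes and matrix effects that the
simulator does not model.

Problem sizes used by the test suite and acceptance script were chosen so a
full run trains on an ordinary CPU: autoencoder quality gates use a
300-molecule library (150 epochs); the end-to-end retrieval gate trains the
spectral encoder on 4 simulated spectra for each of 250 molecules of a
500-molecule index (12 epochs) and evaluates on fresh spectra of the same
molecules; the bit-reproducibility gate runs a 32-molecule pipeline twice.

## Known limitations

* Exact MCS blows up on large symmetric molecules (see above).
* The OECD predicate is purely structural; it does not consult exposure or
  degradation knowledge, and classifies e.g. CF4 as PFAS by the letter of
  the rule.
* SMILES support covers the organic subset plus bracket atoms with charges
  and explicit hydrogens; exotic features (isotopic labels beyond parsing,
  multi-component species) are rejected upstream by design.
* Retrieval confidence calibrates against the library composition: a
  library with few PFAS deflates confidence scores, one with only PFAS
  inflates them. The score is a screening prior, not a probability.
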