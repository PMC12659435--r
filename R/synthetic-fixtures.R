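#' Synthetic molecule libraries and simulated MS2 spectra
#'
#' Desk-scale stand-ins for external molecule databases and licensed
#' spectral libraries: a generator of perfluoroalkyl acids plus random
#' small-molecule background structures, and a deterministic in-silico
#' fragmentation model producing \[M-H\]- MS2 spectra with known ground
#' truth. The fragmentation rules are deliberately simple and stated
#' (cleave acyclic single bonds, charge retained on the heavier side,
#' intensity proportional to heavy-atom count): the goal is a learnable,
#' exactly-checkable relation between structure and spectrum, not chemical
#' realism.
#'
#' @name synthetic-fixtures
NULL

#' Generate a synthetic molecule library with known PFAS labels
#'
#' PFAS members are perfluoroalkyl carboxylic acids (CnF2n+1-COOH) and
#' sulfonic acids (CnF2n+1-SO3H) with chain lengths n = 1..12, plus
#' fluorotelomer-like variants (n:2 fluorotelomer sulfonic acids and
#' alcohols). Background members are random small organics (trees over C,
#' N, O, S with carbonyl/hydroxyl/amine/chloro decorations) that never
#' satisfy the OECD PFAS rule. All records pass [prepare_molecule()],
#' canonical duplicates are never emitted, and output is deterministic per
#' seed.
#'
#' @param n_pfas number of PFAS molecules.
#' @param n_background number of background molecules.
#' @param seed integer seed.
#' @return list of `molecule_record`.
#' @export
generate_library <- function(n_pfas, n_background, seed = 42L) {
  stopifnot(n_pfas >= 0, n_background >= 0)
  with_preserved_seed({
    set.seed(as.integer(seed))
    pfas <- .gen_pfas(n_pfas)
    bg <- .gen_background(n_background, avoid = vapply(
      pfas, `[[`, character(1), "canonical_smiles"))
    c(pfas, bg)
  })
}

.pfas_smiles_pool <- function() {
  chain <- function(n) {
    # CnF2n+1- : (n-1) CF2 units and a terminal CF3
    paste0(strrep("C(F)(F)", n - 1L), "C(F)(F)F")
  }
  smis <- character(0)
  for (n in 1:12) smis <- c(smis, paste0("OC(=O)", chain(n)))        # PFCA
  for (n in 1:12) smis <- c(smis, paste0("OS(=O)(=O)", chain(n)))    # PFSA
  for (n in 2:10) smis <- c(smis, paste0("OS(=O)(=O)CC", chain(n)))  # n:2 FTSA
  for (n in 2:10) smis <- c(smis, paste0("OCC", chain(n)))           # n:2 FTOH
  for (n in 2:10) smis <- c(smis, paste0("NC(=O)", chain(n)))        # PFAmide
  for (n in 1:8)  smis <- c(smis, paste0("OC(=O)C(F)(F)O", chain(n))) # PFECA
  for (n in 1:10) smis <- c(smis, paste0("OC(=O)", strrep("C(F)(F)", n),
                                         "C(=O)O"))                  # PFdiCA
  for (n in 1:10) smis <- c(smis, paste0("NS(=O)(=O)", chain(n)))    # FASA
  for (n in 2:10) smis <- c(smis, paste0("OC(=O)CC", chain(n)))      # n:2 FTCA
  for (n in 2:8)  smis <- c(smis, paste0("OC(=O)CCC", chain(n)))     # n:3 FTCA
  for (n in 1:8)  smis <- c(smis, paste0("OS(=O)(=O)C(F)(F)O", chain(n)))
  smis
}

.gen_pfas <- function(n) {
  pool <- .pfas_smiles_pool()
  if (n > length(pool))
    stop(sprintf("at most %d distinct synthetic PFAS available", length(pool)),
         call. = FALSE)
  sel <- pool[sample.int(length(pool), n)]
  recs <- lapply(sel, prepare_molecule)
  stopifnot(!any(vapply(recs, is_rejection, logical(1))))
  stopifnot(all(vapply(recs, `[[`, logical(1), "is_pfas")))
  recs
}

# random acyclic small organics; resampled until non-PFAS, valid and unique
.gen_background <- function(n, avoid = character(0)) {
  seen <- c(avoid)
  out <- list()
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 50L * n + 200L)
      stop("background generator failed to converge", call. = FALSE)
    smi <- .random_organic_smiles()
    rec <- prepare_molecule(smi)
    if (is_rejection(rec) || rec$is_pfas) next
    if (rec$canonical_smiles %in% seen) next
    seen <- c(seen, rec$canonical_smiles)
    out[[length(out) + 1L]] <- rec
  }
  out
}

.random_organic_smiles <- function() {
  # random carbon tree with heteroatom decorations, respecting valence 4
  n_c <- sample(3:10, 1L)
  used <- rep(1L, n_c)   # bonds consumed per skeleton atom (root starts at 1)
  used[1] <- 0L
  parent <- integer(n_c)
  for (i in seq_len(n_c)[-1]) {
    free <- which(used[seq_len(i - 1L)] < 3L)  # keep one slot for decoration
    if (length(free) == 0L) { parent[i] <- NA_integer_; next }
    p <- if (length(free) == 1L) free else sample(free, 1L)
    parent[i] <- p
    used[p] <- used[p] + 1L
    used[i] <- used[i] + 1L
  }
  keep <- !is.na(parent) | seq_len(n_c) == 1L
  idx <- which(keep)
  deco <- character(n_c)
  for (i in idx) {
    cap <- 4L - used[i]
    r <- stats::runif(1)
    deco[i] <- if (cap >= 2L && r < 0.12) "(=O)" else if (cap >= 1L) {
      if (r < 0.24) "(O)" else if (r < 0.30) "(N)" else
        if (r < 0.34) "(Cl)" else if (r < 0.37) "(F)" else ""
    } else ""
  }
  kids <- split(idx[idx != 1L & !is.na(parent[idx])],
                parent[idx[idx != 1L & !is.na(parent[idx])]])
  build <- function(i) {
    ks <- kids[[as.character(i)]]
    body <- paste0(vapply(ks, function(k) paste0("(", build(k), ")"),
                          character(1)), collapse = "")
    paste0("C", deco[i], body)
  }
  build(1L)
}

#' Simulate an \[M-H\]- MS2 spectrum for a known molecule
#'
#' The precursor is the deprotonated molecule (m/z = M - 1.007276 Da).
#' Fragments arise from cleaving each acyclic single bond of the molecular
#' graph; the heavier side retains the charge with m/z = side mass -
#' 1.007276, so fragment and complementary neutral-loss masses sum exactly
#' to the parent mass. The `richness` most massive unique fragments are
#' kept; intensities are proportional to fragment heavy-atom count with the
#' base peak at 1; Gaussian m/z jitter with standard deviation `noise_sd`
#' emulates mass error. Collision energy is drawn uniformly in \[10, 50\]
#' eV and the record always passes [filter_spectrum()].
#'
#' @param record a `molecule_record` with monoisotopic mass < 1000 Da.
#' @param richness maximum number of fragment peaks.
#' @param noise_sd m/z jitter standard deviation (Da).
#' @param seed integer seed; identical seeds give identical spectra.
#' @return a `spectrum_record` with `compound_key = record$inchikey2d`.
#' @export
simulate_spectrum <- function(record, richness = 12L, noise_sd = 0.003,
                              seed = 1L) {
  stopifnot(inherits(record, "molecule_record"),
            record$monoisotopic_mass < 1000)
  mol <- record$graph
  frags <- fragment_masses(mol)
  with_preserved_seed({
    set.seed(as.integer(seed))
    precursor <- record$monoisotopic_mass - .PROTON_MASS
    if (nrow(frags) == 0L) {
      pk <- data.frame(mz = precursor, intensity = 1, is_loss = FALSE)
    } else {
      frags <- frags[order(frags$mass, decreasing = TRUE), , drop = FALSE]
      frags <- frags[!duplicated(round(frags$mass, 6)), , drop = FALSE]
      frags <- frags[seq_len(min(richness, nrow(frags))), , drop = FALSE]
      mz <- frags$mass - .PROTON_MASS
      inten <- frags$heavy / max(frags$heavy)
      if (noise_sd > 0) mz <- mz + stats::rnorm(length(mz), 0, noise_sd)
      keep <- mz > 0
      pk <- data.frame(mz = mz[keep], intensity = inten[keep],
                       is_loss = FALSE)
    }
    ce <- stats::runif(1, 10, 50)
    spectrum_record(precursor_mz = precursor, peaks = pk,
                    adduct = "[M-H]-", ion_mode = "negative",
                    collision_energy = ce,
                    compound_key = record$inchikey2d,
                    source_id = sprintf("%s/seed%d", record$inchikey2d,
                                        as.integer(seed)))
  })
}

#' Enumerate single-bond cleavage fragments of a molecular graph
#'
#' Every acyclic (non-ring) single non-aromatic bond is cleaved; for each
#' cleavage both sides are returned with their monoisotopic masses
#' (hydrogens as in the parent, so the two sides sum exactly to the parent
#' mass) and heavy-atom counts.
#'
#' @param mol a `mol_graph`.
#' @return data frame with columns `mass`, `heavy`, `heavier_side`.
#' @keywords internal
fragment_masses <- function(mol) {
  nb <- nrow(mol$bonds)
  cleavable <- which(!mol$ring_bond & mol$bonds$order == 1L & !mol$bonds$arom)
  if (length(cleavable) == 0L)
    return(data.frame(mass = numeric(0), heavy = integer(0),
                      heavier_side = logical(0)))
  atom_mass <- .MONO_MASS[mol$symbol] + mol$h * .MONO_MASS[["H"]]
  total <- sum(atom_mass)
  out <- vector("list", length(cleavable))
  for (ii in seq_along(cleavable)) {
    k <- cleavable[ii]
    # atoms reachable from a1 without crossing bond k
    side <- .component_without_bond(mol, k)
    m1 <- sum(atom_mass[side]); m2 <- total - m1
    h1 <- length(side); h2 <- mol$n - h1
    if (m1 >= m2) out[[ii]] <- data.frame(mass = m1, heavy = h1, heavier_side = TRUE)
    else out[[ii]] <- data.frame(mass = m2, heavy = h2, heavier_side = TRUE)
  }
  do.call(rbind, out)
}

.component_without_bond <- function(mol, k) {
  a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
  adj <- vector("list", mol$n)
  for (j in seq_len(nrow(mol$bonds))) {
    if (j == k) next
    adj[[mol$bonds$a1[j]]] <- c(adj[[mol$bonds$a1[j]]], mol$bonds$a2[j])
    adj[[mol$bonds$a2[j]]] <- c(adj[[mol$bonds$a2[j]]], mol$bonds$a1[j])
  }
  seen <- rep(FALSE, mol$n); seen[a] <- TRUE; stack <- a
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  which(seen)
}

#' Materialize a spectra benchmark on disk
#'
#' Writes `spectra_per_compound` simulated spectra for every molecule into
#' an MGF file plus a truth TSV (`spectrum_id`, `canonical_smiles`,
#' `inchikey2d`, `formula`), both round-trippable through [read_spectra()].
#'
#' @param library list of `molecule_record`.
#' @param spectra_per_compound spectra per molecule.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param noise_sd,richness forwarded to [simulate_spectrum()].
#' @return list with `mgf` and `truth` paths.
#' @export
make_fixtures <- function(library, spectra_per_compound = 3L, seed = 42L,
                          dir = tempfile("fixtures"), noise_sd = 0.003,
                          richness = 12L) {
  stopifnot(length(library) > 0L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(); truth <- list()
  for (i in seq_along(library)) {
    rec <- library[[i]]
    for (j in seq_len(spectra_per_compound)) {
      sid <- sprintf("%s_%02d", rec$inchikey2d, j)
      sp <- simulate_spectrum(rec, richness = richness, noise_sd = noise_sd,
                              seed = seed + 1000L * i + j)
      sp$source_id <- sid
      specs[[length(specs) + 1L]] <- sp
      truth[[length(truth) + 1L]] <- data.frame(
        spectrum_id = sid, canonical_smiles = rec$canonical_smiles,
        inchikey2d = rec$inchikey2d, formula = rec$formula)
    }
  }
  mgf <- file.path(dir, "spectra.mgf")
  tsv <- file.path(dir, "truth.tsv")
  write_spectra(specs, mgf, "mgf")
  utils::write.table(do.call(rbind, truth), tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  list(mgf = mgf, truth = tsv)
}
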