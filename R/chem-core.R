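#' Molecule ingestion and cleaning
#'
#' `prepare_molecule()` turns a raw SMILES string into a cleaned
#' `molecule_record`: stereochemistry is stripped, the structure is
#' canonicalized (Open Babel canonical SMILES), and the record is rejected
#' if it is unparseable, disconnected (contains a dot), contains an element
#' outside the supported set (C, N, H, O, P, S, Cl, Br, F, I, B), exceeds
#' 1000 Da monoisotopic mass, or tokenizes to more than 110 SMILES tokens.
#' The thresholds mirror the filters applied when assembling small-molecule
#' training libraries for spectrum-to-structure models.
#'
#' @param raw_smiles a single SMILES string.
#' @return on success, an object of class `molecule_record` with fields
#'   `source_smiles`, `canonical_smiles`, `inchikey2d`, `formula`,
#'   `monoisotopic_mass`, `is_pfas` and `smiles_tokens`; on failure an
#'   object of class `molecule_rejection` whose `reason` is one of
#'   `"unparseable"`, `"disconnected"`, `"disallowed-element"`,
#'   `"too-heavy"`, `"too-long"` or `"key-generation-failed"`.
#' @examples
#' \donttest{
#' rec <- prepare_molecule("C(/F)=C/F")   # stereo is stripped
#' rec$canonical_smiles
#' prepare_molecule("CCO.[Na+]")          # rejected: disconnected
#' }
#' @export
prepare_molecule <- function(raw_smiles) {
  if (!is.character(raw_smiles) || length(raw_smiles) != 1L ||
      is.na(raw_smiles) || !nzchar(trimws(raw_smiles)))
    stop("raw_smiles must be a non-empty string", call. = FALSE)
  s <- trimws(raw_smiles)
  if (grepl(".", s, fixed = TRUE))
    return(.reject(s, "disconnected"))
  s_nostereo <- gsub("[/\\\\@]", "", s)
  canonical <- .ob_canonical(s_nostereo)
  if (is.na(canonical) || !nzchar(canonical))
    return(.reject(s, "unparseable"))
  if (grepl(".", canonical, fixed = TRUE))
    return(.reject(s, "disconnected"))
  mol <- tryCatch(parse_smiles(canonical), error = function(e) NULL)
  if (is.null(mol))
    return(.reject(s, "unparseable"))
  if (!all(mol$symbol %in% .ALLOWED_ELEMENTS))
    return(.reject(s, "disallowed-element"))
  mass <- mol_mono_mass(mol)
  if (mass >= 1000)
    return(.reject(s, "too-heavy"))
  toks <- tokenize_smiles(canonical)
  if (length(toks) > 110L)
    return(.reject(s, "too-long"))
  key <- tryCatch(.ob_inchikey2d(canonical), error = function(e) NA_character_)
  if (is.na(key) || nchar(key) != 14L || grepl("[^A-Z]", key))
    return(.reject(s, "key-generation-failed"))
  structure(list(
    source_smiles = raw_smiles,
    canonical_smiles = canonical,
    inchikey2d = key,
    formula = mol_formula(mol),
    monoisotopic_mass = mass,
    is_pfas = classify_pfas_graph(mol),
    smiles_tokens = toks,
    graph = mol
  ), class = "molecule_record")
}

.reject <- function(smiles, reason) {
  structure(list(source_smiles = smiles, reason = reason),
            class = "molecule_rejection")
}

#' Test whether a molecule-preparation result is a rejection
#' @param x result of [prepare_molecule()].
#' @export
is_rejection <- function(x) inherits(x, "molecule_rejection")

.ob_canonical <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", smiles),
    error = function(e) NA_character_)
  if (is.na(out)) return(NA_character_)
  strsplit(trimws(out), "[ \t\n]")[[1]][1]
}

.ob_inchikey2d <- function(canonical_smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "INCHIKEY", canonical_smiles),
    error = function(e) NA_character_)
  if (is.na(out) || !nzchar(trimws(out))) return(NA_character_)
  substr(trimws(out), 1L, 14L)
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record> ", x$canonical_smiles, "\n", sep = "")
  cat("  formula: ", x$formula,
      sprintf("   monoisotopic mass: %.4f Da", x$monoisotopic_mass), "\n",
      sep = "")
  cat("  inchikey2d: ", x$inchikey2d,
      "   PFAS: ", if (x$is_pfas) "yes" else "no", "\n", sep = "")
  invisible(x)
}

#' @export
print.molecule_rejection <- function(x, ...) {
  cat("<molecule_rejection> reason: ", x$reason,
      "  (", x$source_smiles, ")\n", sep = "")
  invisible(x)
}

#' Split a SMILES string into tokens
#'
#' Each character is one token except the two-letter element symbols `Cl`
#' and `Br`. Concatenating the tokens reproduces the input exactly.
#'
#' @param smiles a SMILES string.
#' @return character vector of tokens.
#' @examples
#' tokenize_smiles("C(Cl)Br")  # "C" "(" "Cl" ")" "Br"
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  regmatches(smiles, gregexpr("Cl|Br|.", smiles))[[1]]
}

#' Generate a randomized SMILES serialization of a molecule
#'
#' Emits an alternative (non-canonical) valid SMILES for the same structure
#' by serializing the molecular graph from a random start atom with random
#' branch order. The result canonicalizes back to
#' `record$canonical_smiles`. Used for input augmentation when training the
#' SMILES autoencoder: each epoch sees a fresh serialization while the
#' decoding target stays canonical.
#'
#' @param record a `molecule_record`.
#' @param seed integer seed; the same seed always yields the same string.
#' @return a SMILES string.
#' @export
randomize_smiles <- function(record, seed) {
  stopifnot(inherits(record, "molecule_record"))
  mol <- record$graph
  with_preserved_seed({
    set.seed(as.integer(seed) %% .Machine$integer.max)
    start <- sample.int(mol$n, 1L)
    write_smiles(mol, start = start, shuffle = TRUE)
  })
}

# evaluate expr with the global RNG state saved and restored
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' First 14 characters of the standard InChIKey (connectivity hash)
#'
#' The leading 14-character block of the InChIKey hashes atomic
#' connectivity while ignoring stereochemistry, so stereoisomers of one
#' skeleton share the same key. Used as the compound identity for
#' dataset partitioning and for molecule-accuracy scoring.
#'
#' @param x a `molecule_record` or a SMILES string.
#' @return 14-character uppercase string.
#' @export
inchikey2d <- function(x) {
  if (inherits(x, "molecule_record")) return(x$inchikey2d)
  stopifnot(is.character(x), length(x) == 1L)
  key <- .ob_inchikey2d(x)
  if (is.na(key) || nchar(key) != 14L || grepl("[^A-Z]", key))
    stop("key-generation-failed", call. = FALSE)
  key
}

#' Molecular formula and monoisotopic mass
#'
#' Formula in Hill notation (C first, then H, then remaining elements
#' alphabetically; fully alphabetical when no carbon), counting implicit
#' hydrogens. Mass is the monoisotopic mass from standard atomic masses.
#'
#' @param record a `molecule_record`.
#' @return list with `formula` and `monoisotopic_mass` (Da).
#' @export
formula_and_mass <- function(record) {
  stopifnot(inherits(record, "molecule_record"))
  list(formula = record$formula, monoisotopic_mass = record$monoisotopic_mass)
}

#' Classify a molecule as PFAS under the revised OECD structural rule
#'
#' A molecule is PFAS if it contains at least one perfluorinated methyl
#' (-CF3) or methylene (-CF2-) group, i.e. some carbon with at least two
#' fluorine neighbours and no hydrogen, chlorine, bromine or iodine
#' attached to that carbon (implicit hydrogens count as attached).
#' The single neighbour-count predicate covers both the CF3 and CF2 cases.
#'
#' @param record a `molecule_record`.
#' @return logical.
#' @examples
#' \donttest{
#' classify_pfas(prepare_molecule("OS(=O)(=O)C(F)(F)C(F)(F)F"))  # TRUE
#' classify_pfas(prepare_molecule("C(F)(F)F"))  # FALSE: CHF3 carbon has an H
#' }
#' @export
classify_pfas <- function(record) {
  stopifnot(inherits(record, "molecule_record"))
  classify_pfas_graph(record$graph)
}

#' @keywords internal
classify_pfas_graph <- function(mol) {
  if (mol$n == 0L) return(FALSE)
  for (i in which(mol$symbol == "C")) {
    nbr <- c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
    nbr_sym <- mol$symbol[nbr]
    n_f <- sum(nbr_sym == "F")
    if (n_f < 2L) next
    n_bad <- mol$h[i] + sum(nbr_sym %in% c("H", "Cl", "Br", "I"))
    if (n_bad == 0L) return(TRUE)
  }
  FALSE
}

#' Read a molecule library from a SMILES text file
#'
#' One SMILES per line, optionally followed by a tab-separated identifier.
#' Each entry is cleaned with [prepare_molecule()]; rejected entries are
#' collected (with their violated rule) rather than silently dropped.
#'
#' @param path file path.
#' @return list with `records` (list of `molecule_record`) and `rejections`
#'   (list of `molecule_rejection`).
#' @export
read_molecule_library <- function(path) {
  if (!file.exists(path)) stop("io: file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  records <- list(); rejections <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    res <- prepare_molecule(parts[1])
    if (is_rejection(res)) rejections[[length(rejections) + 1L]] <- res
    else {
      if (length(parts) > 1L) res$id <- parts[2]
      records[[length(records) + 1L]] <- res
    }
  }
  list(records = records, rejections = rejections)
}

#' Write a cleaned molecule library
#'
#' Writes one canonical SMILES per line (with optional identifier) plus a
#' TSV sidecar (`<path>.tsv`) with canonical_smiles, inchikey2d, formula,
#' mass and is_pfas columns.
#'
#' @param records list of `molecule_record`.
#' @param path output path for the SMILES file.
#' @param sidecar write the TSV sidecar too?
#' @return `path`, invisibly.
#' @export
write_molecule_library <- function(records, path, sidecar = TRUE) {
  stopifnot(length(records) > 0L)
  lines <- vapply(records, function(r) {
    if (!is.null(r$id)) paste(r$canonical_smiles, r$id, sep = "\t")
    else r$canonical_smiles
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  if (isTRUE(sidecar)) {
    df <- data.frame(
      canonical_smiles = vapply(records, `[[`, character(1), "canonical_smiles"),
      inchikey2d = vapply(records, `[[`, character(1), "inchikey2d"),
      formula = vapply(records, `[[`, character(1), "formula"),
      mass = vapply(records, `[[`, numeric(1), "monoisotopic_mass"),
      is_pfas = vapply(records, `[[`, logical(1), "is_pfas"))
    utils::write.table(df, paste0(path, ".tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
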