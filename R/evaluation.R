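#' Structural and retrieval evaluation metrics
#'
#' The metric suite for judging retrieved candidates against reference
#' structures: maximum-common-substructure (MCS) similarity, path-based
#' fingerprint Tanimoto statistics, molecule/formula retrieval accuracy
#' at the compound and spectrum level, and the dataset-level PFAS
#' confidence.
#'
#' @name evaluation
NULL

#' Maximum-common-substructure similarity metrics
#'
#' Computes the maximum common induced substructure of two molecules under
#' atom matching (element, aromaticity, ring membership) and bond matching
#' (order, aromaticity, ring-bond status), then reports three heavy-atom
#' ratios: `ratio = a_MCS / a_r`, `overlap = a_MCS / min(a_r, a_p)` and
#' `tanimoto = a_MCS / (a_r + a_p - a_MCS)`, where `a_r` and `a_p` are the
#' heavy-atom counts of the reference and predicted molecules. The MCS is
#' found as a maximum clique of the modular product graph; the common
#' substructure is not required to be connected.
#'
#' @param reference `molecule_record` of the correct molecule.
#' @param predicted `molecule_record` of the candidate.
#' @return list with `ratio`, `tanimoto`, `overlap` and `a_mcs`.
#' @export
mcs_metrics <- function(reference, predicted) {
  stopifnot(inherits(reference, "molecule_record"),
            inherits(predicted, "molecule_record"))
  g1 <- reference$graph; g2 <- predicted$graph
  if (g1$n == 0L || g2$n == 0L) stop("degenerate: empty molecule", call. = FALSE)
  a_mcs <- mcs_size(g1, g2)
  ar <- g1$n; ap <- g2$n
  list(ratio = a_mcs / ar,
       tanimoto = a_mcs / (ar + ap - a_mcs),
       overlap = a_mcs / min(ar, ap),
       a_mcs = a_mcs)
}

# atom compatibility labels and bond labels used by both the clique search
# and the exhaustive oracle
.atom_label <- function(mol) {
  paste(mol$symbol, mol$aromatic, mol$ring_atom, sep = "|")
}
.bond_matrix <- function(mol) {
  # 0 = no bond; otherwise an integer code of (order, arom, ring)
  Bm <- matrix(0L, mol$n, mol$n)
  if (nrow(mol$bonds) > 0L) {
    code <- mol$bonds$order + 10L * mol$bonds$arom + 100L * mol$ring_bond
    Bm[cbind(mol$bonds$a1, mol$bonds$a2)] <- code
    Bm[cbind(mol$bonds$a2, mol$bonds$a1)] <- code
  }
  Bm
}

#' Size (heavy atoms) of the maximum common induced substructure
#' @keywords internal
mcs_size <- function(g1, g2) {
  l1 <- .atom_label(g1); l2 <- .atom_label(g2)
  B1 <- .bond_matrix(g1); B2 <- .bond_matrix(g2)
  pairs <- which(outer(l1, l2, "=="), arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(0L)
  # modular product: edges where the bond pattern (including absence)
  # agrees between the two molecules
  i1 <- pairs[, 1]; i2 <- pairs[, 2]
  adj <- (B1[i1, i1, drop = FALSE] == B2[i2, i2, drop = FALSE]) &
    outer(i1, i1, "!=") & outer(i2, i2, "!=")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::clique_num(g))
}

#' Path-based 2048-bit molecular fingerprint
#'
#' Enumerates all simple linear paths of 1..8 atoms, labels each path by
#' its atom symbols and bond orders (direction-canonicalized), and hashes
#' the labels onto 2048 bits.
#'
#' @param record a `molecule_record` (or `mol_graph`).
#' @param nbits fingerprint width.
#' @param max_len maximum path length in atoms.
#' @return logical vector of length `nbits`.
#' @export
path_fingerprint <- function(record, nbits = 2048L, max_len = 8L) {
  mol <- if (inherits(record, "molecule_record")) record$graph else record
  Bm <- .bond_matrix(mol)
  labels <- character(0)
  atom_tok <- ifelse(mol$aromatic, tolower(mol$symbol), mol$symbol)
  paths <- new.env(parent = emptyenv())
  extend <- function(path) {
    last <- path[length(path)]
    lab_fwd <- .path_label(path, atom_tok, Bm)
    lab_rev <- .path_label(rev(path), atom_tok, Bm)
    labels <<- c(labels, if (lab_fwd <= lab_rev) lab_fwd else lab_rev)
    if (length(path) >= max_len) return()
    nbrs <- which(Bm[last, ] != 0L)
    for (nb in nbrs) if (!(nb %in% path)) extend(c(path, nb))
  }
  for (i in seq_len(mol$n)) extend(i)
  bits <- rep(FALSE, nbits)
  bits[unique(vapply(labels, .string_hash, integer(1), mod = nbits)) + 1L] <- TRUE
  bits
}

.path_label <- function(path, atom_tok, Bm) {
  n <- length(path)
  if (n == 1L) return(atom_tok[path])
  parts <- character(2L * n - 1L)
  parts[seq(1L, 2L * n - 1L, by = 2L)] <- atom_tok[path]
  parts[seq(2L, 2L * n - 2L, by = 2L)] <-
    as.character(Bm[cbind(path[-n], path[-1L])])
  paste(parts, collapse = "")
}

# deterministic polynomial string hash
.string_hash <- function(s, mod) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  as.integer(h %% mod)
}

#' Tanimoto similarity between two fingerprints
#' @param a,b logical fingerprint vectors.
#' @return similarity in \[0, 1\] (1 when both are empty).
#' @export
tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Fingerprint similarity statistics against a candidate list
#'
#' Average, maximum and minimum Tanimoto similarity between the reference
#' molecule and every candidate, using the 2048-bit path fingerprint.
#'
#' @param reference `molecule_record`.
#' @param candidates non-empty list of `molecule_record`.
#' @return list with `avg`, `max`, `min`.
#' @export
fingerprint_similarity_stats <- function(reference, candidates) {
  if (length(candidates) == 0L)
    stop("empty-input: no candidates", call. = FALSE)
  fr <- path_fingerprint(reference)
  sims <- vapply(candidates, function(c) tanimoto(fr, path_fingerprint(c)),
                 numeric(1))
  list(avg = mean(sims), max = max(sims), min = min(sims))
}

#' Retrieval accuracy report
#'
#' Scores annotation results against ground truth. A molecule match means
#' a candidate shares the truth's InChIKey2D; a formula match means equal
#' Hill formula strings. Reports: MA and FA (percentage of unique
#' compounds with at least one spectrum whose top-k contains the correct
#' molecule / formula), MAS and FAS (percentage of individual spectra),
#' and per-compound annotation accuracy (correct spectra / total spectra).
#'
#' @param results list of `annotation_result` (or named list mapping
#'   spectrum id to result).
#' @param truth named list or data frame mapping spectrum id to the true
#'   `molecule_record` (or a data frame with `spectrum_id`, `inchikey2d`,
#'   `formula` columns).
#' @return list of class `retrieval_report`: `ma`, `fa`, `mas`, `fas`
#'   (percentages), `n_compounds`, `n_spectra`, and `per_compound` (data
#'   frame with `inchikey2d`, `n_spectra`, `n_correct`,
#'   `annotation_accuracy`, `mean_confidence`).
#' @export
evaluate_retrieval <- function(results, truth) {
  if (is.data.frame(truth)) {
    stopifnot(all(c("spectrum_id", "inchikey2d", "formula") %in% names(truth)))
    tkey <- truth$inchikey2d; tform <- truth$formula
    names(tkey) <- truth$spectrum_id; names(tform) <- truth$spectrum_id
  } else {
    tkey <- vapply(truth, `[[`, character(1), "inchikey2d")
    tform <- vapply(truth, `[[`, character(1), "formula")
  }
  ids <- vapply(results, `[[`, character(1), "spectrum_id")
  if (!all(ids %in% names(tkey)))
    stop("missing-truth: spectra without a truth entry: ",
         paste(utils::head(setdiff(ids, names(tkey))), collapse = ", "),
         call. = FALSE)
  mol_ok <- logical(length(results))
  form_ok <- logical(length(results))
  conf <- numeric(length(results))
  for (i in seq_along(results)) {
    h <- results[[i]]$hits
    mol_ok[i] <- tkey[[ids[i]]] %in% h$inchikey2d
    form_ok[i] <- tform[[ids[i]]] %in% h$formula
    conf[i] <- results[[i]]$confidence_score
  }
  key_of <- unname(tkey[ids])
  per <- do.call(rbind, lapply(split(seq_along(results), key_of), function(ix) {
    data.frame(inchikey2d = key_of[ix[1]],
               n_spectra = length(ix),
               n_correct = sum(mol_ok[ix]),
               annotation_accuracy = 100 * mean(mol_ok[ix]),
               mean_confidence = mean(conf[ix]))
  }))
  rownames(per) <- NULL
  structure(list(
    ma = 100 * mean(vapply(split(mol_ok, key_of), any, logical(1))),
    fa = 100 * mean(vapply(split(form_ok, key_of), any, logical(1))),
    mas = 100 * mean(mol_ok),
    fas = 100 * mean(form_ok),
    n_compounds = length(unique(key_of)),
    n_spectra = length(results),
    per_compound = per), class = "retrieval_report")
}

#' @export
print.retrieval_report <- function(x, ...) {
  cat(sprintf(paste0("<retrieval_report> %d compounds / %d spectra\n",
                     "  MA %.1f%%  FA %.1f%%  MAS %.1f%%  FAS %.1f%%\n"),
              x$n_compounds, x$n_spectra, x$ma, x$fa, x$mas, x$fas))
  invisible(x)
}

#' Dataset-level PFAS confidence
#'
#' Percentage of spectra whose candidate list is entirely PFAS (strict-all
#' semantics: a 95% per-spectrum confidence does not count).
#'
#' @param results list of `annotation_result`.
#' @return percentage in \[0, 100\].
#' @export
dataset_confidence_level <- function(results) {
  if (length(results) == 0L) stop("empty-input", call. = FALSE)
  all_pfas <- vapply(results, function(r) all(r$hits$is_pfas), logical(1))
  100 * mean(all_pfas)
}

#' Write a retrieval report as JSON and per-compound TSV
#'
#' @param report a `retrieval_report`.
#' @param json_path,tsv_path output paths (NULL to skip either).
#' @return invisible list of written paths.
#' @export
write_retrieval_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(report[c("ma", "fa", "mas", "fas", "n_compounds",
                                  "n_spectra")],
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path))
    utils::write.table(report$per_compound, tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(list(json = json_path, tsv = tsv_path))
}
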