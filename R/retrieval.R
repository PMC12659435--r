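#' Candidate retrieval and PFAS confidence scoring
#'
#' Spectra are annotated by embedding them with the spectral encoder and
#' retrieving the nearest molecular structures in the chemical latent
#' space; distance is the mean squared error between embeddings. The
#' per-spectrum confidence score is the percentage of retrieved candidates
#' that satisfy the OECD PFAS structural rule.
#'
#' @name retrieval
NULL

#' Build an embedding index over a molecule library
#'
#' One embedding per unique canonical structure (duplicates indexed once).
#'
#' @param library list of `molecule_record`.
#' @param ae a trained `smiles_ae`.
#' @return an object of class `embedding_index`: `embeddings` (matrix, one
#'   row per molecule) and `records`.
#' @export
build_index <- function(library, ae) {
  if (length(library) == 0L) stop("empty-input: empty library", call. = FALSE)
  canon <- vapply(library, `[[`, character(1), "canonical_smiles")
  keep <- !duplicated(canon)
  records <- library[keep]
  emb <- t(vapply(records, function(r) encode_molecule(r, ae),
                  numeric(ae$config$latent_dim)))
  structure(list(embeddings = emb, records = records,
                 latent_dim = ae$config$latent_dim),
            class = "embedding_index")
}

#' @export
print.embedding_index <- function(x, ...) {
  cat("<embedding_index>", nrow(x$embeddings), "structures; latent dim",
      x$latent_dim, ";", sum(vapply(x$records, `[[`, logical(1), "is_pfas")),
      "PFAS\n")
  invisible(x)
}

#' Retrieve the k nearest structures for a query embedding
#'
#' Exhaustive scan returning the `k` candidates with the smallest mean
#' squared error to the query, ascending; ties are broken by canonical
#' SMILES lexicographic order. Fewer than `k` index entries return all.
#'
#' @param query numeric latent vector (E_s or E_a).
#' @param index an `embedding_index`.
#' @param k number of candidates (default 20).
#' @return data frame of class `candidate_hits` with columns `rank`,
#'   `canonical_smiles`, `inchikey2d`, `formula`, `mw`, `distance`,
#'   `is_pfas`.
#' @export
retrieve_topk <- function(query, index, k = 20L) {
  stopifnot(inherits(index, "embedding_index"))
  if (k < 1L) stop("domain: k must be >= 1", call. = FALSE)
  if (length(query) != index$latent_dim)
    stop("shape: query length != index latent dim", call. = FALSE)
  d2 <- index$embeddings - matrix(query, nrow(index$embeddings),
                                  index$latent_dim, byrow = TRUE)
  mse <- rowMeans(d2 * d2)
  canon <- vapply(index$records, `[[`, character(1), "canonical_smiles")
  ord <- order(mse, canon, method = "radix")
  sel <- ord[seq_len(min(k, length(ord)))]
  out <- data.frame(
    rank = seq_along(sel),
    canonical_smiles = canon[sel],
    inchikey2d = vapply(index$records[sel], `[[`, character(1), "inchikey2d"),
    formula = vapply(index$records[sel], `[[`, character(1), "formula"),
    mw = vapply(index$records[sel], `[[`, numeric(1), "monoisotopic_mass"),
    distance = mse[sel],
    is_pfas = vapply(index$records[sel], `[[`, logical(1), "is_pfas"))
  class(out) <- c("candidate_hits", "data.frame")
  out
}

#' PFAS annotation confidence of a candidate list
#'
#' Percentage of retrieved candidates classified as PFAS.
#'
#' @param hits a `candidate_hits` data frame (or any data frame with an
#'   `is_pfas` column).
#' @return percentage in \[0, 100\].
#' @export
confidence_score <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L)
    stop("empty-input: no candidate hits", call. = FALSE)
  100 * sum(hits$is_pfas) / nrow(hits)
}

#' Annotate spectra against an embedding index
#'
#' Full inference: preprocess each accepted spectrum (normalize, add loss
#' features, tokenize), embed it, retrieve the top-k candidates and compute
#' the PFAS confidence score.
#'
#' @param spectra list of `spectrum_record`.
#' @param encoder a trained `spectral_encoder`.
#' @param index an `embedding_index`.
#' @param k candidates per spectrum.
#' @param max_peaks,max_len forwarded to [tokenize_spectrum()].
#' @param apply_filter drop spectra failing [filter_spectrum()]?
#' @return list of `annotation_result`: each has `spectrum_id`, `hits`,
#'   `confidence_score`.
#' @export
annotate_spectra <- function(spectra, encoder, index, k = 20L,
                             max_peaks = 100L, max_len = 256L,
                             apply_filter = TRUE) {
  stopifnot(inherits(encoder, "spectral_encoder"),
            inherits(index, "embedding_index"))
  if (apply_filter)
    spectra <- Filter(function(s) filter_spectrum(s)$accept, spectra)
  if (length(spectra) == 0L)
    stop("empty-input: no spectra to annotate", call. = FALSE)
  ts <- lapply(spectra, function(s) {
    s$peaks <- normalize_intensities(s$peaks[!s$peaks$is_loss, , drop = FALSE])
    tokenize_spectrum(add_loss_features(s), max_peaks, max_len)
  })
  emb <- encode_spectrum(ts, encoder)
  lapply(seq_along(spectra), function(i) {
    hits <- retrieve_topk(emb[i, ], index, k)
    structure(list(spectrum_id = spectra[[i]]$source_id,
                   compound_key = spectra[[i]]$compound_key,
                   hits = hits,
                   confidence_score = confidence_score(hits)),
              class = "annotation_result")
  })
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation_result>", x$spectrum_id,
      sprintf(" confidence %.0f%%\n", x$confidence_score))
  print(utils::head(x$hits, 5))
  invisible(x)
}

#' Write annotation results as a TSV table
#'
#' One row per (spectrum, candidate) with rank, structure, formula, mass,
#' embedding distance, PFAS flag, per-spectrum confidence and the mass
#' difference to the top candidate.
#'
#' @param results list of `annotation_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(results, path) {
  rows <- lapply(results, function(r) {
    h <- r$hits
    data.frame(spectrum_id = r$spectrum_id, rank = h$rank,
               canonical_smiles = h$canonical_smiles, formula = h$formula,
               mw = h$mw, distance = h$distance, is_pfas = h$is_pfas,
               confidence_score = r$confidence_score,
               mw_diff = h$mw - h$mw[1])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cluster spectra by precursor mass at ppm tolerance
#'
#' Two spectra are related when
#' `abs(pm1 - pm2) / max(pm1, pm2) * 1e6 <= tol_ppm` (inclusive); clusters
#' are the connected components of this relation, so chains of pairwise
#' matches merge transitively (single-linkage behaviour).
#'
#' @param spectra list of `spectrum_record` (or a numeric vector of
#'   precursor m/z values).
#' @param tol_ppm tolerance in ppm.
#' @return integer vector of cluster ids, one per spectrum (empty input
#'   gives an empty vector).
#' @export
cluster_by_precursor <- function(spectra, tol_ppm = 5) {
  pm <- if (is.numeric(spectra)) spectra
        else vapply(spectra, `[[`, numeric(1), "precursor_mz")
  n <- length(pm)
  if (n == 0L) return(integer(0))
  ord <- order(pm)
  cid <- integer(n)
  cur <- 1L
  cid[ord[1]] <- 1L
  # sorted sweep: the pairwise relation only links mass-adjacent spectra,
  # so connected components are runs of consecutive linked precursors
  for (i in seq_len(n - 1L)) {
    a <- pm[ord[i]]; b <- pm[ord[i + 1L]]
    linked <- abs(a - b) / max(a, b) * 1e6 <= tol_ppm
    if (!linked) cur <- cur + 1L
    cid[ord[i + 1L]] <- cur
  }
  cid
}
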