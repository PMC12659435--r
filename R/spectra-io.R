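#' Spectrum records and peak lists
#'
#' A `spectrum_record` holds one MS2 acquisition: precursor m/z, adduct,
#' ionization mode, collision energy, a peak data frame (`mz`, `intensity`,
#' `is_loss`), an optional `compound_key` (InChIKey2D of the known parent)
#' and a `source_id`. Peaks are kept sorted ascending by m/z within each
#' segment (fragments, then neutral-loss features).
#'
#' @param precursor_mz precursor m/z (Da).
#' @param peaks data frame with columns `mz` and `intensity` (an `is_loss`
#'   column is added if absent).
#' @param adduct adduct string, e.g. `"[M-H]-"`.
#' @param ion_mode `"negative"` or `"positive"`.
#' @param collision_energy collision energy in eV (may be `NA`).
#' @param compound_key optional 14-character InChIKey2D of the true parent.
#' @param source_id spectrum identifier.
#' @return an object of class `spectrum_record`.
#' @export
spectrum_record <- function(precursor_mz, peaks, adduct = "[M-H]-",
                            ion_mode = "negative", collision_energy = NA_real_,
                            compound_key = NA_character_, source_id = "") {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L)
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  if (is.null(peaks$is_loss)) peaks$is_loss <- FALSE
  stopifnot(all(peaks$mz > 0), all(peaks$intensity >= 0))
  ord <- order(peaks$is_loss, peaks$mz)
  peaks <- peaks[ord, c("mz", "intensity", "is_loss"), drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(precursor_mz = as.numeric(precursor_mz),
                 adduct = adduct, ion_mode = ion_mode,
                 collision_energy = as.numeric(collision_energy),
                 peaks = peaks, compound_key = compound_key,
                 source_id = source_id),
            class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record> %s  precursor %.4f  %s %s  CE %s  %d peaks\n",
              x$source_id, x$precursor_mz, x$ion_mode, x$adduct,
              if (is.na(x$collision_energy)) "?" else
                format(x$collision_energy),
              nrow(x$peaks)))
  invisible(x)
}

#' Read MS2 spectra from an MGF or MSP file
#'
#' MGF entries follow the `BEGIN IONS`/`END IONS` convention with
#' `PEPMASS`, optional `CHARGE`, `ADDUCT`/`ION`, `IONMODE`,
#' `COLLISION_ENERGY`, `TITLE`, `COMPOUND_KEY`; MSP entries follow the NIST
#' convention (`Name:`, `PrecursorMZ:`, `Num Peaks:` ...). Entries missing
#' a precursor m/z or containing no peaks are skipped with a warning and
#' counted in the `skipped` attribute.
#'
#' @param path file path.
#' @param format `"mgf"` or `"msp"`; default guessed from the extension.
#' @return list of `spectrum_record` with attribute `skipped` (number of
#'   unparseable entries).
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "msp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("io: file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "msp") "msp" else "mgf"
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- if (format == "mgf") .parse_mgf(lines) else .parse_msp(lines)
  if (length(out$records) == 0L)
    stop("empty-input: no parseable spectra in ", path, call. = FALSE)
  if (out$skipped > 0L)
    warning(sprintf("skipped %d unparseable spectra in %s", out$skipped, path),
            call. = FALSE)
  structure(out$records, skipped = out$skipped)
}

.parse_peak_lines <- function(pl) {
  if (length(pl) == 0L) return(NULL)
  mat <- do.call(rbind, lapply(strsplit(trimws(pl), "[ \t]+"), function(x) {
    suppressWarnings(as.numeric(x[1:2]))
  }))
  if (any(is.na(mat))) return(NULL)
  data.frame(mz = mat[, 1], intensity = mat[, 2], is_loss = FALSE)
}

.parse_mgf <- function(lines) {
  records <- list(); skipped <- 0L; i <- 1L; n <- length(lines)
  idx <- 0L
  while (i <= n) {
    if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
    j <- i + 1L
    hdr <- character(0); pk <- character(0)
    while (j <= n && trimws(lines[j]) != "END IONS") {
      ln <- trimws(lines[j])
      if (nzchar(ln)) {
        if (grepl("=", ln, fixed = TRUE)) hdr <- c(hdr, ln) else pk <- c(pk, ln)
      }
      j <- j + 1L
    }
    i <- j + 1L
    idx <- idx + 1L
    kv <- strsplit(hdr, "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    getv <- function(k) { m <- match(k, keys); if (is.na(m)) NA else vals[m] }
    pep <- suppressWarnings(as.numeric(strsplit(
      if (is.na(getv("PEPMASS"))) "" else getv("PEPMASS"), "[ \t]+")[[1]][1]))
    peaks <- .parse_peak_lines(pk)
    if (length(pep) == 0L || is.na(pep) || is.null(peaks) || nrow(peaks) == 0L) {
      skipped <- skipped + 1L; next
    }
    ce <- suppressWarnings(as.numeric(getv("COLLISION_ENERGY")))
    ionmode <- getv("IONMODE")
    charge <- getv("CHARGE")
    if (is.na(ionmode) && !is.na(charge))
      ionmode <- if (grepl("-", charge, fixed = TRUE)) "negative" else "positive"
    adduct <- getv("ADDUCT"); if (is.na(adduct)) adduct <- getv("ION")
    title <- getv("TITLE")
    records[[length(records) + 1L]] <- spectrum_record(
      precursor_mz = pep, peaks = peaks,
      adduct = if (is.na(adduct)) "" else adduct,
      ion_mode = if (is.na(ionmode)) "" else tolower(ionmode),
      collision_energy = if (length(ce) == 0L) NA_real_ else ce,
      compound_key = getv("COMPOUND_KEY"),
      source_id = if (is.na(title)) sprintf("spectrum_%d", idx) else title)
  }
  list(records = records, skipped = skipped)
}

.parse_msp <- function(lines) {
  # entries are blank-line-separated blocks of "Key: value" headers + peaks
  records <- list(); skipped <- 0L
  lines <- c(lines, "")
  flush_block <- function(block) {
    block <- block[nzchar(trimws(block))]
    if (length(block) == 0L) return(NULL)
    is_hdr <- grepl("^[A-Za-z][A-Za-z0-9_ ]*:", block)
    hdr <- block[is_hdr]; pk <- block[!is_hdr]
    keys <- toupper(trimws(sub(":.*$", "", hdr)))
    vals <- trimws(sub("^[^:]*:", "", hdr))
    getv <- function(k) { m <- match(k, keys); if (is.na(m)) NA else vals[m] }
    pep <- suppressWarnings(as.numeric(getv("PRECURSORMZ")))
    peaks <- .parse_peak_lines(pk)
    if (is.na(pep) || is.null(peaks) || nrow(peaks) == 0L) return("skip")
    ce <- suppressWarnings(as.numeric(gsub("[^0-9.]", "",
      if (is.na(getv("COLLISION_ENERGY"))) "" else getv("COLLISION_ENERGY"))))
    nm <- getv("NAME")
    spectrum_record(
      precursor_mz = pep, peaks = peaks,
      adduct = if (is.na(getv("PRECURSOR_TYPE"))) "" else getv("PRECURSOR_TYPE"),
      ion_mode = switch(toupper(if (is.na(getv("ION_MODE"))) "" else getv("ION_MODE")),
                        "N" = "negative", "NEGATIVE" = "negative",
                        "P" = "positive", "POSITIVE" = "positive", ""),
      collision_energy = if (length(ce) == 0L || is.na(ce)) NA_real_ else ce,
      compound_key = getv("COMPOUND_KEY"),
      source_id = if (is.na(nm)) "" else nm)
  }
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    j <- i
    while (j <= n && nzchar(trimws(lines[j]))) j <- j + 1L
    res <- flush_block(lines[i:(j - 1L)])
    if (identical(res, "skip")) skipped <- skipped + 1L
    else if (!is.null(res)) records[[length(records) + 1L]] <- res
    i <- j
  }
  list(records = records, skipped = skipped)
}

#' Write spectra to MGF or MSP
#'
#' Peak lines are written as `mz intensity` with 4 decimal places on m/z,
#' UTF-8 encoded; metadata round-trips through [read_spectra()].
#'
#' @param records list of `spectrum_record`.
#' @param path output path.
#' @param format `"mgf"` or `"msp"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(records, path, format = c("mgf", "msp")) {
  format <- match.arg(format)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    frag <- rec$peaks[!rec$peaks$is_loss, , drop = FALSE]
    pl <- sprintf("%.4f %.6g", frag$mz, frag$intensity)
    if (format == "mgf") {
      writeLines(c("BEGIN IONS",
                   sprintf("TITLE=%s", rec$source_id),
                   sprintf("PEPMASS=%.6f", rec$precursor_mz),
                   "CHARGE=1-",
                   sprintf("IONMODE=%s", rec$ion_mode),
                   sprintf("ADDUCT=%s", rec$adduct),
                   if (!is.na(rec$collision_energy))
                     sprintf("COLLISION_ENERGY=%g", rec$collision_energy),
                   if (!is.na(rec$compound_key))
                     sprintf("COMPOUND_KEY=%s", rec$compound_key),
                   pl, "END IONS", ""), con)
    } else {
      writeLines(c(sprintf("Name: %s", rec$source_id),
                   sprintf("PrecursorMZ: %.6f", rec$precursor_mz),
                   sprintf("Precursor_type: %s", rec$adduct),
                   sprintf("Ion_mode: %s",
                           if (rec$ion_mode == "negative") "N" else "P"),
                   if (!is.na(rec$collision_energy))
                     sprintf("Collision_energy: %g", rec$collision_energy),
                   if (!is.na(rec$compound_key))
                     sprintf("Compound_key: %s", rec$compound_key),
                   sprintf("Num Peaks: %d", nrow(frag)),
                   pl, ""), con)
    }
  }
  invisible(path)
}

#' Validity filter for training/inference spectra
#'
#' A spectrum is accepted iff (1) precursor m/z < 1000, (2) negative
#' ionization with an \[M-H\]- adduct, and (3) collision energy between 10
#' and 50 eV inclusive. The first violated criterion names the rejection.
#' Adduct strings are normalized case/whitespace-insensitively;
#' `"[M-H]-"`, `"[M-H]1-"` and `"M-H"` all count as \[M-H\]-. Missing or
#' ramped collision energies are rejected as `missing-metadata`.
#'
#' @param rec a `spectrum_record`.
#' @return list with `accept` (logical) and `reason` (`NA` when accepted;
#'   otherwise `"precursor-range"`, `"ion-mode"`, `"adduct"`,
#'   `"collision-energy"` or `"missing-metadata"`).
#' @export
filter_spectrum <- function(rec) {
  stopifnot(inherits(rec, "spectrum_record"))
  rej <- function(reason) list(accept = FALSE, reason = reason)
  if (!is.finite(rec$precursor_mz) || rec$precursor_mz >= 1000)
    return(rej("precursor-range"))
  if (!identical(tolower(rec$ion_mode), "negative"))
    return(rej("ion-mode"))
  if (!.is_m_minus_h(rec$adduct))
    return(rej("adduct"))
  if (is.na(rec$collision_energy))
    return(rej("missing-metadata"))
  if (rec$collision_energy < 10 || rec$collision_energy > 50)
    return(rej("collision-energy"))
  list(accept = TRUE, reason = NA_character_)
}

.is_m_minus_h <- function(adduct) {
  if (is.na(adduct)) return(FALSE)
  a <- toupper(gsub("[[:space:]]", "", adduct))
  a %in% c("[M-H]-", "[M-H]1-", "M-H", "[M-H]", "(M-H)-")
}

#' Normalize peak intensities to the base peak
#'
#' Divides every intensity by the maximum so the base peak is 1.0.
#'
#' @param peaks data frame with `mz` and `intensity`.
#' @return the peak data frame with normalized intensities.
#' @export
normalize_intensities <- function(peaks) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0L) stop("empty-spectrum", call. = FALSE)
  mx <- max(peaks$intensity)
  if (mx <= 0) stop("degenerate-spectrum: all intensities zero", call. = FALSE)
  peaks$intensity <- peaks$intensity / mx
  peaks
}

#' Append neutral-loss features to a spectrum
#'
#' For every fragment peak p, a loss feature is added at
#' `precursor_mz - p$mz` carrying p's intensity: the neutral counterpart of
#' the detected charged fragment, which is otherwise invisible in MS2.
#' Loss features with non-positive m/z are dropped; fragment peaks are
#' unchanged.
#'
#' @param rec a `spectrum_record` with normalized intensities.
#' @return a new `spectrum_record` with loss peaks appended.
#' @export
add_loss_features <- function(rec) {
  stopifnot(inherits(rec, "spectrum_record"))
  frag <- rec$peaks[!rec$peaks$is_loss, , drop = FALSE]
  loss <- data.frame(mz = rec$precursor_mz - frag$mz,
                     intensity = frag$intensity, is_loss = TRUE)
  loss <- loss[loss$mz > 0, , drop = FALSE]
  rec$peaks <- rbind(frag, loss[order(loss$mz), , drop = FALSE])
  rownames(rec$peaks) <- NULL
  rec
}

#' Tokenize a spectrum at 0.01-Da resolution
#'
#' m/z values are rounded to two decimals (half away from zero) and mapped
#' to integer token ids `round(mz * 100)`, so the vocabulary spans 0..100000
#' for m/z in (0, 1000]. Fragment peaks are capped to the `max_peaks` most
#' intense before loss augmentation is considered; tokens are ordered
#' fragments-then-losses, each ascending by m/z, and truncated at
#' `max_len`. `detokenize_mz()` inverts the mapping to `round(mz, 2)`.
#'
#' @param rec a preprocessed `spectrum_record` (normalized, losses added).
#' @param max_peaks cap on fragment peaks (by intensity).
#' @param max_len cap on total sequence length.
#' @return object of class `tokenized_spectrum`: list with integer `tokens`,
#'   `intensities` in \[0,1\], and `segment_flags` (`"fragment"`/`"loss"`).
#' @export
tokenize_spectrum <- function(rec, max_peaks = 100L, max_len = 256L) {
  stopifnot(inherits(rec, "spectrum_record"))
  pk <- rec$peaks
  frag <- pk[!pk$is_loss, , drop = FALSE]
  loss <- pk[pk$is_loss, , drop = FALSE]
  if (nrow(frag) > max_peaks) {
    keep <- order(frag$intensity, decreasing = TRUE)[seq_len(max_peaks)]
    kept_mz <- frag$mz[sort(keep)]
    frag <- frag[sort(keep), , drop = FALSE]
    # drop losses whose fragment was dropped
    if (nrow(loss) > 0L) {
      loss_src <- rec$precursor_mz - loss$mz
      loss <- loss[vapply(loss_src, function(m)
        any(abs(kept_mz - m) < 1e-9), logical(1)), , drop = FALSE]
    }
  }
  frag <- frag[order(frag$mz), , drop = FALSE]
  loss <- loss[order(loss$mz), , drop = FALSE]
  mzs <- c(frag$mz, loss$mz)
  ints <- c(frag$intensity, loss$intensity)
  segs <- c(rep("fragment", nrow(frag)), rep("loss", nrow(loss)))
  tok <- mz_token(mzs)
  if (any(tok < 0L | tok > 100000L))
    stop("mz-range: token id outside [0, 100000]", call. = FALSE)
  if (length(tok) > max_len) {
    tok <- tok[seq_len(max_len)]; ints <- ints[seq_len(max_len)]
    segs <- segs[seq_len(max_len)]
  }
  structure(list(tokens = tok, intensities = ints, segment_flags = segs),
            class = "tokenized_spectrum")
}

#' @rdname tokenize_spectrum
#' @param mz numeric m/z values.
#' @export
mz_token <- function(mz) {
  # round half away from zero at the second decimal
  as.integer(floor(mz * 100 + 0.5))
}

#' @rdname tokenize_spectrum
#' @param token integer token ids.
#' @export
detokenize_mz <- function(token) token / 100

#' Precursor mass matching at ppm tolerance
#'
#' True iff `|observed - theoretical| / theoretical * 1e6 <= tol_ppm`
#' (inclusive). The denominator is always the theoretical mass, so the
#' relation is only approximately symmetric; see
#' [cluster_by_precursor()] for the symmetric max-denominator variant used
#' when grouping unannotated spectra.
#'
#' @param observed observed m/z (Da).
#' @param theoretical theoretical m/z (Da).
#' @param tol_ppm tolerance in parts per million.
#' @return logical.
#' @export
match_precursor_ppm <- function(observed, theoretical, tol_ppm = 5) {
  if (any(observed <= 0) || any(theoretical <= 0))
    stop("domain: masses must be positive", call. = FALSE)
  abs(observed - theoretical) / theoretical * 1e6 <= tol_ppm
}
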