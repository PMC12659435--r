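#' Compound-level dataset partitioning
#'
#' Splits spectra into train/validation/test sets at the compound level:
#' the distinct InChIKey2D compound keys are randomly partitioned according
#' to `fractions`, and all spectra of a compound travel together. This
#' prevents leakage of a structure (including its stereoisomers, which share
#' a key) across splits.
#'
#' @param records list of `spectrum_record`, each carrying a `compound_key`.
#' @param fractions numeric length-3 vector `(train, val, test)` summing
#'   to 1.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return list with elements `train`, `val`, `test` (lists of records) and
#'   `assignment` (data frame `compound_key`, `split`, `n_spectra`).
#' @export
split_by_compound <- function(records, fractions = c(0.9, 0, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8,
            all(fractions >= 0))
  keys <- vapply(records, function(r) {
    k <- r$compound_key
    if (is.null(k) || is.na(k)) NA_character_ else k
  }, character(1))
  if (any(is.na(keys)))
    stop("unlabeled: record without compound_key", call. = FALSE)
  uk <- unique(keys)
  n_nonzero <- sum(fractions > 0)
  if (length(uk) < n_nonzero)
    stop("too-few-compounds: fewer compounds than non-empty splits",
         call. = FALSE)
  perm <- with_preserved_seed({
    set.seed(as.integer(seed))
    sample(uk)
  })
  n <- length(perm)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  # guarantee each non-empty split gets at least one compound
  if (fractions[1] > 0 && n_train == 0L) n_train <- 1L
  if (fractions[2] > 0 && n_val == 0L) n_val <- 1L
  if (fractions[3] > 0 && n_train + n_val >= n)
    n_train <- n - n_val - 1L
  split_of <- rep("test", n)
  split_of[seq_len(n_train)] <- "train"
  if (n_val > 0L) split_of[n_train + seq_len(n_val)] <- "val"
  if (fractions[3] == 0) split_of[split_of == "test"] <- "train"
  names(split_of) <- perm
  pick <- function(s) records[keys %in% names(split_of)[split_of == s]]
  assignment <- data.frame(
    compound_key = perm,
    split = unname(split_of),
    n_spectra = vapply(perm, function(k) sum(keys == k), integer(1)))
  list(train = pick("train"), val = pick("val"), test = pick("test"),
       assignment = assignment)
}

#' Balance spectrum counts per compound
#'
#' Standardizes every compound to exactly `threshold` spectra.
#' Under-represented compounds are replicated whole
#' `floor(threshold / n)` times and the remainder drawn without
#' replacement; over-represented compounds keep a uniform random subset of
#' size `threshold`. Used on the training split only, to stabilize
#' training when spectrum counts per compound vary by orders of magnitude.
#'
#' @param records_by_compound named list mapping compound key to a list of
#'   `spectrum_record`s, or a flat list of records (grouped by their
#'   `compound_key`).
#' @param threshold target spectra per compound (default 50).
#' @param seed integer seed.
#' @return named list mapping compound key to exactly `threshold` records.
#' @export
oversample <- function(records_by_compound, threshold = 50L, seed = 1L) {
  if (threshold < 1L) stop("domain: threshold must be >= 1", call. = FALSE)
  if (!is.null(names(records_by_compound)) &&
      all(vapply(records_by_compound, is.list, logical(1))) &&
      !inherits(records_by_compound[[1]], "spectrum_record")) {
    grouped <- records_by_compound
  } else {
    keys <- vapply(records_by_compound, `[[`, character(1), "compound_key")
    grouped <- split(records_by_compound, keys)
  }
  stopifnot(all(vapply(grouped, length, integer(1)) >= 1L))
  with_preserved_seed({
    set.seed(as.integer(seed))
    lapply(grouped, function(sp) {
      n <- length(sp)
      if (n == threshold) return(sp)
      if (n > threshold) return(sp[sort(sample.int(n, threshold))])
      reps <- threshold %/% n
      rem <- threshold - reps * n
      idx <- c(rep(seq_len(n), reps),
               if (rem > 0L) sample.int(n, rem) else integer(0))
      sp[idx]
    })
  })
}

#' Write a split manifest TSV
#'
#' @param assignment the `assignment` data frame from [split_by_compound()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(assignment, path) {
  utils::write.table(assignment, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
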