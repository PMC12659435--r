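test_that("MGF parsing preserves precursor and peaks, skips broken entries", {
  mgf <- file.path(tempdir(), "t1.mgf")
  writeLines(c("BEGIN IONS", "TITLE=a", "PEPMASS=412.9664", "CHARGE=1-",
               "IONMODE=negative", "ADDUCT=[M-H]-", "COLLISION_ENERGY=35",
               "118.9925 100", "168.9893 50", "368.9766 20", "END IONS",
               "BEGIN IONS", "TITLE=broken (no pepmass)", "IONMODE=negative",
               "100.0 1", "END IONS"), mgf)
  expect_warning(recs <- read_spectra(mgf), "skipped 1")
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$precursor_mz, 412.9664)
  expect_equal(nrow(recs[[1]]$peaks), 3L)
  expect_equal(recs[[1]]$collision_energy, 35)
  expect_identical(recs[[1]]$ion_mode, "negative")
})

test_that("MSP parsing follows the NIST convention", {
  msp <- file.path(tempdir(), "t1.msp")
  writeLines(c("Name: PFOS-like", "PrecursorMZ: 498.9302",
               "Precursor_type: [M-H]-", "Ion_mode: N",
               "Collision_energy: 40", "Num Peaks: 2",
               "79.9574 100", "98.9561 80", "",
               "Name: no precursor", "Num Peaks: 1", "50.0 1", ""), msp)
  expect_warning(recs <- read_spectra(msp), "skipped 1")
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$precursor_mz, 498.9302)
  expect_identical(recs[[1]]$ion_mode, "negative")
  expect_equal(recs[[1]]$collision_energy, 40)
})

test_that("spectra round-trip through MGF and MSP to 1e-4 Da", {
  lib <- small_library()
  specs <- quick_spectra(lib[1:6])
  for (fmt in c("mgf", "msp")) {
    path <- file.path(tempdir(), paste0("rt.", fmt))
    write_spectra(specs, path, fmt)
    back <- read_spectra(path)
    expect_length(back, length(specs))
    for (i in seq_along(specs)) {
      expect_equal(back[[i]]$precursor_mz, specs[[i]]$precursor_mz,
                   tolerance = 1e-4)
      expect_equal(back[[i]]$peaks$mz,
                   specs[[i]]$peaks$mz[!specs[[i]]$peaks$is_loss],
                   tolerance = 1e-4)
      expect_identical(filter_spectrum(back[[i]])$accept, TRUE)
    }
  }
  expect_error(read_spectra(file.path(tempdir(), "absent.mgf")), "io")
})

test_that("validity filter applies the three criteria with inclusive CE bounds", {
  base <- function(...) {
    args <- utils::modifyList(
      list(precursor_mz = 499.0, peaks = data.frame(mz = 100, intensity = 1),
           adduct = "[M-H]-", ion_mode = "negative", collision_energy = 35),
      list(...))
    do.call(spectrum_record, args)
  }
  expect_true(filter_spectrum(base())$accept)
  expect_identical(filter_spectrum(base(precursor_mz = 1200))$reason,
                   "precursor-range")
  expect_identical(filter_spectrum(base(ion_mode = "positive"))$reason,
                   "ion-mode")
  expect_identical(filter_spectrum(base(adduct = "[M+H]+"))$reason, "adduct")
  expect_identical(filter_spectrum(base(collision_energy = 60))$reason,
                   "collision-energy")
  expect_identical(filter_spectrum(base(collision_energy = 5))$reason,
                   "collision-energy")
  # inclusive at both ends
  expect_true(filter_spectrum(base(collision_energy = 10))$accept)
  expect_true(filter_spectrum(base(collision_energy = 50))$accept)
  expect_identical(filter_spectrum(base(collision_energy = NA))$reason,
                   "missing-metadata")
  # adduct normalization
  for (a in c("[M-H]-", "[M-H]1-", "m-h", " [M-H]- "))
    expect_true(filter_spectrum(base(adduct = a))$accept)
})

test_that("intensity normalization sets the base peak to 1", {
  pk <- data.frame(mz = c(100, 200), intensity = c(50, 100))
  out <- normalize_intensities(pk)
  expect_equal(out$intensity, c(0.5, 1.0))
  expect_equal(normalize_intensities(
    data.frame(mz = 1, intensity = 17))$intensity, 1.0)
  expect_equal(normalize_intensities(
    data.frame(mz = c(100, 150), intensity = c(2, 2)))$intensity, c(1, 1))
  expect_error(normalize_intensities(pk[0, ]), "empty-spectrum")
  expect_error(normalize_intensities(
    data.frame(mz = 1, intensity = 0)), "degenerate")
})

test_that("loss features mirror fragments about the precursor", {
  rec <- spectrum_record(200.0, data.frame(mz = c(50, 120, 200),
                                           intensity = c(0.5, 1.0, 0.2)),
                         collision_energy = 30)
  out <- add_loss_features(rec)
  loss <- out$peaks[out$peaks$is_loss, ]
  frag <- out$peaks[!out$peaks$is_loss, ]
  # fragment at exactly the precursor gives loss mz 0 -> dropped
  expect_equal(nrow(loss), 2L)
  expect_equal(sort(loss$mz), c(80, 150))
  expect_equal(loss$intensity[order(loss$mz)], c(1.0, 0.5))
  # fragments unchanged, count at most doubled
  expect_equal(frag$mz, rec$peaks$mz)
  expect_lte(nrow(loss), nrow(frag))
  # conservation
  for (lm in loss$mz)
    expect_true(any(abs(lm + frag$mz - rec$precursor_mz) < 0.005))
})

test_that("0.01-Da tokenization rounds half away from zero and inverts", {
  expect_identical(mz_token(118.9925), 11899L)
  expect_identical(mz_token(50.005), 5001L)
  set.seed(31)
  mz <- runif(1000, 1e-3, 1000 - 1e-3)
  expect_equal(detokenize_mz(mz_token(mz)), round(mz, 2), tolerance = 1e-12)
})

test_that("spectrum tokenization orders fragments then losses and caps peaks", {
  rec <- spectrum_record(300.0, data.frame(mz = c(120.5, 40.25, 250.0),
                                           intensity = c(1.0, 0.4, 0.8)),
                         collision_energy = 30)
  ts <- tokenize_spectrum(add_loss_features(rec))
  expect_s3_class(ts, "tokenized_spectrum")
  expect_identical(length(ts$tokens), length(ts$intensities))
  expect_identical(length(ts$tokens), length(ts$segment_flags))
  expect_equal(max(ts$intensities), 1)
  frag_part <- ts$tokens[ts$segment_flags == "fragment"]
  loss_part <- ts$tokens[ts$segment_flags == "loss"]
  expect_false(is.unsorted(frag_part))
  expect_false(is.unsorted(loss_part))
  expect_identical(frag_part, mz_token(c(40.25, 120.5, 250.0)))
  # peak cap keeps the most intense fragments
  rec2 <- spectrum_record(900.0, data.frame(mz = seq(10, 500, by = 10),
                                            intensity = seq(0.02, 1,
                                                            length.out = 50)),
                          collision_energy = 30)
  ts2 <- tokenize_spectrum(add_loss_features(rec2), max_peaks = 5L)
  expect_identical(sum(ts2$segment_flags == "fragment"), 5L)
  expect_identical(sum(ts2$segment_flags == "loss"), 5L)
  # deterministic
  expect_identical(tokenize_spectrum(add_loss_features(rec)),
                   tokenize_spectrum(add_loss_features(rec)))
})

test_that("ppm matching is inclusive and divides by the theoretical mass", {
  expect_true(match_precursor_ppm(500.0000, 500.0020, 5))   # 4 ppm
  expect_false(match_precursor_ppm(500.0000, 500.0100, 5))  # 20 ppm
  expect_true(match_precursor_ppm(500.0000, 500.0025, 5))   # exactly 5 ppm
  expect_error(match_precursor_ppm(-1, 500), "domain")
})
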