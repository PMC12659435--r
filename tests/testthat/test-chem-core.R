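test_that("prepare_molecule cleans, canonicalizes and is idempotent", {
  rec <- prepare_molecule("C(/F)=C/F")
  expect_s3_class(rec, "molecule_record")
  expect_false(grepl("[/\\\\@]", rec$canonical_smiles))
  # idempotence: preparing the canonical form returns the same string
  rec2 <- prepare_molecule(rec$canonical_smiles)
  expect_identical(rec2$canonical_smiles, rec$canonical_smiles)

  r3 <- prepare_molecule("OCC")
  expect_identical(r3$canonical_smiles,
                   prepare_molecule(r3$canonical_smiles)$canonical_smiles)
})

test_that("prepare_molecule rejects with the violated rule", {
  expect_identical(prepare_molecule("CCO.[Na+]")$reason, "disconnected")
  expect_identical(prepare_molecule("[Si](C)(C)C")$reason,
                   "disallowed-element")
  expect_identical(prepare_molecule("xx!!notasmiles")$reason, "unparseable")
  # > 1000 Da: a long perfluorinated chain
  heavy <- paste0("OC(=O)", strrep("C(F)(F)", 20), "F")
  expect_identical(prepare_molecule(heavy)$reason, "too-heavy")
  expect_true(is_rejection(prepare_molecule("CCO.[Na+]")))
  expect_false(is_rejection(prepare_molecule("CCO")))
})

test_that("record invariants hold across a generated library", {
  lib <- small_library()
  for (r in lib) {
    expect_false(grepl("[@/\\\\.]", r$canonical_smiles))
    expect_lte(length(r$smiles_tokens), 110L)
    expect_lt(r$monoisotopic_mass, 1000)
    expect_match(r$inchikey2d, "^[A-Z]{14}$")
    expect_identical(paste(r$smiles_tokens, collapse = ""),
                     r$canonical_smiles)
  }
})

test_that("tokenize_smiles treats Cl/Br as single tokens and round-trips", {
  expect_identical(tokenize_smiles("CCO"), c("C", "C", "O"))
  expect_identical(tokenize_smiles("C(Cl)Br"), c("C", "(", "Cl", ")", "Br"))
  expect_identical(tokenize_smiles("c1ccccc1"),
                   c("c", "1", "c", "c", "c", "c", "c", "1"))
  for (s in c("OS(=O)(=O)C(F)(F)F", "[O-]C(=O)CBr", "C%12CCC%12",
              "ClC(Cl)(Cl)Cl")) {
    expect_identical(paste(tokenize_smiles(s), collapse = ""), s)
  }
})

test_that("randomized SMILES are deterministic per seed and canonicalize back", {
  lib <- small_library()
  for (r in lib[seq(1, length(lib), by = 3)]) {
    expect_identical(randomize_smiles(r, 7L), randomize_smiles(r, 7L))
    for (seed in c(1L, 2L, 3L)) {
      rnd <- randomize_smiles(r, seed)
      back <- prepare_molecule(rnd)
      expect_s3_class(back, "molecule_record")
      expect_identical(back$canonical_smiles, r$canonical_smiles)
    }
  }
  # single-atom molecule has a unique serialization
  expect_identical(randomize_smiles(prepare_molecule("C"), 99L), "C")
})

test_that("inchikey2d hashes connectivity and ignores stereochemistry", {
  expect_identical(inchikey2d(prepare_molecule("CCO")), "LFQSCWFLJHTTHZ")
  r_form <- prepare_molecule("C[C@H](O)CC")
  s_form <- prepare_molecule("C[C@@H](O)CC")
  expect_identical(r_form$inchikey2d, s_form$inchikey2d)
  expect_false(inchikey2d(prepare_molecule("CCO")) ==
                 inchikey2d(prepare_molecule("COC")))
})

test_that("formula and monoisotopic mass match atomic-mass summation", {
  m <- prepare_molecule("C")
  expect_identical(m$formula, "CH4")
  expect_equal(m$monoisotopic_mass, 16.0313, tolerance = 1e-4)
  w <- prepare_molecule("O")
  expect_identical(w$formula, "H2O")
  expect_equal(w$monoisotopic_mass, 18.0106, tolerance = 1e-4)
  t <- prepare_molecule("OS(=O)(=O)C(F)(F)F")
  expect_identical(t$formula, "CHF3O3S")
  expect_equal(t$monoisotopic_mass, oracle_formula_mass("CHF3O3S"),
               tolerance = 1e-4)
  # Hill ordering without carbon: alphabetical
  expect_identical(prepare_molecule("OO")$formula, "H2O2")
  # oracle agreement across the library
  for (r in small_library())
    expect_equal(r$monoisotopic_mass, oracle_formula_mass(r$formula),
                 tolerance = 1e-6)
})

test_that("OECD PFAS rule: >=2 F on a carbon with no attached H/Cl/Br/I", {
  expect_true(classify_pfas(prepare_molecule("OS(=O)(=O)C(F)(F)C(F)(F)F")))
  expect_false(classify_pfas(prepare_molecule("CCO")))
  expect_false(classify_pfas(prepare_molecule("C(F)(F)F")))   # CHF3
  expect_false(classify_pfas(prepare_molecule("FCF")))        # CH2F2
  expect_true(classify_pfas(prepare_molecule("FC(F)(F)C(F)(F)F")))
})

test_that("molecule library IO round-trips with sidecar", {
  lib <- small_library()[1:8]
  path <- file.path(tempdir(), "lib_roundtrip.smi")
  write_molecule_library(lib, path)
  back <- read_molecule_library(path)
  expect_length(back$records, 8L)
  expect_identical(vapply(back$records, `[[`, character(1), "canonical_smiles"),
                   vapply(lib, `[[`, character(1), "canonical_smiles"))
  side <- read.delim(paste0(path, ".tsv"))
  expect_identical(nrow(side), 8L)
  expect_identical(side$is_pfas, vapply(lib, `[[`, logical(1), "is_pfas"))
  # rejected entries are reported, not dropped silently
  writeLines(c("CCO", "CCO.[Na+]", "CCC"), path)
  mix <- read_molecule_library(path)
  expect_length(mix$records, 2L)
  expect_length(mix$rejections, 1L)
  expect_identical(mix$rejections[[1]]$reason, "disconnected")
})
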