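test_that("MCS metrics reproduce hand-derived values", {
  eth <- prepare_molecule("CC")
  prop <- prepare_molecule("CCC")
  m <- mcs_metrics(eth, prop)
  expect_equal(m$ratio, 1)
  expect_equal(m$overlap, 1)
  expect_equal(m$tanimoto, 2 / 3)
  # identical molecules
  m2 <- mcs_metrics(prop, prop)
  expect_equal(unlist(m2[c("ratio", "tanimoto", "overlap")]), c(1, 1, 1),
               ignore_attr = TRUE)
  # no common typed atom
  m3 <- mcs_metrics(prepare_molecule("C"), prepare_molecule("O"))
  expect_equal(unlist(m3[c("ratio", "tanimoto", "overlap")]), c(0, 0, 0),
               ignore_attr = TRUE)
})

test_that("MCS respects ring membership and bond order in matching", {
  # cyclohexane vs hexane share no ring-atom correspondence
  cyc <- prepare_molecule("C1CCCCC1")
  hex <- prepare_molecule("CCCCCC")
  expect_equal(mcs_metrics(cyc, hex)$a_mcs, 0L)
  # double vs single bonds do not match
  ethene <- prepare_molecule("C=C")
  ethane <- prepare_molecule("CC")
  expect_equal(mcs_metrics(ethene, ethane)$a_mcs, 1L)
})

test_that("MCS equals the exhaustive oracle on small molecule pairs", {
  smis <- c("CCO", "CCC", "CC(C)O", "OCC(N)C", "CC(=O)O", "c1ccccc1",
            "Cc1ccccc1", "OC(=O)C(F)(F)F")
  recs <- lapply(smis, prepare_molecule)
  for (i in seq_along(recs)) for (j in seq_len(i)) {
    got <- mcs_metrics(recs[[i]], recs[[j]])$a_mcs
    want <- oracle_mcs_size(recs[[i]], recs[[j]])
    expect_identical(as.integer(got), as.integer(want),
                     info = paste(smis[i], "vs", smis[j]))
  }
})

test_that("MCS triple obeys its order relations", {
  smis <- list(c("CCO", "CCCO"), c("CC(=O)O", "CCC"), c("c1ccccc1", "CCO"),
               c("OC(=O)C(F)(F)F", "FC(F)(F)F"))
  for (pr in smis) {
    a <- prepare_molecule(pr[1]); b <- prepare_molecule(pr[2])
    m <- mcs_metrics(a, b)
    expect_lte(m$tanimoto, m$overlap + 1e-12)
    if (b$graph$n <= a$graph$n)
      expect_gte(m$overlap, m$ratio - 1e-12)
  }
})

test_that("fingerprint similarity statistics follow the Tanimoto definition", {
  ref <- prepare_molecule("CCO")
  st <- fingerprint_similarity_stats(ref, list(ref))
  expect_equal(unlist(st), c(avg = 1, max = 1, min = 1))
  cands <- lapply(c("CCO", "CCC", "c1ccccc1"), prepare_molecule)
  st2 <- fingerprint_similarity_stats(ref, cands)
  expect_gte(st2$max, st2$avg)
  expect_lte(st2$min, st2$avg)
  expect_equal(st2$max, 1)  # self among candidates
  # permutation invariance
  st3 <- fingerprint_similarity_stats(ref, cands[c(3, 1, 2)])
  expect_equal(st2, st3)
  expect_error(fingerprint_similarity_stats(ref, list()), "empty-input")
  # hand-constructed set arithmetic
  a <- rep(FALSE, 2048); a[1:3] <- TRUE
  b <- rep(FALSE, 2048); b[2:5] <- TRUE
  expect_equal(tanimoto(a, b), 2 / 5)
})

# hand-built annotation results: 3 compounds, 10 spectra
mk_result <- function(id, hit_keys, hit_formulas, pfas) {
  hits <- data.frame(rank = seq_along(hit_keys),
                     canonical_smiles = paste0("S", seq_along(hit_keys)),
                     inchikey2d = hit_keys, formula = hit_formulas,
                     mw = 100, distance = seq_along(hit_keys) * 0.1,
                     is_pfas = pfas)
  structure(list(spectrum_id = id, hits = hits,
                 confidence_score = 100 * mean(pfas)),
            class = "annotation_result")
}

test_that("retrieval evaluation reproduces hand-computed MA/FA/MAS/FAS", {
  K <- c(A = "AAAAAAAAAAAAAA", B = "BBBBBBBBBBBBBB", C = "CCCCCCCCCCCCCC")
  other <- "ZZZZZZZZZZZZZZ"
  truth <- data.frame(
    spectrum_id = paste0("s", 1:10),
    inchikey2d = c(rep(K["A"], 4), rep(K["B"], 3), rep(K["C"], 3)),
    formula = c(rep("C2H6O", 4), rep("C3H8", 3), rep("CH4", 3)))
  results <- list(
    # compound A: 1 of 4 spectra correct -> MA hit, MAS 1/10 so far
    mk_result("s1", c(K["A"], other), c("C2H6O", "X"), c(TRUE, FALSE)),
    mk_result("s2", c(other, other), c("X", "X"), c(FALSE, FALSE)),
    mk_result("s3", c(other, other), c("X", "X"), c(FALSE, FALSE)),
    mk_result("s4", c(other, other), c("X", "X"), c(FALSE, FALSE)),
    # compound B: formula right, structure wrong -> FA yes, MA no
    mk_result("s5", c(other, other), c("C3H8", "X"), c(TRUE, TRUE)),
    mk_result("s6", c(other, other), c("X", "X"), c(TRUE, TRUE)),
    mk_result("s7", c(other, other), c("X", "X"), c(TRUE, TRUE)),
    # compound C: never retrieved
    mk_result("s8", c(other, other), c("X", "X"), c(FALSE, TRUE)),
    mk_result("s9", c(other, other), c("X", "X"), c(FALSE, TRUE)),
    mk_result("s10", c(other, other), c("X", "X"), c(FALSE, TRUE)))
  rep <- evaluate_retrieval(results, truth)
  expect_equal(rep$ma, 100 * 1 / 3)    # only compound A
  expect_equal(rep$fa, 100 * 2 / 3)    # A (via s1) and B (via s5)
  expect_equal(rep$mas, 100 * 1 / 10)
  expect_equal(rep$fas, 100 * 2 / 10)
  expect_identical(rep$n_compounds, 3L)
  expect_identical(rep$n_spectra, 10L)
  pc <- rep$per_compound
  expect_equal(pc$annotation_accuracy[pc$inchikey2d == K[["A"]]], 25)
  expect_equal(pc$n_correct[pc$inchikey2d == K[["C"]]], 0L)
  # orphan spectrum
  expect_error(evaluate_retrieval(results, truth[-1, ]), "missing-truth")
})

test_that("dataset confidence level uses strict all-PFAS semantics", {
  all_p <- mk_result("x1", c("K1", "K2"), c("F1", "F2"), c(TRUE, TRUE))
  one_not <- mk_result("x2", c("K1", "K2"), c("F1", "F2"), c(TRUE, FALSE))
  expect_equal(dataset_confidence_level(list(all_p, all_p)), 100)
  expect_equal(dataset_confidence_level(list(all_p, all_p, all_p, one_not)),
               75)
  # a 50% per-spectrum confidence never counts toward the numerator
  expect_equal(dataset_confidence_level(list(one_not)), 0)
  expect_error(dataset_confidence_level(list()), "empty-input")
})
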