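# independent brute-force oracles used to check the package implementations

# --- maximum common induced substructure by exhaustive subset enumeration ---
# enumerates subsets of reference atoms in decreasing size and searches for
# an injective, label- and induced-bond-preserving map into the predicted
# molecule by plain backtracking; completely independent of the clique-based
# implementation in the package
oracle_mcs_size <- function(rec_ref, rec_pred) {
  g1 <- rec_ref$graph; g2 <- rec_pred$graph
  lab <- function(m) paste(m$symbol, m$aromatic, m$ring_atom, sep = "|")
  bm <- function(m) {
    B <- matrix(0L, m$n, m$n)
    if (nrow(m$bonds) > 0L) {
      code <- m$bonds$order + 10L * m$bonds$arom + 100L * m$ring_bond
      B[cbind(m$bonds$a1, m$bonds$a2)] <- code
      B[cbind(m$bonds$a2, m$bonds$a1)] <- code
    }
    B
  }
  l1 <- lab(g1); l2 <- lab(g2); B1 <- bm(g1); B2 <- bm(g2)
  can_embed <- function(subset) {
    k <- length(subset)
    assign_next <- function(i, used, map) {
      if (i > k) return(TRUE)
      a <- subset[i]
      for (cand in seq_len(g2$n)) {
        if (used[cand] || l1[a] != l2[cand]) next
        ok <- TRUE
        for (j in seq_len(i - 1L)) {
          if (B1[a, subset[j]] != B2[cand, map[j]]) { ok <- FALSE; break }
        }
        if (!ok) next
        used2 <- used; used2[cand] <- TRUE
        if (assign_next(i + 1L, used2, c(map, cand))) return(TRUE)
      }
      FALSE
    }
    assign_next(1L, rep(FALSE, g2$n), integer(0))
  }
  n <- g1$n
  for (size in seq(min(n, g2$n), 1L)) {
    subsets <- utils::combn(n, size, simplify = FALSE)
    for (s in subsets) if (can_embed(s)) return(size)
  }
  0L
}

# --- exhaustive top-k retrieval by full sort ------------------------------
oracle_topk <- function(query, embeddings, canon, k) {
  mse <- colMeans((t(embeddings) - query)^2)
  ord <- order(mse, canon, method = "radix")
  ord[seq_len(min(k, length(ord)))]
}

# --- O(n^2) clustering via connected components ---------------------------
oracle_clusters <- function(pm, tol_ppm = 5) {
  n <- length(pm)
  A <- outer(pm, pm, function(a, b) abs(a - b) / pmax(a, b) * 1e6 <= tol_ppm)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

# same-partition equivalence of two cluster labelings
same_partition <- function(c1, c2) {
  identical(outer(c1, c1, "=="), outer(c2, c2, "=="))
}

# --- atomic-mass summation from a formula string --------------------------
oracle_formula_mass <- function(formula) {
  masses <- c(H = 1.00782503207, B = 11.0093054, C = 12.0,
              N = 14.0030740048, O = 15.9949146196, F = 18.99840322,
              P = 30.97376163, S = 31.97207100, Cl = 34.96885268,
              Br = 78.9183371, I = 126.904473)
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  tot <- 0
  for (tk in toks) {
    el <- gsub("[0-9]", "", tk)
    cnt <- gsub("[^0-9]", "", tk)
    tot <- tot + masses[[el]] * if (nzchar(cnt)) as.integer(cnt) else 1L
  }
  tot
}
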