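#' Molecular graphs from SMILES
#'
#' A minimal molecular-graph layer over SMILES strings, restricted to the
#' eleven elements supported by the screening pipeline (C, N, H, O, P, S,
#' Cl, Br, F, I, B). The graph representation backs formula and
#' monoisotopic-mass computation, the OECD PFAS structural predicate,
#' in-silico fragmentation, path fingerprints and maximum-common-substructure
#' search. Canonicalization itself is delegated to Open Babel (via
#' \pkg{ChemmineOB}); this layer never needs to produce canonical output,
#' only chemically faithful graphs and valid (possibly randomized)
#' serializations.
#'
#' @name smiles-graph
#' @keywords internal
NULL

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, aromatic lowercase atoms, bracket atoms with
#' explicit hydrogen counts and charges, ring closures (including `%nn`),
#' branches, and explicit bond orders. Stereo bond markers (`/`, `\\`) are
#' read as plain single bonds and chirality tags inside brackets are
#' ignored; callers that must guarantee stereo-free structures strip these
#' upstream. Disconnected structures (`.`) are an error.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `mol_graph`: a list with `n` (atom count),
#'   `symbol`, `aromatic`, `charge`, `hexp` (explicit H count, `NA` when
#'   implicit), `h` (resolved total hydrogen count per atom), `bonds`
#'   (data frame `a1`, `a2`, `order`, `arom`), and ring-membership flags
#'   `ring_atom`, `ring_bond`.
#' @keywords internal
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  nc <- length(chars)
  if (nc == 0L) stop("empty SMILES", call. = FALSE)

  sym <- character(0); arom <- logical(0); charge <- integer(0)
  hexp <- integer(0)
  b_a1 <- integer(0); b_a2 <- integer(0); b_ord <- integer(0); b_arom <- logical(0)

  prev <- 0L                  # atom index awaiting a bond to the next atom
  pending_bond <- NA_character_
  stack <- integer(0)
  ring_open <- list()         # digit -> list(atom, bond)

  add_atom <- function(s, ar, ch, hx) {
    sym <<- c(sym, s); arom <<- c(arom, ar)
    charge <<- c(charge, as.integer(ch)); hexp <<- c(hexp, as.integer(hx))
    length(sym)
  }
  add_bond <- function(a1, a2, bondchar, both_arom) {
    if (is.na(bondchar)) {
      if (both_arom) { ord <- 1L; ar <- TRUE } else { ord <- 1L; ar <- FALSE }
    } else {
      ord <- switch(bondchar, "-" = 1L, "/" = 1L, "\\" = 1L,
                    "=" = 2L, "#" = 3L, ":" = 1L,
                    stop("bad bond char", call. = FALSE))
      ar <- identical(bondchar, ":")
    }
    b_a1 <<- c(b_a1, a1); b_a2 <<- c(b_a2, a2)
    b_ord <<- c(b_ord, ord); b_arom <<- c(b_arom, ar)
  }
  link <- function(idx) {
    if (prev > 0L)
      add_bond(prev, idx, pending_bond, arom[prev] && arom[idx])
    pending_bond <<- NA_character_
    prev <<- idx
  }

  i <- 1L
  while (i <= nc) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= nc && chars[j] != "]") j <- j + 1L
      if (j > nc) stop("unterminated bracket atom", call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parse_bracket_atom(body)
      idx <- add_atom(at$symbol, at$aromatic, at$charge, at$hcount)
      link(idx)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < nc && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      idx <- add_atom(paste0(ch, chars[i + 1L]), FALSE, 0L, NA_integer_)
      link(idx); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      idx <- add_atom(ch, FALSE, 0L, NA_integer_)
      link(idx); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE, 0L, NA_integer_)
      link(idx); i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch; i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced parenthesis", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > nc) stop("bad %nn ring closure", call. = FALSE)
        key <- paste(chars[(i + 1L):(i + 2L)], collapse = "")
        i <- i + 3L
      } else {
        key <- ch; i <- i + 1L
      }
      if (prev == 0L) stop("ring closure before any atom", call. = FALSE)
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        bondchar <- pending_bond
        if (is.na(bondchar)) bondchar <- op$bond
        add_bond(op$atom, prev, bondchar, arom[op$atom] && arom[prev])
        ring_open[[key]] <- NULL
      } else {
        ring_open[[key]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- NA_character_
    } else if (ch == ".") {
      stop("disconnected SMILES (dot) not supported", call. = FALSE)
    } else {
      stop(sprintf("unexpected character '%s' in SMILES", ch), call. = FALSE)
    }
  }
  if (length(ring_open) > 0L) stop("unclosed ring bond", call. = FALSE)
  if (length(stack) > 0L) stop("unbalanced parenthesis", call. = FALSE)
  n <- length(sym)
  if (n == 0L) stop("no atoms parsed", call. = FALSE)

  mol <- list(n = n, symbol = sym, aromatic = arom, charge = charge,
              hexp = hexp,
              bonds = data.frame(a1 = b_a1, a2 = b_a2, order = b_ord,
                                 arom = b_arom))
  mol <- .perceive_rings(mol)
  # an "aromatic" bond outside any ring (e.g. biphenyl written without '-')
  # is really a single bond between two aromatic systems
  if (nrow(mol$bonds) > 0L) {
    demote <- mol$bonds$arom & !mol$ring_bond
    mol$bonds$arom[demote] <- FALSE
  }
  mol$h <- .implicit_hydrogens(mol)
  class(mol) <- "mol_graph"
  mol
}

.parse_bracket_atom <- function(body) {
  # [isotope? symbol chiral? Hcount? charge? :class?]
  re <- "^([0-9]*)([A-IK-PR-Zb-ik-pr-z][a-z]?)(@{0,2}H?[0-9]*)?"
  # simpler manual scan
  i <- 1L; cs <- strsplit(body, "", fixed = TRUE)[[1]]; nc <- length(cs)
  while (i <= nc && grepl("^[0-9]$", cs[i])) i <- i + 1L  # isotope ignored
  if (i > nc) stop("bad bracket atom", call. = FALSE)
  if (i < nc && grepl("^[A-Z]$", cs[i]) && grepl("^[a-z]$", cs[i + 1L])) {
    # any two-letter element symbol (Cl, Br, but also Si, Na, ...); elements
    # outside the supported set are caught downstream by the element filter
    symbol <- paste0(cs[i], cs[i + 1L]); aromatic <- FALSE; i <- i + 2L
  } else if (grepl("^[A-Z]$", cs[i])) {
    symbol <- cs[i]; aromatic <- FALSE; i <- i + 1L
  } else if (grepl("^[a-z]$", cs[i])) {
    symbol <- toupper(cs[i]); aromatic <- TRUE; i <- i + 1L
  } else stop("bad bracket atom symbol", call. = FALSE)
  while (i <= nc && cs[i] == "@") i <- i + 1L  # chirality ignored
  hcount <- 0L
  if (i <= nc && cs[i] == "H") {
    i <- i + 1L; d <- ""
    while (i <= nc && grepl("^[0-9]$", cs[i])) { d <- paste0(d, cs[i]); i <- i + 1L }
    hcount <- if (nzchar(d)) as.integer(d) else 1L
  }
  charge <- 0L
  if (i <= nc && cs[i] %in% c("+", "-")) {
    sgn <- if (cs[i] == "+") 1L else -1L
    k <- 0L
    while (i <= nc && cs[i] %in% c("+", "-")) { k <- k + 1L; i <- i + 1L }
    d <- ""
    while (i <= nc && grepl("^[0-9]$", cs[i])) { d <- paste0(d, cs[i]); i <- i + 1L }
    charge <- if (nzchar(d)) sgn * as.integer(d) else sgn * k
  }
  # atom class (:n) ignored
  list(symbol = symbol, aromatic = aromatic, charge = charge, hcount = hcount)
}

# ring membership: a bond is in a ring iff it is not a bridge
.perceive_rings <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) {
    mol$ring_bond <- logical(0)
    mol$ring_atom <- rep(FALSE, mol$n)
    return(mol)
  }
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < mol$n)
    g <- igraph::add_vertices(g, mol$n - igraph::vcount(g))
  br <- igraph::bridges(g)
  ring_bond <- rep(TRUE, nb)
  ring_bond[as.integer(br)] <- FALSE
  mol$ring_bond <- ring_bond
  ring_atom <- rep(FALSE, mol$n)
  ra <- unique(c(mol$bonds$a1[ring_bond], mol$bonds$a2[ring_bond]))
  ring_atom[ra] <- TRUE
  mol$ring_atom <- ring_atom
  mol
}

# fill implicit hydrogens from default valence ladders; aromatic atoms are
# treated as carrying one extra (pi) bond beyond their sigma connections
.implicit_hydrogens <- function(mol) {
  bondsum <- rep(0, mol$n)
  if (nrow(mol$bonds) > 0L) {
    ord <- ifelse(mol$bonds$arom, 1, mol$bonds$order)
    for (k in seq_len(nrow(mol$bonds))) {
      bondsum[mol$bonds$a1[k]] <- bondsum[mol$bonds$a1[k]] + ord[k]
      bondsum[mol$bonds$a2[k]] <- bondsum[mol$bonds$a2[k]] + ord[k]
    }
  }
  h <- integer(mol$n)
  for (i in seq_len(mol$n)) {
    if (!is.na(mol$hexp[i])) { h[i] <- mol$hexp[i]; next }
    bs <- bondsum[i] + if (mol$aromatic[i]) 1 else 0
    vals <- .VALENCES[[mol$symbol[i]]]
    if (is.null(vals)) { h[i] <- 0L; next }
    v <- vals[vals >= bs]
    h[i] <- if (length(v) == 0L) 0L else as.integer(v[1] - bs)
  }
  h
}

#' Serialize a molecular graph back to SMILES
#'
#' Depth-first serialization with ring-closure digits. Atom visiting order is
#' controlled by `start` and `shuffle`, which is how randomized SMILES are
#' produced; with the defaults the output order follows atom indices. Output
#' is always a valid SMILES that re-parses to the same graph (and hence
#' canonicalizes to the same structure); it is not itself canonical.
#'
#' @param mol a `mol_graph`.
#' @param start index of the first atom to emit.
#' @param shuffle logical; randomize the order in which branches are visited
#'   (uses the current RNG stream).
#' @return a SMILES string.
#' @keywords internal
write_smiles <- function(mol, start = 1L, shuffle = FALSE) {
  n <- mol$n
  nb <- nrow(mol$bonds)
  adj <- vector("list", n)
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      adj[[a]] <- c(adj[[a]], k); adj[[b]] <- c(adj[[b]], k)
    }
  }
  other_end <- function(k, at) {
    if (mol$bonds$a1[k] == at) mol$bonds$a2[k] else mol$bonds$a1[k]
  }
  out <- character(0)
  emit <- function(x) out <<- c(out, x)

  bond_char <- function(k) {
    if (nb == 0L) return("")
    if (mol$bonds$arom[k]) return("")
    o <- mol$bonds$order[k]
    if (o == 2L) return("=")
    if (o == 3L) return("#")
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    if (mol$aromatic[a] && mol$aromatic[b]) return("-")  # e.g. biphenyl
    ""
  }
  atom_token <- function(i) {
    s <- mol$symbol[i]
    tok_sym <- if (mol$aromatic[i]) tolower(s) else s
    needs_bracket <- mol$charge[i] != 0L || !is.na(mol$hexp[i]) ||
      (mol$aromatic[i] && !(s %in% .AROMATIC_OK))
    if (!needs_bracket) return(tok_sym)
    h <- mol$h[i]
    htxt <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ch <- mol$charge[i]
    ctxt <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
            else sprintf("%+d", ch)
    paste0("[", tok_sym, htxt, ctxt, "]")
  }

  # two-phase serialization: a DFS spanning tree first (so both ends of every
  # ring-closure bond are known), then emission with closure digits placed
  # immediately after their atom tokens
  order_children <- function(ks) {
    if (length(ks) <= 1L) return(ks)
    if (shuffle) sample(ks) else ks
  }
  tree_bond <- rep(FALSE, max(nb, 1L))
  visit_order <- integer(0)
  visited1 <- rep(FALSE, n)
  children <- vector("list", n)
  dfs1 <- function(at) {
    visited1[at] <<- TRUE
    visit_order <<- c(visit_order, at)
    ks <- order_children(adj[[at]])
    for (k in ks) {
      oth <- other_end(k, at)
      if (!visited1[oth]) {
        tree_bond[k] <<- TRUE
        children[[at]] <<- c(children[[at]], list(list(bond = k, atom = oth)))
        dfs1(oth)
      }
    }
  }
  dfs1(start)
  if (!all(visited1)) stop("disconnected molecular graph", call. = FALSE)
  back_edges <- if (nb > 0L) which(!tree_bond[seq_len(nb)]) else integer(0)
  next_digit <- 1L
  open_at <- vector("list", n)
  close_at <- vector("list", n)
  pos <- match(seq_len(n), visit_order)
  for (k in back_edges) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    first <- if (pos[a] <= pos[b]) a else b
    second <- if (pos[a] <= pos[b]) b else a
    d <- next_digit; next_digit <- next_digit + 1L
    dtxt <- if (d < 10L) as.character(d) else paste0("%", sprintf("%02d", d))
    open_at[[first]] <- c(open_at[[first]], list(list(txt = paste0(bond_char(k), dtxt))))
    close_at[[second]] <- c(close_at[[second]], list(list(txt = dtxt)))
  }
  # phase 2: emit
  emit2 <- function(at, via_bond) {
    if (!is.null(via_bond)) emit(bond_char(via_bond))
    emit(atom_token(at))
    for (x in open_at[[at]]) emit(x$txt)
    for (x in close_at[[at]]) emit(x$txt)
    kids <- children[[at]]
    nk <- length(kids)
    for (j in seq_along(kids)) {
      last <- (j == nk)
      if (!last) emit("(")
      emit2(kids[[j]]$atom, kids[[j]]$bond)
      if (!last) emit(")")
    }
  }
  emit2(start, NULL)
  paste(out, collapse = "")
}

#' @keywords internal
heavy_atom_count <- function(mol) mol$n

# elemental composition including implicit hydrogens, as a named count vector
.atom_counts <- function(mol) {
  counts <- table(mol$symbol)
  out <- as.integer(counts); names(out) <- names(counts)
  nh <- sum(mol$h)
  if (nh > 0) out["H"] <- (if (is.na(out["H"])) 0L else out["H"]) + nh
  out[!is.na(out)]
}

#' Hill-notation molecular formula of a molecular graph
#' @keywords internal
mol_formula <- function(mol) {
  cnt <- .atom_counts(mol)
  els <- names(cnt)
  if ("C" %in% els) {
    first <- c("C", if ("H" %in% els) "H")
    rest <- sort(setdiff(els, first))
    ord <- c(first, rest)
  } else {
    ord <- sort(els)
  }
  paste0(vapply(ord, function(e) {
    k <- cnt[[e]]
    if (k == 1L) e else paste0(e, k)
  }, character(1)), collapse = "")
}

#' Monoisotopic mass (Da) of a molecular graph
#' @keywords internal
mol_mono_mass <- function(mol) {
  cnt <- .atom_counts(mol)
  unknown <- setdiff(names(cnt), names(.MONO_MASS))
  if (length(unknown) > 0L)
    stop("no monoisotopic mass for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sum(.MONO_MASS[names(cnt)] * as.numeric(cnt))
}
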