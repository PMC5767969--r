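# chem_mol: a small molecular-graph toolkit sufficient for cyclodipeptide
# chemistry: a SMILES subset parser, implicit-hydrogen bookkeeping, a
# Morgan/CANGEN-style canonical SMILES writer, and an ECFP-style circular
# fingerprint.  No cheminformatics dependency is available in this R
# stack, so these primitives are implemented here; structures are emitted
# without stereo descriptors (the circular fingerprints used for scoring
# are stereo-insensitive, and stereo markers in input SMILES are accepted
# and discarded).

# A molecule is a list:
#   atoms: data.frame(el, charge, arom, nH, role)
#   bonds: data.frame(a, b, order)  order: 1, 2, 3, or 1.5 (aromatic)
# `role` is free-text provenance used by the tailoring transforms
# ("ringN", "carbonylC", "carbonylO", "alphaC", "betaC", "sidechain", ...).

mol_new <- function() {
  list(atoms = data.frame(el = character(), charge = integer(),
                          arom = logical(), nH = integer(),
                          role = character(), stringsAsFactors = FALSE),
       bonds = data.frame(a = integer(), b = integer(), order = numeric()))
}

mol_add_atom <- function(mol, el, charge = 0L, arom = FALSE, nH = NA,
                         role = "") {
  mol$atoms <- rbind(mol$atoms,
                     data.frame(el = el, charge = as.integer(charge),
                                arom = arom, nH = as.integer(nH),
                                role = role, stringsAsFactors = FALSE))
  mol
}

mol_add_bond <- function(mol, a, b, order = 1) {
  mol$bonds <- rbind(mol$bonds, data.frame(a = a, b = b, order = order))
  mol
}

# default valences for implicit-H assignment (organic subset we need)
VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3)

mol_degree_sum <- function(mol, i) {
  bo <- mol$bonds[mol$bonds$a == i | mol$bonds$b == i, "order"]
  # each aromatic bond counts 1.5; an aromatic atom's pi contribution is
  # handled by rounding the total down after summation (two aromatic bonds
  # -> 3, three -> 4), the usual bookkeeping trick
  floor(sum(bo) + 1e-9)
}

# fill nH for atoms where it is NA, from standard valence + charge
mol_assign_h <- function(mol) {
  for (i in seq_len(nrow(mol$atoms))) {
    if (!is.na(mol$atoms$nH[i])) next
    el <- mol$atoms$el[i]
    v <- VALENCE[[el]]
    if (is.null(v)) stopf("no default valence for element %s", el)
    chg <- mol$atoms$charge[i]
    # cation N/P gains a bonding slot; any other charge removes one
    if (chg > 0 && el %in% c("N", "P")) v <- v + chg
    else if (chg != 0) v <- v - abs(chg)
    used <- mol_degree_sum(mol, i)
    mol$atoms$nH[i] <- max(0L, as.integer(v - used))
  }
  mol
}

mol_neighbors <- function(mol, i) {
  c(mol$bonds$b[mol$bonds$a == i], mol$bonds$a[mol$bonds$b == i])
}

mol_bond_order <- function(mol, i, j) {
  hit <- (mol$bonds$a == i & mol$bonds$b == j) |
         (mol$bonds$a == j & mol$bonds$b == i)
  mol$bonds$order[hit][1L]
}

mol_set_bond_order <- function(mol, i, j, order) {
  hit <- (mol$bonds$a == i & mol$bonds$b == j) |
         (mol$bonds$a == j & mol$bonds$b == i)
  mol$bonds$order[hit] <- order
  mol
}

# ---- SMILES parsing (subset) ----------------------------------------------

#' Parse a SMILES string into the internal molecular graph
#'
#' Supported subset: organic-subset atoms C N O S P (aromatic c n o s),
#' bracket atoms with charge/explicit H (e.g. `[nH]`, `[N+]`, `[O-]`),
#' bonds `- = #`, branches, ring-closure digits and `%nn`.  Tetrahedral
#' stereo markers (`@`, `@@`, `/`, `\`) are accepted and discarded.
#'
#' @param smiles SMILES string
#' @return a molecule object
#' @keywords internal
parse_smiles <- function(smiles) {
  mol <- mol_new()
  n <- nchar(smiles)
  i <- 1L
  prev <- NA_integer_
  pending_order <- NA_real_
  stack <- integer()
  ring <- list()
  new_atom <- function(el, arom, charge = 0L, nH = NA) {
    mol <<- mol_add_atom(mol, el, charge, arom, nH)
    idx <- nrow(mol$atoms)
    if (!is.na(prev)) {
      o <- if (!is.na(pending_order)) pending_order
           else if (arom && mol$atoms$arom[prev]) 1.5 else 1
      mol <<- mol_add_bond(mol, prev, idx, o)
    }
    prev <<- idx
    pending_order <<- NA_real_
    idx
  }
  while (i <= n) {
    ch <- substr(smiles, i, i)
    if (ch %in% c("C", "N", "O", "S", "P")) {
      new_atom(ch, FALSE); i <- i + 1L
    } else if (ch %in% c("c", "n", "o", "s")) {
      new_atom(toupper(ch), TRUE); i <- i + 1L
    } else if (ch == "[") {
      j <- regexpr("]", substr(smiles, i, n), fixed = TRUE)
      if (j < 0) stopf("unterminated bracket atom in SMILES")
      tok <- substr(smiles, i + 1L, i + j - 2L)
      m <- regmatches(tok, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]?))?([+-][0-9]?)?$", tok))[[1]]
      if (!length(m)) stopf("unsupported bracket atom [%s]", tok)
      sym <- m[3L]
      arom <- sym == tolower(sym)
      el <- toupper(substr(sym, 1L, 1L))
      if (nchar(sym) > 1L) el <- paste0(el, substr(sym, 2L, 2L))
      nH <- if (nzchar(m[5L])) { if (nzchar(m[6L])) as.integer(m[6L]) else 1L }
            else 0L
      chg <- 0L
      if (nzchar(m[7L])) {
        sgn <- if (substr(m[7L], 1L, 1L) == "+") 1L else -1L
        mag <- if (nchar(m[7L]) > 1L) as.integer(substr(m[7L], 2L, 2L)) else 1L
        chg <- sgn * mag
      }
      new_atom(el, arom, chg, nH)
      i <- i + j
    } else if (ch %in% c("-", "=", "#")) {
      pending_order <- c(`-` = 1, `=` = 2, `#` = 3)[[ch]]
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      i <- i + 1L                    # cis/trans markers discarded
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") { num <- substr(smiles, i + 1L, i + 2L); i <- i + 3L }
      else { num <- ch; i <- i + 1L }
      if (is.null(ring[[num]])) {
        ring[[num]] <- list(atom = prev, order = pending_order)
        pending_order <- NA_real_
      } else {
        o <- pending_order
        if (is.na(o)) o <- ring[[num]]$order
        if (is.na(o)) o <- if (mol$atoms$arom[prev] &&
                               mol$atoms$arom[ring[[num]]$atom]) 1.5 else 1
        mol <- mol_add_bond(mol, ring[[num]]$atom, prev, o)
        ring[num] <- list(NULL)
        pending_order <- NA_real_
      }
    } else if (ch == ".") {
      stopf("disconnected SMILES components are not supported")
    } else {
      stopf("unsupported SMILES character '%s'", ch)
    }
  }
  if (length(Filter(Negate(is.null), ring)))
    stopf("unclosed ring bond in SMILES")
  if (!nrow(mol$atoms)) stopf("empty SMILES")
  mol$atoms$role <- ""
  mol_assign_h(mol)
}

# ---- canonical ranking and SMILES output ----------------------------------

# CANGEN-style canonical ranks: refine initial invariants by iterated
# neighbourhood hashing; break residual ties deterministically.
canon_ranks <- function(mol) {
  natom <- nrow(mol$atoms)
  nbs <- lapply(seq_len(natom), function(i) mol_neighbors(mol, i))
  ords <- lapply(seq_len(natom), function(i)
    vapply(nbs[[i]], function(j) mol_bond_order(mol, i, j), 0))
  inv <- paste(mol$atoms$el, mol$atoms$charge, mol$atoms$arom,
               mol$atoms$nH, lengths(nbs),
               vapply(seq_len(natom), function(i) mol_degree_sum(mol, i), 0))
  rank <- match(inv, sort(unique(inv)))
  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(natom), function(i)
        paste(sprintf("%05d", rank[i]),
              paste(sort(paste0(ords[[i]], ":",
                                sprintf("%05d", rank[nbs[[i]]]))),
                    collapse = ",")), "")
      new_rank <- match(key, sort(unique(key)))
      # partition only ever refines; padded old-rank prefix keeps labels
      # stable, so equal class counts means a fixed point
      if (length(unique(new_rank)) == length(unique(rank))) return(new_rank)
      rank <- new_rank
    }
  }
  rank <- refine(rank)
  while (length(unique(rank)) < natom) {
    # break one tie: lowest-index atom in the lowest tied class
    tab <- table(rank)
    cls <- as.integer(names(tab)[tab > 1L])[1L]
    first <- which(rank == cls)[1L]
    rank <- rank * 2L
    rank[first] <- rank[first] - 1L
    rank <- refine(match(rank, sort(unique(rank))))
  }
  rank
}

atom_token <- function(mol, i) {
  el <- mol$atoms$el[i]
  arom <- mol$atoms$arom[i]
  chg <- mol$atoms$charge[i]
  nH <- mol$atoms$nH[i]
  sym <- if (arom) tolower(el) else el
  plain_ok <- chg == 0L && el %in% c("C", "N", "O", "S", "P")
  if (plain_ok) {
    # organic-subset shorthand legal only when implicit-H recomputation
    # would reproduce nH; aromatic N with an H must be bracketed
    v <- VALENCE[[el]]
    used <- mol_degree_sum(mol, i)
    implied <- max(0L, as.integer(v - used))
    if (implied == nH) return(sym)
  }
  h <- if (nH == 0L) "" else if (nH == 1L) "H" else paste0("H", nH)
  c_ <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
        else if (chg > 0) paste0("+", chg) else paste0("-", abs(chg))
  paste0("[", sym, h, c_, "]")
}

bond_token <- function(order, arom_pair = FALSE) {
  if (order == 2) "="
  else if (order == 3) "#"
  else if (order == 1 && arom_pair) "-"   # explicit single between aromatics
  else ""
}

#' Canonical SMILES of a molecule object
#' @param mol molecule
#' @return SMILES string; deterministic for a given molecular graph
#' @keywords internal
write_smiles <- function(mol) {
  natom <- nrow(mol$atoms)
  rank <- canon_ranks(mol)
  visited <- logical(natom)
  ring_no <- 0L
  ring_open <- list()   # key "i-j" -> digit
  ring_at <- replicate(natom, character(0), simplify = FALSE)
  # assign ring-closure digits via DFS spanning tree
  out <- character(0)
  # precompute neighbor order: canonical rank ascending
  nbs <- lapply(seq_len(natom), function(i) {
    nb <- mol_neighbors(mol, i)
    nb[order(rank[nb])]
  })
  edge_seen <- new.env(hash = TRUE)
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  # first pass: find ring-closure edges via DFS
  closure <- list()
  dfs1 <- function(i, from) {
    visited[i] <<- TRUE
    for (j in nbs[[i]]) {
      if (!is.na(from) && j == from && is.null(edge_seen[[ekey(i, j)]])) {
        edge_seen[[ekey(i, j)]] <- TRUE
        next
      }
      if (!is.null(edge_seen[[ekey(i, j)]])) next
      edge_seen[[ekey(i, j)]] <- TRUE
      if (visited[j]) {
        ring_no <<- ring_no + 1L
        d <- if (ring_no < 10L) as.character(ring_no)
             else paste0("%", ring_no)
        ring_at[[i]] <<- c(ring_at[[i]], d)
        ring_at[[j]] <<- c(ring_at[[j]], d)
        closure[[ekey(i, j)]] <<- d
      } else dfs1(j, i)
    }
  }
  root <- which.min(rank)
  dfs1(root, NA_integer_)
  # second pass: emit
  visited <- logical(natom)
  emit <- function(i, from) {
    visited[i] <<- TRUE
    tok <- atom_token(mol, i)
    # ring-closure digits with their bond order markers
    for (d in ring_at[[i]]) {
      # find partner edge for bond symbol
      partner <- NA_integer_
      for (key in names(closure)) if (identical(closure[[key]], d)) {
        ij <- as.integer(strsplit(key, " ")[[1]])
        if (i %in% ij) partner <- setdiff(ij, i)
      }
      b <- if (!is.na(partner))
        bond_token(mol_bond_order(mol, i, partner),
                   mol$atoms$arom[i] && mol$atoms$arom[partner])
      else ""
      tok <- paste0(tok, b, d)
    }
    kids <- Filter(function(j) !visited[j] &&
                     is.null(closure[[ekey(i, j)]]), nbs[[i]])
    if (!is.na(from)) kids <- setdiff(kids, from)
    parts <- character(0)
    for (z in seq_along(kids)) {
      j <- kids[z]
      if (visited[j]) next
      o <- mol_bond_order(mol, i, j)
      b <- bond_token(o, mol$atoms$arom[i] && mol$atoms$arom[j])
      sub <- emit(j, i)
      parts <- c(parts,
                 if (z < length(kids)) paste0("(", b, sub, ")")
                 else paste0(b, sub))
    }
    paste0(tok, paste(parts, collapse = ""))
  }
  emit(root, NA_integer_)
}

#' Canonicalize a SMILES string
#'
#' Parses with the internal subset parser and re-emits the canonical form;
#' idempotent.  Stereo markers are discarded.
#'
#' @param smiles SMILES string
#' @return canonical SMILES
#' @export
canonical_smiles <- function(smiles) {
  write_smiles(parse_smiles(smiles))
}

# ---- ECFP-style circular fingerprint --------------------------------------

# deterministic 32-bit mixing (xorshift-multiply, fixed constants;
# versioned: changing these changes every fingerprint)
hash_mix <- function(values) {
  h <- 2166136261 %% 2147483647
  for (v in values) {
    h <- bitwXor(as.integer(h), as.integer(abs(v) %% 2147483647))
    h <- (abs(h) * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' Circular substructure fingerprint (ECFP-style)
#'
#' Radius-3 (diameter 6) circular environments hashed to a fixed-width bit
#' set; collisions are accepted as in standard ECFP practice.  The hash is
#' pinned (fingerprint version 1): fingerprints are comparable only within
#' a version.
#'
#' @param smiles molecule as SMILES (or a parsed molecule object)
#' @param radius maximum environment radius (default 3 = ECFP6-equivalent)
#' @param nbits fold width (default 2048)
#' @return object of class `fingerprint`: sorted unique bit positions
#'   (0-based), with attributes `nbits` and `version`
#' @export
fingerprint <- function(smiles, radius = 3L, nbits = 2048L) {
  mol <- if (is.character(smiles)) parse_smiles(smiles) else smiles
  natom <- nrow(mol$atoms)
  ids <- vapply(seq_len(natom), function(i) {
    hash_mix(c(match(mol$atoms$el[i], names(VALENCE)),
               mol$atoms$charge[i] + 10L,
               as.integer(mol$atoms$arom[i]),
               mol$atoms$nH[i],
               length(mol_neighbors(mol, i))))
  }, 0L)
  all_ids <- ids
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(natom), function(i) {
      nb <- mol_neighbors(mol, i)
      ord <- vapply(nb, function(j) mol_bond_order(mol, i, j), 0)
      pairs <- sort(ord * 1e9 + ids[nb])
      hash_mix(c(r, ids[i], round(pairs)))
    }, 0L)
    all_ids <- c(all_ids, ids)
  }
  bits <- sort(unique(as.integer(abs(all_ids) %% nbits)))
  structure(bits, class = "fingerprint", nbits = nbits, version = 1L)
}

#' Tanimoto coefficient between two fingerprints
#'
#' @param fp_a,fp_b [fingerprint()] objects (or plain integer bit sets)
#' @return |A intersect B| / |A union B| in `[0, 1]`; two empty sets give 0
#'   with a warning
#' @export
tanimoto <- function(fp_a, fp_b) {
  a <- as.integer(fp_a); b <- as.integer(fp_b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}
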