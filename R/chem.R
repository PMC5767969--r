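# chem: predicted cyclodipeptide structures.  The 2,5-diketopiperazine
# (DKP) scaffold is assembled from the two predicted substrates; tailoring
# reactions implied by annotated cluster domains are applied as graph
# transforms, enumerating all placements when the reaction site is
# ambiguous ("combinatorial libraries"); libraries are scored against
# known structures by circular-fingerprint Tanimoto.

# side-chain SMILES fragments, attachment at the first atom (the beta
# carbon); proline is handled specially (its side chain closes onto the
# ring nitrogen)
SIDECHAIN <- c(
  A = "C",           R = "CCCNC(=N)N",  N = "CC(N)=O",   D = "CC(=O)O",
  C = "CS",          E = "CCC(=O)O",    Q = "CCC(N)=O",  G = "",
  H = "Cc1c[nH]cn1", I = "C(C)CC",      K = "CCCCN",     L = "CC(C)C",
  M = "CCSC",        F = "Cc1ccccc1",   P = "special",   S = "CO",
  T = "C(O)C",       V = "C(C)C",       W = "Cc1c[nH]c2ccccc12",
  Y = "Cc1ccc(O)cc1")

#' Build the 2,5-diketopiperazine scaffold for two amino-acid substrates
#'
#' Symmetric in its two arguments; stereo descriptors are not emitted (the
#' downstream fingerprints are stereo-insensitive).  Proline side chains
#' close correctly onto their ring nitrogen.
#'
#' @param aa1,aa2 one-letter amino-acid codes
#' @return canonical SMILES string
#' @export
build_dkp <- function(aa1, aa2) {
  mol <- build_dkp_mol(aa1, aa2)
  write_smiles(mol)
}

# internal: build the annotated molecule object.  Ring atom roles:
# ringN1/ringN2, carbonylC1/2, carbonylO1/2, alphaC1/2; side-chain roles
# carry the residue slot ("side1"/"side2"), beta carbons "betaC1"/"betaC2".
build_dkp_mol <- function(aa1, aa2) {
  for (aa in c(aa1, aa2)) if (!aa %in% AA20) stopf("unknown residue '%s'", aa)
  # canonical argument order makes build_dkp symmetric by construction
  if (match(aa1, AA20) > match(aa2, AA20)) { t <- aa1; aa1 <- aa2; aa2 <- t }
  smi1 <- residue_run(aa1, "7")
  smi2 <- residue_run(aa2, "8")
  smiles <- paste0("O=C9", smi2, "C(=O)", smi1, "9")
  mol <- parse_smiles(smiles)
  annotate_dkp_roles(mol, aa1, aa2)
}

# "C(alpha)(side chain)N(ring)" run for one residue; pro_digit closes the
# pyrrolidine
residue_run <- function(aa, pro_digit) {
  if (aa == "P") paste0("C", pro_digit, "CCCN", pro_digit)
  else if (aa == "G") "CN"
  else paste0("C(", SIDECHAIN[[aa]], ")N")
}

# role annotation by re-walking the constructed SMILES: the parser adds
# atoms in string order, so positions are known by construction
annotate_dkp_roles <- function(mol, aa1, aa2) {
  # atom order for "O=C9 <run2> C(=O) <run1> 9":
  #   1 carbonylO(2-side), 2 carbonylC(2-side), then run2 atoms,
  #   then carbonylC(1-side), its O, then run1 atoms
  n_side <- function(aa) {
    if (aa == "G") 0L
    else if (aa == "P") 3L
    else nrow(parse_smiles(SIDECHAIN[[aa]])$atoms)
  }
  role <- character(nrow(mol$atoms))
  i <- 1L
  role[i] <- "carbonylO2"; i <- i + 1L
  role[i] <- "carbonylC2"; i <- i + 1L
  role[i] <- "alphaC2"; i <- i + 1L
  k2 <- n_side(aa2)
  if (k2 > 0L) {
    role[i] <- "betaC2"
    if (k2 > 1L) role[(i + 1L):(i + k2 - 1L)] <- "side2"
    i <- i + k2
  }
  role[i] <- "ringN2"; i <- i + 1L
  role[i] <- "carbonylC1"; i <- i + 1L
  role[i] <- "carbonylO1"; i <- i + 1L
  role[i] <- "alphaC1"; i <- i + 1L
  k1 <- n_side(aa1)
  if (k1 > 0L) {
    role[i] <- "betaC1"
    if (k1 > 1L) role[(i + 1L):(i + k1 - 1L)] <- "side1"
    i <- i + k1
  }
  role[i] <- "ringN1"
  mol$atoms$role <- role
  mol$residues <- c(aa1, aa2)
  mol
}

role_idx <- function(mol, role) which(mol$atoms$role == role)

# ---- tailoring reactions --------------------------------------------------

#' The packaged cyclodipeptide tailoring reaction library
#'
#' Six experimentally characterized tailoring activities, each keyed to
#' the cluster domain that licenses it.  Transform semantics are the
#' package's curation (the regiochemistry of the methyltransferases in
#' particular is curator-editable):
#' * `CYP121` — intramolecular aryl-aryl C-C coupling (mycocyclosin-type);
#'   requires two aromatic side chains.
#' * `CDO_NOX` — pulcherriminic-type N-oxygenase: N-oxide at both ring
#'   nitrogens.
#' * `AlbA` — alpha,beta-dehydrogenation at one or both residues
#'   (albonoursin-type); ambiguous site, combinatorial.
#' * `Ndas_1149` — O-methylation of an available hydroxyl.
#' * `Amir_4628` — ring N-methylation (either or both NH).
#' * `Ndas_1145` — amide O- and N-methylation (lactim ether at one amide
#'   plus N-methyl at the other nitrogen).
#' @return named list of reaction definitions
#' @export
tailoring_reactions <- function() {
  list(
    AlbA = list(required_domain = "AlbA", site_ambiguous = TRUE,
                fn = rxn_dehydrogenate),
    CYP121 = list(required_domain = "CYP121", site_ambiguous = FALSE,
                  fn = rxn_aryl_couple),
    CDO_NOX = list(required_domain = "CDO_NOX", site_ambiguous = FALSE,
                   fn = rxn_n_oxygenate),
    Amir_4628 = list(required_domain = "Amir_4628", site_ambiguous = TRUE,
                     fn = rxn_ring_n_methylate),
    Ndas_1145 = list(required_domain = "Ndas_1145", site_ambiguous = TRUE,
                     fn = rxn_amide_on_methylate),
    Ndas_1149 = list(required_domain = "Ndas_1149", site_ambiguous = TRUE,
                     fn = rxn_o_methylate)
  )
}

# each rxn_* returns a (possibly empty) list of product molecules;
# empty = not applicable to this substrate

# alpha,beta dehydrogenation: C(alpha)-C(beta) single bond becomes double
rxn_dehydrogenate <- function(mol) {
  sites <- list()
  for (r in 1:2) {
    a <- role_idx(mol, paste0("alphaC", r))
    b <- role_idx(mol, paste0("betaC", r))
    if (!length(a) || !length(b)) next
    if (mol$residues[r] == "P") next                 # ring strain: skip
    if (mol$atoms$nH[a] < 1L || mol$atoms$nH[b] < 1L) next
    if (mol_bond_order(mol, a, b) != 1) next
    sites[[length(sites) + 1L]] <- c(a, b)
  }
  if (!length(sites)) return(list())
  apply_site <- function(m, s) {
    m <- mol_set_bond_order(m, s[1L], s[2L], 2)
    m$atoms$nH[s] <- m$atoms$nH[s] - 1L
    m
  }
  out <- lapply(sites, function(s) apply_site(mol, s))
  if (length(sites) == 2L)
    out <- c(out, list(apply_site(apply_site(mol, sites[[1]]), sites[[2]])))
  out
}

# aryl-aryl C-C coupling between the two aromatic side chains; the coupled
# carbon on each ring is, deterministically, an aromatic CH adjacent to a
# substituted ring atom (for tyrosine this is the position ortho to the
# hydroxyl, the mycocyclosin regiochemistry)
rxn_aryl_couple <- function(mol) {
  pick <- function(r) {
    side <- c(role_idx(mol, paste0("betaC", r)),
              role_idx(mol, paste0("side", r)))
    ar <- side[mol$atoms$arom[side]]
    ch <- ar[mol$atoms$nH[ar] >= 1L & mol$atoms$el[ar] == "C"]
    if (!length(ch)) return(NA_integer_)
    # prefer a CH ortho to an oxygen-substituted ring atom (tyrosine:
    # ortho to the phenol OH, the mycocyclosin regiochemistry), then any
    # CH ortho to a substituted ring atom other than the attachment
    has_o_sub <- function(j) any(mol$atoms$el[mol_neighbors(mol, j)] == "O")
    score_o <- vapply(ch, function(i) {
      nb <- mol_neighbors(mol, i)
      any(mol$atoms$arom[nb] & mol$atoms$nH[nb] == 0L &
            vapply(nb, has_o_sub, TRUE))
    }, TRUE)
    score_s <- vapply(ch, function(i) {
      nb <- mol_neighbors(mol, i)
      sub <- nb[mol$atoms$arom[nb] & mol$atoms$nH[nb] == 0L]
      any(!vapply(sub, function(j)
        any(mol_neighbors(mol, j) %in%
              role_idx(mol, paste0("betaC", r))), TRUE))
    }, TRUE)
    cand <- if (any(score_o)) ch[score_o]
            else if (any(score_s)) ch[score_s] else ch
    cand[which.min(canon_ranks(mol)[cand])]
  }
  c1 <- pick(1L); c2 <- pick(2L)
  if (is.na(c1) || is.na(c2)) return(list())
  m <- mol_add_bond(mol, c1, c2, 1)
  m$atoms$nH[c(c1, c2)] <- m$atoms$nH[c(c1, c2)] - 1L
  list(m)
}

# pulcherriminic-type N-oxygenase: N-oxide at both ring nitrogens
rxn_n_oxygenate <- function(mol) {
  ns <- c(role_idx(mol, "ringN1"), role_idx(mol, "ringN2"))
  if (length(ns) != 2L || any(mol$atoms$charge[ns] != 0L)) return(list())
  m <- mol
  for (nn in ns) {
    m$atoms$charge[nn] <- 1L
    if (m$atoms$nH[nn] > 0L) m$atoms$nH[nn] <- m$atoms$nH[nn] - 1L
    m <- mol_add_atom(m, "O", charge = -1L, arom = FALSE, nH = 0L,
                      role = "noxide")
    m <- mol_add_bond(m, nn, nrow(m$atoms), 1)
  }
  list(m)
}

# ring N-methylation: either NH, or both
rxn_ring_n_methylate <- function(mol) {
  ns <- c(role_idx(mol, "ringN1"), role_idx(mol, "ringN2"))
  ns <- ns[mol$atoms$nH[ns] >= 1L & mol$atoms$charge[ns] == 0L]
  if (!length(ns)) return(list())
  methylate <- function(m, nn) {
    m$atoms$nH[nn] <- m$atoms$nH[nn] - 1L
    m <- mol_add_atom(m, "C", nH = 3L, role = "nmethyl")
    mol_add_bond(m, nn, nrow(m$atoms), 1)
  }
  out <- lapply(ns, function(nn) methylate(mol, nn))
  if (length(ns) == 2L)
    out <- c(out, list(methylate(methylate(mol, ns[1L]), ns[2L])))
  out
}

# O-methylation of an available hydroxyl (Ser/Thr/Tyr OH, carboxyl OH)
rxn_o_methylate <- function(mol) {
  os <- which(mol$atoms$el == "O" & mol$atoms$nH == 1L &
                mol$atoms$charge == 0L)
  if (!length(os)) return(list())
  lapply(os, function(oo) {
    m <- mol
    m$atoms$nH[oo] <- 0L
    m <- mol_add_atom(m, "C", nH = 3L, role = "omethyl")
    mol_add_bond(m, oo, nrow(m$atoms), 1)
  })
}

# amide O- and N-methylation: one amide becomes its lactim methyl ether
# (C(OMe)=N, nitrogen loses H), the opposite ring nitrogen is N-methylated
rxn_amide_on_methylate <- function(mol) {
  out <- list()
  for (r in 1:2) {
    other <- 3L - r
    cc <- role_idx(mol, paste0("carbonylC", r))
    oo <- role_idx(mol, paste0("carbonylO", r))
    # the ring N double-bonded partner of this carbonyl: the N of the
    # *other* residue unit (amide C(r)=O bonds N(other))
    nn <- role_idx(mol, paste0("ringN", other))
    nme <- role_idx(mol, paste0("ringN", r))
    if (!length(cc) || !length(oo) || !length(nn) || !length(nme)) next
    if (mol$atoms$nH[nn] < 1L || mol$atoms$nH[nme] < 1L) next
    m <- mol
    m <- mol_set_bond_order(m, cc, oo, 1)
    m$atoms$nH[oo] <- 0L
    m <- mol_add_atom(m, "C", nH = 3L, role = "omethyl")
    m <- mol_add_bond(m, oo, nrow(m$atoms), 1)
    m <- mol_set_bond_order(m, cc, nn, 2)
    m$atoms$nH[nn] <- m$atoms$nH[nn] - 1L
    m$atoms$nH[nme] <- m$atoms$nH[nme] - 1L
    m <- mol_add_atom(m, "C", nH = 3L, role = "nmethyl")
    m <- mol_add_bond(m, nme, nrow(m$atoms), 1)
    out[[length(out) + 1L]] <- m
  }
  out
}

# ---- library construction and scoring -------------------------------------

#' Apply tailoring reactions and build the predicted compound library
#'
#' Starting from the untailored scaffold, every reaction whose licensing
#' domain is present is applied to every structure reached so far;
#' ambiguous sites enumerate all placements.  The untailored scaffold is
#' always retained.  The library is deduplicated on canonical SMILES,
#' ordered lexicographically, and capped.
#'
#' @param aa1,aa2 predicted substrates (one-letter codes)
#' @param domains character vector of annotated domain names (e.g.
#'   `c("AlbA", "CYP121")`)
#' @param reactions reaction library, default [tailoring_reactions()]
#' @param cap maximum library size (default 64)
#' @return object of class `compound_library`: data.frame with `smiles`
#'   and `provenance` (comma-separated reactions applied)
#' @export
apply_tailoring <- function(aa1, aa2, domains = character(),
                            reactions = tailoring_reactions(),
                            cap = 64L) {
  scaffold <- build_dkp_mol(aa1, aa2)
  pool <- list(list(mol = scaffold, prov = character()))
  active <- reactions[vapply(reactions, function(r)
    r$required_domain %in% domains, TRUE)]
  for (rn in names(active)) {
    new <- list()
    for (entry in pool) {
      prods <- tryCatch(active[[rn]]$fn(entry$mol),
                        error = function(e) {
                          warning(sprintf("%s transform failed: %s", rn,
                                          conditionMessage(e)))
                          list()
                        })
      for (pm in prods)
        new[[length(new) + 1L]] <- list(mol = pm,
                                        prov = c(entry$prov, rn))
    }
    pool <- c(pool, new)
    if (length(pool) > 4L * cap) pool <- pool[seq_len(4L * cap)]
  }
  smi <- vapply(pool, function(e) write_smiles(e$mol), "")
  prov <- vapply(pool, function(e) paste(e$prov, collapse = ","), "")
  keep <- !duplicated(smi)
  df <- data.frame(smiles = smi[keep], provenance = prov[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(df$smiles), , drop = FALSE]
  if (nrow(df) > cap) df <- df[seq_len(cap), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("compound_library", "data.frame"))
}

#' Score a predicted compound library against a known structure
#'
#' Tanimoto similarity (circular fingerprints, [fingerprint()]) of the
#' truth against every library member; the median (mean of middle pair for
#' even counts) and maximum are reported.
#'
#' @param library a `compound_library` (or character vector of SMILES)
#' @param truth_smiles known product structure
#' @return list with `median_tanimoto`, `max_tanimoto`, `tanimotos`
#' @export
score_prediction <- function(library, truth_smiles) {
  smi <- if (is.data.frame(library)) library$smiles else as.character(library)
  if (!length(smi)) stopf("empty compound library")
  ft <- fingerprint(truth_smiles)
  tans <- vapply(smi, function(s) tanimoto(fingerprint(s), ft), 0)
  list(median_tanimoto = stats::median(tans),
       max_tanimoto = max(tans),
       tanimotos = tans)
}

#' Average of per-cluster median Tanimoto scores
#'
#' The batch aggregate used to summarize structure-prediction accuracy
#' over a panel of known cluster-compound pairs.
#'
#' @param medians numeric vector of per-cluster median Tanimoto values
#' @return their mean
#' @export
average_median_tanimoto <- function(medians) mean(medians)
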