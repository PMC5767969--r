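# Independent oracles.  The Viterbi oracle enumerates every path in the
# documented architecture recursively; the naive Bayes oracle applies
# Bayes' rule with plain arithmetic; the cheminformatics oracle shells
# out to the pre-installed Python rdkit.

oracle_viterbi <- function(hmm, protein) {
  k <- hmm$n_states
  aa <- strsplit(protein, "")[[1]]
  L <- length(aa)
  idx <- match(aa, AA20)
  lo <- function(s, p) if (is.na(idx[p])) 0 else unname(hmm$match_lo[s, idx[p]])
  t <- hmm$tr_l2
  best <- -Inf
  rec_M <- function(p, s, acc) {
    if (acc == -Inf) return()
    if (acc > best) best <<- acc            # free exit after any match
    if (p < L) {
      if (s < k) rec_M(p + 1L, s + 1L, acc + t$mm[s] + lo(s + 1L, p + 1L))
      rec_I(p + 1L, s, acc + t$mi[s])
    }
    if (s < k) rec_D(p, s + 1L, acc + t$md[s])
  }
  rec_I <- function(p, s, acc) {
    if (acc == -Inf) return()
    if (p < L) {
      if (s < k) rec_M(p + 1L, s + 1L, acc + t$im[s] + lo(s + 1L, p + 1L))
      rec_I(p + 1L, s, acc + t$ii[s])
    }
    if (s < k) rec_D(p, s + 1L, acc + t$id[s])
  }
  rec_D <- function(p, s, acc) {
    if (acc == -Inf) return()
    if (p < L && s < k) rec_M(p + 1L, s + 1L, acc + t$dm[s] + lo(s + 1L, p + 1L))
    if (s < k) rec_D(p, s + 1L, acc + t$dd[s])
  }
  for (p0 in seq_len(L)) for (s0 in seq_len(k))
    rec_M(p0, s0, -log2(k) + lo(s0, p0))
  best
}

oracle_nb_posterior <- function(model, vector) {
  cat_idx <- match(vector, c(AA20, "-"))
  num <- vapply(model$classes, function(cl) {
    p <- model$priors[[cl]]
    for (pos in seq_along(vector))
      p <- p * model$likelihoods[pos, cl, cat_idx[pos]]
    p
  }, 0)
  num / sum(num)
}

# canonicalize via Python rdkit (pre-installed in this stack); returns NA
# if the interpreter is somehow unusable, in which case callers fall back
# to frozen expectations
rdkit_canonical <- function(smiles) {
  script <- sprintf(
    "import sys\nfrom rdkit import Chem\nprint(Chem.CanonSmiles(%s))",
    deparse(smiles))
  out <- tryCatch(
    system2("python", "-", input = script, stdout = TRUE, stderr = FALSE),
    error = function(e) NA_character_)
  if (length(out) != 1L || !nzchar(out)) NA_character_ else out
}
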