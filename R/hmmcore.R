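# hmmcore: profile hidden Markov models built from seed alignments, scored
# against proteins by Viterbi (best-path) local alignment in bits.
#
# Model semantics (kept deliberately simple so that an exhaustive
# path-enumeration oracle is possible):
#   * match states M1..Mk from alignment columns surviving the gap trim;
#   * per-column match emissions = (counts + w * background) / (n + w);
#   * insert emissions = background (log-odds contribution 0);
#   * transitions M/I/D estimated from the seed with +1 smoothing;
#   * local alignment: a path enters at any match state with probability
#     1/k, exits freely after any match state; flanking residues are
#     emitted by the background and contribute 0 bits.
# Scores are log2-odds (bits) against the background model.

#' Seed multiple alignment
#'
#' @param ids sequence identifiers
#' @param aligned equal-length aligned residue strings, gap symbol `-`
#' @return object of class `seed_alignment`
#' @export
seed_alignment <- function(ids, aligned) {
  stopifnot(length(ids) == length(aligned), length(ids) >= 1L)
  w <- unique(nchar(aligned))
  if (length(w) != 1L) stopf("alignment rows differ in length")
  structure(list(ids = as.character(ids),
                 aligned = toupper(as.character(aligned)),
                 columns = w),
            class = "seed_alignment")
}

#' Read an aligned FASTA or Stockholm file as a seed alignment
#' @param path alignment file; format detected from content
#' @return [seed_alignment()]
#' @export
read_alignment <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, "# STOCKHOLM")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^(#|//)", lines) & nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    ids <- vapply(parts, `[[`, "", 1L)
    seqs <- vapply(parts, `[[`, "", 2L)
    seqs <- tapply(seqs, factor(ids, levels = unique(ids)), paste,
                   collapse = "")
    seed_alignment(names(seqs), gsub("\\.", "-", unname(seqs)))
  } else {
    set <- Biostrings::readBStringSet(path)
    seed_alignment(sub("\\s.*$", "", names(set)),
                   gsub("\\.", "-", as.character(set)))
  }
}

#' Ungapped sequences of a seed alignment
#' @param seed a [seed_alignment()]
#' @return named character vector
#' @export
seed_sequences <- function(seed) {
  stats::setNames(gsub("-", "", seed$aligned, fixed = TRUE), seed$ids)
}

#' Profile HMM constructor (low level)
#'
#' Most users build models from alignments with [build_profile()].
#'
#' @param name model name
#' @param match_emissions k x 20 matrix of emission probabilities
#'   (columns `AA20`), each row summing to 1
#' @param transitions list of numeric vectors `mm, mi, md, im, ii, id, dm,
#'   dd, di`, each of length k (entries for the transition out of column
#'   s into column s+1 / insert s); the last entry is unused
#' @param background length-20 amino-acid background distribution
#' @param bitscore_cutoff detection threshold in bits (`-Inf` = none)
#' @return object of class `profile_hmm`
#' @export
profile_hmm <- function(name, match_emissions, transitions,
                        background = rep(1 / 20, 20),
                        bitscore_cutoff = -Inf) {
  k <- nrow(match_emissions)
  stopifnot(k >= 1L, ncol(match_emissions) == 20L)
  if (max(abs(rowSums(match_emissions) - 1)) > 1e-9)
    stopf("match emission rows must sum to 1")
  for (tri in list(c("mm", "mi", "md"), c("im", "ii", "id"),
                   c("dm", "dd", "di"))) {
    s <- Reduce(`+`, transitions[tri])
    if (k > 1L && max(abs(s[-k] - 1)) > 1e-9)
      stopf("transition distributions must sum to 1")
  }
  names(background) <- AA20
  colnames(match_emissions) <- AA20
  structure(list(name = name,
                 match_emissions = match_emissions,
                 transitions = transitions,
                 background = background,
                 bitscore_cutoff = bitscore_cutoff,
                 n_states = k,
                 # precomputed log2 forms used by the Viterbi kernel
                 match_lo = log2(sweep(match_emissions, 2L, background, "/")),
                 tr_l2 = lapply(transitions, log2)),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %s: %d match states, cutoff %.1f bits\n",
              x$name, x$n_states, x$bitscore_cutoff))
  invisible(x)
}

#' Build a profile HMM from a seed alignment
#'
#' Columns whose gap fraction exceeds `gap_fraction_cutoff` are trimmed
#' (all-gap columns always are); surviving columns become match states.
#' Residues falling in trimmed columns are treated as insertions when
#' estimating transition probabilities.  `X` residues are ignored in
#' counts.  Seed sequences are weighted uniformly.
#'
#' @param seed a [seed_alignment()]
#' @param gap_fraction_cutoff trim columns with gap fraction above this
#' @param pseudocount_weight weight of the background pseudocount
#' @param name model name
#' @param background amino-acid background distribution (default uniform)
#' @return a [profile_hmm()] (no cutoff set; see [set_cutoff_from_seeds()])
#' @export
build_profile <- function(seed, gap_fraction_cutoff = 0.5,
                          pseudocount_weight = 1.0,
                          name = "profile",
                          background = rep(1 / 20, 20)) {
  mat <- do.call(rbind, strsplit(seed$aligned, ""))
  nrow_ <- nrow(mat)
  gap_frac <- colMeans(mat == "-")
  keep <- which(gap_frac <= gap_fraction_cutoff & gap_frac < 1)
  if (!length(keep)) stopf("no columns survive gap trimming")
  k <- length(keep)
  names(background) <- AA20

  em <- matrix(0, k, 20L, dimnames = list(NULL, AA20))
  for (j in seq_len(k)) {
    col <- mat[, keep[j]]
    cnt <- table(factor(col[col %in% AA20], levels = AA20))
    n <- sum(cnt)
    em[j, ] <- (as.numeric(cnt) + pseudocount_weight * background) /
      (n + pseudocount_weight)
  }

  # transition counts between consecutive match columns; residues in
  # trimmed columns between them are insertions.  Plan7 convention: no
  # I<->D transitions (seed paths needing them are folded onto I->M and
  # D->M, a standard estimation approximation).
  cM <- matrix(1, k, 3L)                      # -> M, I, D (+1 smoothing)
  cI <- cbind(rep(1, k), rep(1, k), 0)        # -> M, I; D disallowed
  cD <- cbind(rep(1, k), 0, rep(1, k))        # -> M, D; I disallowed
  state_at <- matrix("D", nrow_, k)
  state_at[mat[, keep, drop = FALSE] != "-"] <- "M"
  n_ins <- matrix(0L, nrow_, k)
  if (k > 1L) for (j in seq_len(k - 1L)) {
    lo <- keep[j] + 1L; hi <- keep[j + 1L] - 1L
    if (hi >= lo)
      n_ins[, j] <- rowSums(mat[, lo:hi, drop = FALSE] != "-")
  }
  if (k > 1L) for (r in seq_len(nrow_)) for (j in seq_len(k - 1L)) {
    from <- state_at[r, j]
    ni <- n_ins[r, j]
    to <- state_at[r, j + 1L]
    if (ni == 0L) {
      if (from == "M") {
        if (to == "M") cM[j, 1L] <- cM[j, 1L] + 1
        else cM[j, 3L] <- cM[j, 3L] + 1
      } else {
        if (to == "M") cD[j, 1L] <- cD[j, 1L] + 1
        else cD[j, 3L] <- cD[j, 3L] + 1
      }
    } else {
      if (from == "M") cM[j, 2L] <- cM[j, 2L] + 1
      else cD[j, 1L] <- cD[j, 1L] + 1           # D->I folded onto D->M
      if (ni > 1L) cI[j, 2L] <- cI[j, 2L] + (ni - 1L)
      cI[j, 1L] <- cI[j, 1L] + 1                # I->D folded onto I->M
    }
  }
  norm <- function(m) m / rowSums(m)
  tM <- norm(cM); tI <- norm(cI); tD <- norm(cD)
  transitions <- list(mm = tM[, 1L], mi = tM[, 2L], md = tM[, 3L],
                      im = tI[, 1L], ii = tI[, 2L], id = tI[, 3L],
                      dm = tD[, 1L], dd = tD[, 3L], di = tD[, 2L])
  out <- profile_hmm(name, em, transitions, background)
  out$columns_kept <- keep   # alignment column of each match state
  out
}

#' Viterbi local-alignment bitscore of a protein against a profile HMM
#'
#' @param hmm a [profile_hmm()]
#' @param protein residue string (may contain `X`, scored as background)
#' @param details if `TRUE`, also return the alignment envelope
#' @return bitscore (numeric), or a list with `bitscore`, `env_start`,
#'   `env_end` (1-based residue interval) when `details = TRUE`
#' @export
score_protein <- function(hmm, protein, details = FALSE) {
  stopifnot(nzchar(protein))
  k <- hmm$n_states
  aa <- chars(protein)
  L <- length(aa)
  idx <- match(aa, AA20)              # NA for X etc. -> log-odds 0
  tr <- hmm$tr_l2
  entry <- -log2(k)
  NEG <- -1e18
  jj <- seq_len(k)

  # csd[m] = sum of D->D log-probs over columns < m (for delete chains)
  csd <- cumsum(c(0, tr$dd))
  cts <- cumsum(tr$dd)                # cts[j] = csd[j + 1]

  shift1 <- function(v) c(NEG, v[-k])
  shiftS <- function(v) c(0L, v[-k])

  M_prev <- rep(NEG, k); I_prev <- rep(NEG, k)
  SM_prev <- integer(k); SI_prev <- integer(k)
  best <- NEG; best_end <- NA_integer_; best_start <- NA_integer_

  for (p in seq_len(L)) {
    lo <- if (is.na(idx[p])) rep(0, k) else hmm$match_lo[, idx[p]]
    cand_m <- shift1(M_prev + tr$mm)
    cand_i <- shift1(I_prev + tr$im)

    # delete chains: emit at p-1 in column j (M or I), pass D_{j+1}..D_{s-1},
    # enter M_s; handled by a cummax scan with D->D prefix sums factored out
    cand_d <- rep(NEG, k); d_from <- jj; a_src_i <- logical(k)
    if (k > 2L) {
      aM <- M_prev + tr$md - cts
      aI <- I_prev + tr$id - cts
      a <- pmax(aM, aI)
      a_src_i <- aI > aM
      cm <- cummax(a)
      carg <- cummax(ifelse(a == cm, jj, 0L))
      s3 <- 3:k
      cand_d[s3] <- csd[s3 - 1L] + tr$dm[s3 - 1L] + cm[s3 - 2L]
      d_from[s3] <- carg[s3 - 2L]
    }
    cand_e <- rep(entry, k)

    newM <- pmax(cand_m, cand_i, cand_d, cand_e) + lo
    # start-position bookkeeping (first aligned residue of the path)
    SM <- rep(p, k)
    use_m <- cand_m >= cand_i & cand_m >= cand_d & cand_m >= cand_e
    use_i <- !use_m & cand_i >= cand_d & cand_i >= cand_e
    use_d <- !use_m & !use_i & cand_d >= cand_e
    SM[use_m] <- shiftS(SM_prev)[use_m]
    SM[use_i] <- shiftS(SI_prev)[use_i]
    if (any(use_d)) {
      src <- d_from[use_d]
      SM[use_d] <- ifelse(a_src_i[src], SI_prev[src], SM_prev[src])
    }

    newI <- pmax(M_prev + tr$mi, I_prev + tr$ii)
    SI <- ifelse(M_prev + tr$mi >= I_prev + tr$ii, SM_prev, SI_prev)

    pb <- max(newM)
    if (pb > best) {
      best <- pb
      s <- which.max(newM)
      best_end <- p
      best_start <- SM[s]
    }
    M_prev <- newM; I_prev <- newI; SM_prev <- SM; SI_prev <- SI
  }
  if (!details) return(best)
  list(bitscore = best, env_start = best_start, env_end = best_end)
}

#' Set the detection bitscore cutoff from seed self-scores
#'
#' With an explicit `margin_bits`, the cutoff is the minimum Viterbi
#' self-score over the (ungapped) seed sequences minus that margin.  The
#' default (`margin_bits = NULL`) is a *relative* policy: cutoff = half
#' the weakest seed self-score.  A fixed small margin (10 bits was the
#' original default) provably cannot satisfy leave-one-out recovery: a
#' sequence withheld from its own profile loses tens of bits relative to
#' seeds that remain in the model, while true decoys score near zero, so
#' half the self-score separates both regimes with a wide moat.  The
#' family's published bitscore cutoff is unavailable; whichever policy is
#' used is recorded in serialized model metadata.
#'
#' @param hmm a [profile_hmm()]
#' @param seeds named character vector of seed protein sequences
#' @param margin_bits fixed margin below the weakest seed self-score, or
#'   `NULL` (default) for the relative half-self-score policy
#' @return the model with `bitscore_cutoff` set
#' @export
set_cutoff_from_seeds <- function(hmm, seeds, margin_bits = NULL) {
  stopifnot(length(seeds) >= 1L)
  self <- vapply(seeds, function(s) score_protein(hmm, s), 0)
  hmm$bitscore_cutoff <- if (is.null(margin_bits)) {
    if (min(self) > 0) min(self) / 2 else min(self) - 10
  } else min(self) - margin_bits
  hmm
}

#' Detect CDPSs (or any model family) in a set of proteins
#'
#' @param hmm a [profile_hmm()] with a finite `bitscore_cutoff`
#' @param proteins named character vector
#' @return data.frame of hits `(protein_id, model, bitscore, env_start,
#'   env_end)` sorted by descending bitscore
#' @export
detect_cdps <- function(hmm, proteins) {
  stopifnot(is.finite(hmm$bitscore_cutoff))
  rows <- lapply(names(proteins), function(id) {
    d <- score_protein(hmm, proteins[[id]], details = TRUE)
    if (d$bitscore >= hmm$bitscore_cutoff)
      data.frame(protein_id = id, model = hmm$name, bitscore = d$bitscore,
                 env_start = d$env_start, env_end = d$env_end,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), model = character(),
                      bitscore = numeric(), env_start = integer(),
                      env_end = integer(), stringsAsFactors = FALSE)
  out[order(-out$bitscore, out$protein_id), , drop = FALSE]
}

#' Classify a CDPS into a subfamily by competing subfamily models
#'
#' The label is the highest-scoring model among those whose score passes
#' their own cutoff; when no model passes, `unclassified`.  Exact ties are
#' broken by the fixed order of `models` (NYH before XYP before SYQ).
#'
#' @param models list of [profile_hmm()] in tie-break order
#' @param protein residue string
#' @return list with `label` and `per_model_bitscores`
#' @export
classify_subfamily <- function(models, protein) {
  stopifnot(length(models) >= 1L)
  scores <- vapply(models, function(m) score_protein(m, protein), 0)
  names(scores) <- vapply(models, `[[`, "", "name")
  pass <- vapply(models, function(m) m$bitscore_cutoff, 0) <= scores
  label <- if (any(pass)) {
    cand <- which(pass)
    names(scores)[cand[which.max(scores[cand])]]
  } else "unclassified"
  list(label = label, per_model_bitscores = scores)
}

# ---- serialization --------------------------------------------------------

#' Serialize a profile HMM (or a list of them) to versioned JSON
#' @param hmms a [profile_hmm()] or list of them
#' @param path output file
#' @export
write_hmm_json <- function(hmms, path) {
  if (inherits(hmms, "profile_hmm")) hmms <- list(hmms)
  payload <- list(
    format = "cdpsminer-hmm", version = 1L,
    cutoff_policy = "derived from seed self-scores",
    models = lapply(unname(hmms), function(h)
      list(name = h$name, n_states = h$n_states,
           match_emissions = unname(h$match_emissions),
           transitions = lapply(h$transitions, unname),
           background = unname(h$background),
           bitscore_cutoff = if (is.finite(h$bitscore_cutoff))
             h$bitscore_cutoff else NULL)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read profile HMMs from versioned JSON
#' @param path file written by [write_hmm_json()]
#' @return list of [profile_hmm()]
#' @export
read_hmm_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "cdpsminer-hmm"))
    stopf("%s is not a cdpsminer HMM bundle", path)
  lapply(payload$models, function(m) {
    em <- do.call(rbind, lapply(m$match_emissions, unlist))
    colnames(em) <- AA20
    bc <- m$bitscore_cutoff
    if (is.null(bc) || !is.numeric(bc)) bc <- -Inf
    profile_hmm(m$name, em, lapply(m$transitions, unlist),
                unlist(m$background), bc)
  })
}

#' Import a HMMER3 text-format model (read-only interoperability)
#'
#' Match emissions and match-to-match transitions are mapped onto the
#' internal representation; HMMER's insert-state parameters are averaged
#' into the shared insert distribution.  No cutoff is imported.
#'
#' @param path a HMMER3 `.hmm` file
#' @return a [profile_hmm()]
#' @export
read_hmmer3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name <- sub("^NAME\\s+", "", grep("^NAME", lines, value = TRUE)[1L])
  hi <- grep("^HMM\\s", lines)[1L]
  alpha <- strsplit(trimws(lines[hi]), "\\s+")[[1]][-1L]
  body <- lines[(hi + 2L):length(lines)]
  body <- body[!grepl("^//", body)]
  if (grepl("^\\s*COMPO", body[1L])) body <- body[-1L]
  # skip the two node-0 lines (insert emissions + transitions)
  body <- body[-(1:2)]
  k <- length(body) %/% 3L
  em <- matrix(0, k, 20L, dimnames = list(NULL, AA20))
  tmm <- numeric(k); tmi <- numeric(k); tmd <- numeric(k)
  tim <- numeric(k); tii <- numeric(k); tdm <- numeric(k); tdd <- numeric(k)
  getnum <- function(x) suppressWarnings(as.numeric(x))
  for (s in seq_len(k)) {
    mline <- strsplit(trimws(body[3L * s - 2L]), "\\s+")[[1]]
    p <- exp(-getnum(mline[2:21]))
    names(p) <- alpha[1:20]
    em[s, ] <- p[AA20] / sum(p[AA20])
    tline <- strsplit(trimws(body[3L * s]), "\\s+")[[1]]
    tv <- exp(-getnum(tline[1:7]))  # mm mi md im ii dm dd
    tmm[s] <- tv[1]; tmi[s] <- tv[2]; tmd[s] <- tv[3]
    tim[s] <- tv[4]; tii[s] <- tv[5]; tdm[s] <- tv[6]; tdd[s] <- tv[7]
  }
  eps <- 1e-12
  renorm <- function(a, b, c) {
    tot <- a + b + c
    list(a / tot, b / tot, c / tot)
  }
  m3 <- renorm(tmm + eps, tmi + eps, tmd + eps)
  i3 <- renorm(tim + eps, tii + eps, rep(eps, k))
  d3 <- renorm(tdm + eps, tdd + eps, rep(eps, k))
  profile_hmm(name, em,
              list(mm = m3[[1]], mi = m3[[2]], md = m3[[3]],
                   im = i3[[1]], ii = i3[[2]], id = i3[[3]],
                   dm = d3[[1]], dd = d3[[2]], di = d3[[3]]))
}
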