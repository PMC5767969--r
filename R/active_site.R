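# active_site: align a detected CDPS to the fixed reference alignment
# (profile alignment, so reference columns are never renumbered between
# runs) and read off the residues in the columns where the AlbC reference
# carries each annotated P1/P2 pocket position.

#' Reference CDPS database
#'
#' @param alignment a [seed_alignment()] of reference CDPSs
#' @param reference_id row id of the AlbC-style reference sequence
#' @param pockets list with integer vectors `P1` and `P2`: pocket positions
#'   as 1-based indices on the ungapped reference sequence
#' @return object of class `reference_db`
#' @export
reference_db <- function(alignment, reference_id, pockets) {
  ri <- match(reference_id, alignment$ids)
  if (is.na(ri)) stopf("reference id '%s' not in alignment", reference_id)
  ref_row <- chars(alignment$aligned[[ri]])
  ref_len <- sum(ref_row != "-")
  pockets <- lapply(pockets, as.integer)
  for (p in c("P1", "P2")) {
    v <- pockets[[p]]
    if (is.unsorted(v, strictly = TRUE) || any(v < 1L) || any(v > ref_len))
      stopf("%s pocket indices must be strictly increasing within 1..%d",
            p, ref_len)
  }
  if (length(intersect(pockets$P1, pockets$P2)))
    stopf("P1 and P2 pockets must be disjoint")
  # column of the alignment carrying each ungapped reference index
  ref_cols <- which(ref_row != "-")
  # profile over every informative column so pocket columns are match states
  hmm <- build_profile(alignment, gap_fraction_cutoff = 1.0,
                       name = paste0("ref:", reference_id))
  if (!all(ref_cols %in% hmm$columns_kept))
    stopf("internal: reference columns lost in profile construction")
  structure(list(alignment = alignment, reference_id = reference_id,
                 pockets = pockets, ref_cols = ref_cols, hmm = hmm),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d sequences, reference %s, pockets %d+%d\n",
              length(x$alignment$ids), x$reference_id,
              length(x$pockets$P1), length(x$pockets$P2)))
  invisible(x)
}

#' Load the pocket definition file (JSON: reference_id, P1, P2)
#' @param path JSON file
#' @return list with `reference_id`, `P1`, `P2`
#' @export
read_pocket_map <- function(path) {
  pm <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(reference_id = pm$reference_id,
       P1 = as.integer(pm$P1), P2 = as.integer(pm$P2))
}

# Viterbi with full traceback: same path semantics (and therefore the same
# optimum) as score_protein(), plus the match-column <-> query-residue map.
viterbi_align <- function(hmm, protein) {
  k <- hmm$n_states
  aa <- chars(protein)
  L <- length(aa)
  idx <- match(aa, AA20)
  tr <- hmm$tr_l2
  entry <- -log2(k)
  NEG <- -1e18
  jj <- seq_len(k)
  csd <- cumsum(c(0, tr$dd))
  cts <- cumsum(tr$dd)
  shift1 <- function(v) c(NEG, v[-k])

  M_prev <- rep(NEG, k); I_prev <- rep(NEG, k)
  ptrM <- matrix(0L, k, L); ptrMd <- matrix(0L, k, L)
  ptrMdI <- matrix(FALSE, k, L); ptrI <- matrix(0L, k, L)
  best <- NEG; bp <- NA_integer_; bs <- NA_integer_

  for (p in seq_len(L)) {
    lo <- if (is.na(idx[p])) rep(0, k) else hmm$match_lo[, idx[p]]
    cand_m <- shift1(M_prev + tr$mm)
    cand_i <- shift1(I_prev + tr$im)
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
    use_m <- cand_m >= cand_i & cand_m >= cand_d & cand_m >= entry
    use_i <- !use_m & cand_i >= cand_d & cand_i >= entry
    use_d <- !use_m & !use_i & cand_d >= entry
    ptrM[, p] <- ifelse(use_m, 1L, ifelse(use_i, 2L, ifelse(use_d, 3L, 4L)))
    ptrMd[, p] <- d_from
    ptrMdI[, p] <- a_src_i[d_from]
    newM <- pmax(cand_m, cand_i, cand_d, entry) + lo
    from_m <- M_prev + tr$mi >= I_prev + tr$ii
    ptrI[, p] <- ifelse(from_m, 1L, 2L)
    newI <- pmax(M_prev + tr$mi, I_prev + tr$ii)
    if (max(newM) > best) {
      best <- max(newM); bp <- p; bs <- which.max(newM)
    }
    M_prev <- newM; I_prev <- newI
  }

  match_map <- rep(NA_integer_, k)
  insertions <- integer(0)            # query positions emitted by inserts
  p <- bp; s <- bs; state <- "M"
  while (TRUE) {
    if (state == "M") {
      match_map[s] <- p
      c <- ptrM[s, p]
      if (c == 4L) break
      if (c == 1L) { s <- s - 1L; p <- p - 1L }
      else if (c == 2L) { s <- s - 1L; p <- p - 1L; state <- "I" }
      else { src_i <- ptrMdI[s, p]; s <- ptrMd[s, p]; p <- p - 1L
             state <- if (src_i) "I" else "M" }
    } else {                          # insert at column s
      insertions <- c(insertions, p)
      c <- ptrI[s, p]
      p <- p - 1L
      if (c == 1L) state <- "M"
    }
  }
  list(bitscore = best, match_map = match_map, insertions = rev(insertions))
}

#' Align a query CDPS to the reference alignment
#'
#' Profile-to-sequence alignment: reference columns are preserved and never
#' reordered; query insertions relative to the profile are reported
#' separately.  Deterministic.
#'
#' @param refdb a [reference_db()]
#' @param protein query residue string
#' @param protein_id query id
#' @return object of class `augmented_alignment` with the query row written
#'   over the original reference columns (`-` where unaligned)
#' @export
align_query <- function(refdb, protein, protein_id = "query") {
  if (!nzchar(protein)) stopf("empty query protein")
  va <- viterbi_align(refdb$hmm, protein)
  ncols <- refdb$alignment$columns
  row <- rep("-", ncols)
  aa <- chars(protein)
  kept <- refdb$hmm$columns_kept
  has <- !is.na(va$match_map)
  row[kept[has]] <- aa[va$match_map[has]]
  structure(list(refdb = refdb, protein_id = protein_id, protein = protein,
                 query_row = paste(row, collapse = ""),
                 match_map = va$match_map, insertions = va$insertions,
                 bitscore = va$bitscore),
            class = "augmented_alignment")
}

#' Extract P1/P2 active-site residues from an augmented alignment
#'
#' For each pocket index (1-based on the ungapped reference sequence) the
#' query residue in the column where the reference carries that index is
#' reported; `-` when the query is gapped there.
#'
#' @param aug an [align_query()] result
#' @return object of class `active_site_call`: `protein_id`, `P1_residues`,
#'   `P2_residues`, `aligned_columns`
#' @export
extract_active_site <- function(aug) {
  refdb <- aug$refdb
  qrow <- chars(aug$query_row)
  get <- function(idx) {
    cols <- refdb$ref_cols[idx]
    if (anyNA(cols)) stopf("internal: pocket column not found")
    paste(qrow[cols], collapse = "")
  }
  structure(list(protein_id = aug$protein_id,
                 P1_residues = get(refdb$pockets$P1),
                 P2_residues = get(refdb$pockets$P2),
                 aligned_columns = list(P1 = refdb$ref_cols[refdb$pockets$P1],
                                        P2 = refdb$ref_cols[refdb$pockets$P2])),
            class = "active_site_call")
}

#' One-call convenience: align and extract pocket residues
#' @inheritParams align_query
#' @return an `active_site_call`
#' @export
call_active_site <- function(refdb, protein, protein_id = "query") {
  extract_active_site(align_query(refdb, protein, protein_id))
}

#' Score active-site prediction accuracy against truth
#'
#' Overall accuracy is correct positions over all P1+P2 positions.
#' Off-by-one diagnostics count wrong positions whose predicted residue
#' equals the truth at an adjacent pocket slot (the shifted-alignment
#' failure mode near divergent termini).
#'
#' @param predicted,truth lists of `active_site_call` with matching ids
#' @return list with `overall`, `per_position` (data.frame), `off_by_one`
#' @export
score_active_site_accuracy <- function(predicted, truth) {
  idp <- vapply(predicted, `[[`, "", "protein_id")
  idt <- vapply(truth, `[[`, "", "protein_id")
  m <- match(idp, idt)
  if (anyNA(m)) stopf("truth id missing: %s", idp[is.na(m)][1L])
  truth <- truth[m]
  n_correct <- 0L; n_total <- 0L; n_off1 <- 0L
  per_pos <- NULL
  for (site in c("P1_residues", "P2_residues")) {
    pr <- do.call(rbind, lapply(predicted, function(x) chars(x[[site]])))
    tr <- do.call(rbind, lapply(truth, function(x) chars(x[[site]])))
    stopifnot(ncol(pr) == ncol(tr))
    ok <- pr == tr
    n_correct <- n_correct + sum(ok)
    n_total <- n_total + length(ok)
    # off-by-one: wrong, but the predicted residue matches a neighbouring
    # truth slot
    for (j in seq_len(ncol(pr))) {
      wrong <- which(!ok[, j])
      for (i in wrong) {
        nb <- c(if (j > 1L) tr[i, j - 1L], if (j < ncol(tr)) tr[i, j + 1L])
        if (pr[i, j] %in% nb) n_off1 <- n_off1 + 1L
      }
    }
    per_pos <- rbind(per_pos, data.frame(
      site = sub("_residues", "", site),
      position = seq_len(ncol(pr)),
      accuracy = colMeans(ok),
      stringsAsFactors = FALSE))
  }
  list(overall = n_correct / n_total, per_position = per_pos,
       off_by_one = n_off1)
}

#' Export active-site calls as TSV (id, P1, P2)
#' @param calls list of `active_site_call`
#' @param path output TSV
#' @export
write_active_sites_tsv <- function(calls, path) {
  df <- data.frame(
    protein_id = vapply(calls, `[[`, "", "protein_id"),
    P1 = vapply(calls, `[[`, "", "P1_residues"),
    P2 = vapply(calls, `[[`, "", "P2_residues"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
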