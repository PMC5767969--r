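# validate: leave-one-out cross-validation harnesses mirroring the
# pipeline's validation design: rebuild the model without each sequence in
# turn and test recovery of the withheld sequence.

#' LOOCV of CDPS detection
#'
#' For each seed sequence, the family profile is rebuilt from the
#' remaining rows (cutoff re-derived from the remaining seeds) and the
#' withheld sequence is scored.
#'
#' @param seed a [seed_alignment()] with at least 3 rows
#' @param margin_bits cutoff margin (see [set_cutoff_from_seeds()])
#' @param gap_fraction_cutoff trim parameter for the rebuilt profiles
#' @return list with `sensitivity` and per-sequence data.frame `detail`
#' @export
loocv_detection <- function(seed, margin_bits = NULL,
                            gap_fraction_cutoff = 0.5) {
  n <- length(seed$ids)
  stopifnot(n >= 3L)
  seqs <- seed_sequences(seed)
  detected <- logical(n)
  scores <- numeric(n)
  cutoffs <- numeric(n)
  for (i in seq_len(n)) {
    sub <- seed_alignment(seed$ids[-i], seed$aligned[-i])
    hmm <- build_profile(sub, gap_fraction_cutoff = gap_fraction_cutoff,
                         name = "loocv")
    hmm <- set_cutoff_from_seeds(hmm, seqs[-i], margin_bits)
    scores[i] <- score_protein(hmm, seqs[[i]])
    cutoffs[i] <- hmm$bitscore_cutoff
    detected[i] <- scores[i] >= cutoffs[i]
  }
  list(sensitivity = mean(detected),
       detail = data.frame(id = seed$ids, bitscore = scores,
                           cutoff = cutoffs, detected = detected,
                           stringsAsFactors = FALSE))
}

#' LOOCV of subfamily classification
#'
#' For each sequence, the subfamily models are rebuilt with that sequence
#' withheld from its own subfamily's seed; a subfamily reduced to zero
#' sequences contributes no model (the degenerate single-member case
#' scores 0% when withheld, by construction).
#'
#' @param alignment [seed_alignment()] of the whole family
#' @param subfamilies named character vector: sequence id -> subfamily
#'   label; label order for tie-breaking follows `levels`
#' @param levels subfamily tie-break order
#' @param margin_bits cutoff margin
#' @return list with `accuracy` (overall), `per_subfamily`, `detail`
#' @export
loocv_subfamily <- function(alignment, subfamilies,
                            levels = c("NYH", "XYP", "SYQ"),
                            margin_bits = NULL) {
  ids <- alignment$ids
  stopifnot(all(ids %in% names(subfamilies)))
  labs <- subfamilies[ids]
  seqs <- seed_sequences(alignment)
  pred <- character(length(ids))
  for (i in seq_along(ids)) {
    models <- list()
    for (sf in levels) {
      keep <- which(labs == sf & seq_along(ids) != i)
      if (!length(keep)) next
      sub <- seed_alignment(ids[keep], alignment$aligned[keep])
      hmm <- build_profile(sub, name = sf)
      hmm <- set_cutoff_from_seeds(hmm, seqs[keep], margin_bits)
      models[[sf]] <- hmm
    }
    pred[i] <- classify_subfamily(unname(models), seqs[[i]])$label
  }
  ok <- pred == labs
  list(accuracy = mean(ok),
       per_subfamily = vapply(levels, function(sf)
         if (any(labs == sf)) mean(ok[labs == sf]) else NA_real_, 0),
       detail = data.frame(id = ids, truth = labs, predicted = pred,
                           stringsAsFactors = FALSE))
}

#' LOOCV of active-site residue extraction
#'
#' For each non-reference row, the reference database is rebuilt without
#' that row and the row's ungapped sequence is run as a query; truth is
#' the row's own residues in the pocket columns of the full alignment.
#'
#' @param alignment reference [seed_alignment()]
#' @param reference_id the anchor (AlbC-style) row, never withheld
#' @param pockets list with `P1` and `P2` index vectors (reference
#'   numbering)
#' @return list with `accuracy`, `off_by_one`, `detail` (per-sequence
#'   accuracy), `calls`
#' @export
loocv_active_site <- function(alignment, reference_id, pockets) {
  full <- reference_db(alignment, reference_id, pockets)
  ids <- setdiff(alignment$ids, reference_id)
  seqs <- seed_sequences(alignment)
  truth <- lapply(ids, function(id) truth_active_site(full, id))
  calls <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    keep <- alignment$ids != ids[i]
    sub <- seed_alignment(alignment$ids[keep], alignment$aligned[keep])
    refdb <- reference_db(sub, reference_id, pockets)
    calls[[i]] <- call_active_site(refdb, seqs[[ids[i]]], ids[i])
  }
  acc <- score_active_site_accuracy(calls, truth)
  per_seq <- vapply(seq_along(ids), function(i)
    score_active_site_accuracy(calls[i], truth[i])$overall, 0)
  list(accuracy = acc$overall, off_by_one = acc$off_by_one,
       per_position = acc$per_position,
       detail = data.frame(id = ids, accuracy = per_seq,
                           stringsAsFactors = FALSE),
       calls = calls)
}

#' True pocket residues of an aligned reference-database row
#'
#' Reads the residues directly off the stored alignment (no re-alignment);
#' the ground truth for identity-recovery and LOOCV tests.
#'
#' @param refdb a [reference_db()]
#' @param id row id
#' @return an `active_site_call`
#' @export
truth_active_site <- function(refdb, id) {
  i <- match(id, refdb$alignment$ids)
  if (is.na(i)) stopf("id '%s' not in reference alignment", id)
  row <- chars(refdb$alignment$aligned[[i]])
  structure(list(protein_id = id,
                 P1_residues = paste(row[refdb$ref_cols[refdb$pockets$P1]],
                                     collapse = ""),
                 P2_residues = paste(row[refdb$ref_cols[refdb$pockets$P2]],
                                     collapse = ""),
                 aligned_columns = list(
                   P1 = refdb$ref_cols[refdb$pockets$P1],
                   P2 = refdb$ref_cols[refdb$pockets$P2])),
            class = "active_site_call")
}
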