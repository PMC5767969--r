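# seqio: FASTA / GenBank / GFF3 input-output and a minimal six-frame ORF
# caller so nucleotide input can be processed without an external gene
# finder.  Internal coordinates are 0-based half-open; every emitted GFF3
# file is 1-based inclusive (the conversion is a bijection, tested in
# round-trip).

#' Genome (or protein) record
#'
#' @param id record identifier
#' @param sequence upper-case sequence string
#' @param source free-text provenance
#' @return an object of class `genome_record`
#' @export
genome_record <- function(id, sequence, source = "") {
  if (!nzchar(sequence)) stopf("record '%s': empty sequence", id)
  structure(list(id = id, sequence = sequence, source = source),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%d nt)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' ORF call table constructor
#'
#' Columns: `contig_id`, `start`, `end` (0-based half-open), `strand`
#' (+/-), `protein`, `orf_id`, `caller` (parsed/internal).
#'
#' @param contig_id,start,end,strand,protein,orf_id,caller vectors of equal
#'   length
#' @return a `data.frame` of class `orf_calls`
#' @export
orf_calls <- function(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      protein = character(), orf_id = character(),
                      caller = character()) {
  df <- data.frame(contig_id = as.character(contig_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   protein = as.character(protein),
                   orf_id = as.character(orf_id),
                   caller = as.character(caller),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(df$start >= 0L), all(df$start < df$end),
              all(df$strand %in% c("+", "-")))
    if (any(grepl("*", substr(df$protein, 1L, nchar(df$protein) - 1L),
                  fixed = TRUE)))
      stopf("internal stop codon in protein of ORF '%s'",
            df$orf_id[grepl("\\*.", df$protein)][1L])
  }
  class(df) <- c("orf_calls", "data.frame")
  df
}

validate_alphabet <- function(seqs, ids, valid, what) {
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(chars(seqs[[i]])), valid)
    if (length(bad))
      stopf("record '%s': illegal %s character(s): %s",
            ids[[i]], what, paste(bad, collapse = ", "))
  }
}

#' Read a FASTA file
#'
#' @param path FASTA file
#' @param mode `"nucleotide"`, `"protein"`, or `"auto"` (guess from residue
#'   composition)
#' @return for nucleotide mode, a list of [genome_record()]; for protein
#'   mode, a named character vector of upper-cased sequences
#' @export
read_fasta <- function(path, mode = c("auto", "nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stopf("no such file: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("FASTA parse error in %s: %s",
                                            path, conditionMessage(e)))
  if (!length(set)) stopf("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stopf("duplicate FASTA id: %s", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(set))
  if (mode == "auto") {
    nt_frac <- mean(chars(paste(seqs, collapse = "")) %in% NT_VALID)
    mode <- if (nt_frac > 0.95) "nucleotide" else "protein"
  }
  if (mode == "nucleotide") {
    validate_alphabet(seqs, ids, NT_VALID, "nucleotide")
    lapply(seq_along(ids), function(i)
      genome_record(ids[[i]], seqs[[i]], source = basename(path)))
  } else {
    validate_alphabet(seqs, ids, AA_VALID, "protein")
    stats::setNames(unname(seqs), ids)
  }
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @param width line width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- GenBank flat file (read-only) ----------------------------------------

parse_gb_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  nums <- as.integer(nums)
  segs <- regmatches(loc, gregexpr("[0-9]+\\.\\.[0-9]+", loc))[[1]]
  ivals <- do.call(rbind, lapply(strsplit(segs, "..", fixed = TRUE),
                                 as.integer))
  list(strand = strand, start = min(nums), end = max(nums), ivals = ivals)
}

#' Read a GenBank flat file
#'
#' A deliberately minimal reader: the LOCUS id, ORIGIN sequence, and CDS
#' features (including `complement()` and `join()` locations) are parsed.
#' Proteins come from the `/translation` qualifier when present, otherwise
#' from translation of the (concatenated) coding intervals with table 11.
#'
#' @param path GenBank flat file
#' @return list with `genome` ([genome_record()]) and `orfs`
#'   ([orf_calls()], `caller = "parsed"`)
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1L]), "\\s+")[[1]][2L]
        else basename(path)
  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stopf("GenBank file %s has no ORIGIN block", path)
  seq_lines <- lines[(oi[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  genome <- genome_record(id, sequence, source = basename(path))

  # collect CDS feature blocks between FEATURES and ORIGIN
  fi <- grep("^FEATURES", lines)
  feat <- if (length(fi)) lines[(fi[1L] + 1L):(oi[1L] - 1L)] else character()
  is_key <- grepl("^ {5}\\S", feat)
  key_idx <- which(is_key)
  cds <- orf_calls()
  n <- 0L
  for (k in seq_along(key_idx)) {
    i0 <- key_idx[k]
    i1 <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(feat)
    block <- feat[i0:i1]
    key <- strsplit(trimws(block[1L]), "\\s+")[[1]]
    if (key[1L] != "CDS") next
    # location may continue over lines until the first qualifier
    qual_start <- grep("^\\s+/", block)
    loc_end <- if (length(qual_start)) qual_start[1L] - 1L else length(block)
    loc <- paste(gsub("\\s", "", c(key[2L], trimws(block[seq_len(loc_end)[-1L]]))),
                 collapse = "")
    pl <- parse_gb_location(loc)
    qtxt <- paste(trimws(block[seq.int(loc_end + 1L, length.out = max(0L, length(block) - loc_end))]),
                  collapse = " ")
    trans <- regmatches(qtxt, regexpr('/translation="[^"]*"', qtxt))
    if (length(trans)) {
      protein <- gsub('\\s|/translation=|"', "", trans)
    } else {
      cds_nt <- paste(vapply(seq_len(nrow(pl$ivals)), function(r)
        substr(sequence, pl$ivals[r, 1L], pl$ivals[r, 2L]), ""),
        collapse = "")
      if (pl$strand == "-") cds_nt <- revcomp(cds_nt)
      protein <- sub("\\*$", "", translate11(cds_nt))
    }
    n <- n + 1L
    cds <- rbind(cds, orf_calls(id, pl$start - 1L, pl$end, pl$strand,
                                protein, sprintf("%s_cds%02d", id, n),
                                "parsed"))
  }
  class(cds) <- c("orf_calls", "data.frame")
  list(genome = genome, orfs = cds)
}

# ---- ORF calling ----------------------------------------------------------

orfs_one_strand <- function(seqf, contig_len, strand, min_aa) {
  res <- list()
  starts_ok <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seqf)
  for (frame in 0:2) {
    ncod <- (L - frame) %/% 3L
    if (ncod < 1L) next
    cod_start <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(seqf, cod_start, cod_start + 2L)
    stop_idx <- which(codons %in% stops)
    bounds <- c(0L, stop_idx, ncod + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b] + 1L               # first codon after previous stop
      hi <- bounds[b + 1L] - 1L          # last codon before this stop
      if (hi < lo) next
      has_stop <- bounds[b + 1L] <= ncod
      st <- which(codons[lo:hi] %in% starts_ok)
      if (!length(st)) next
      first <- lo + st[1L] - 1L          # earliest start codon = longest ORF
      n_aa <- hi - first + 1L
      if (n_aa < min_aa) next
      # half-open, 0-based, on this strand's forward reading; include the
      # stop codon when present
      s0 <- cod_start[first] - 1L
      e0 <- cod_start[hi] + 2L + (if (has_stop) 3L else 0L)
      protein <- translate11(substr(seqf, s0 + 1L, cod_start[hi] + 2L))
      # force start codon to M as an initiator
      protein <- paste0("M", substr(protein, 2L, nchar(protein)))
      if (strand == "+") {
        res[[length(res) + 1L]] <- list(start = s0, end = e0, protein = protein)
      } else {
        res[[length(res) + 1L]] <- list(start = contig_len - e0,
                                        end = contig_len - s0,
                                        protein = protein)
      }
    }
  }
  res
}

#' Call ORFs by six-frame scan
#'
#' For each stop-to-stop interval in each of the six frames, the longest
#' open reading frame beginning at ATG/GTG/TTG is reported when it encodes
#' at least `min_aa` residues.  Translation uses the bacterial code (table
#' 11); the initiator codon is rendered as M.  A stand-in for a dedicated
#' gene caller: supply externally called proteins to skip it.
#'
#' @param genome a [genome_record()]
#' @param min_aa minimum protein length in residues
#' @return [orf_calls()] sorted by (contig, start), `caller = "internal"`
#' @export
call_orfs <- function(genome, min_aa = 60L) {
  stopifnot(min_aa >= 1L)
  L <- nchar(genome$sequence)
  fwd <- orfs_one_strand(genome$sequence, L, "+", min_aa)
  rev <- orfs_one_strand(revcomp(genome$sequence), L, "-", min_aa)
  all <- c(lapply(fwd, function(x) c(x, strand = "+")),
           lapply(rev, function(x) c(x, strand = "-")))
  if (!length(all)) return(orf_calls())
  df <- orf_calls(
    contig_id = rep(genome$id, length(all)),
    start = vapply(all, `[[`, 0L, "start"),
    end = vapply(all, `[[`, 0L, "end"),
    strand = vapply(all, `[[`, "", "strand"),
    protein = vapply(all, `[[`, "", "protein"),
    orf_id = "",
    caller = "internal")
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  df$orf_id <- sprintf("%s_orf%03d", genome$id, seq_len(nrow(df)))
  rownames(df) <- NULL
  class(df) <- c("orf_calls", "data.frame")
  df
}

# ---- GFF3 (rtracklayer-backed) --------------------------------------------

#' Write ORF calls (with optional annotations) to GFF3
#'
#' Internal 0-based half-open coordinates become 1-based inclusive GFF3.
#' Extra per-ORF character columns in `annotations` (matched by `orf_id`)
#' are carried as GFF3 attributes; the protein sequence is stored in a
#' `protein` attribute so that write/read round-trips losslessly.
#'
#' @param calls [orf_calls()]
#' @param path output file
#' @param annotations optional data.frame with an `orf_id` column
#' @param contig_lengths optional named vector for `##sequence-region`
#' @return `path`, invisibly
#' @export
write_gff <- function(calls, path, annotations = NULL, contig_lengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(calls)) calls$contig_id else character(),
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
    strand = if (nrow(calls)) calls$strand else character())
  S4Vectors::mcols(gr)$type <- rep("CDS", nrow(calls))
  S4Vectors::mcols(gr)$source <- rep("cdpsminer", nrow(calls))
  S4Vectors::mcols(gr)$phase <- rep(0L, nrow(calls))
  S4Vectors::mcols(gr)$ID <- calls$orf_id
  S4Vectors::mcols(gr)$caller <- calls$caller
  S4Vectors::mcols(gr)$protein <- calls$protein
  if (!is.null(annotations) && nrow(calls)) {
    m <- match(calls$orf_id, annotations$orf_id)
    for (col in setdiff(names(annotations), "orf_id"))
      S4Vectors::mcols(gr)[[col]] <- as.character(annotations[[col]])[m]
  }
  if (!is.null(contig_lengths))
    GenomeInfoDb::seqlengths(gr) <-
      contig_lengths[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a GFF3 file of ORF calls back into an `orf_calls` table
#'
#' @param path GFF3 file written by [write_gff()] (or any GFF3 whose CDS
#'   features carry `ID` attributes)
#' @return [orf_calls()]
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "CDS"]
  mc <- S4Vectors::mcols(gr)
  orf_calls(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein = if ("protein" %in% names(mc)) as.character(mc$protein) else "",
    orf_id = as.character(mc$ID),
    caller = if ("caller" %in% names(mc)) as.character(mc$caller) else "parsed")
}
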