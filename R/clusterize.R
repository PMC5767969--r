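# clusterize: assemble the biosynthetic gene cluster around each detected
# CDPS (all ORFs within a +/- 2.5 kb window, any-overlap rule; overlapping
# CDPS windows merge into multi-CDPS clusters), annotate tailoring and
# resistance domains with a packaged profile-HMM library, and tally
# domain co-occurrence across unique clusters.

#' Domain model for cluster annotation
#'
#' @param name domain name (e.g. `"CYP121"`)
#' @param hmm a [profile_hmm()] with a finite cutoff
#' @param category one of `cdps_tailoring`, `generic_tailoring`,
#'   `resistance`, `other`
#' @param reaction_ref tailoring reaction executed when this domain is
#'   present (must name an entry of [tailoring_reactions()] for
#'   `cdps_tailoring` models)
#' @return object of class `domain_model`
#' @export
domain_model <- function(name, hmm, category = c("cdps_tailoring",
                                                 "generic_tailoring",
                                                 "resistance", "other"),
                         reaction_ref = NULL) {
  category <- match.arg(category)
  if (category == "cdps_tailoring") {
    if (is.null(reaction_ref) || !reaction_ref %in% names(tailoring_reactions()))
      stopf("cdps_tailoring model '%s' must reference a tailoring reaction",
            name)
  }
  structure(list(name = name, category = category, hmm = hmm,
                 reaction_ref = reaction_ref),
            class = "domain_model")
}

#' Build a domain library from seed alignments and a manifest
#'
#' @param seeds named list of [seed_alignment()] (names = domain names)
#' @param manifest data.frame with columns `name`, `category`,
#'   `reaction_ref` (NA allowed)
#' @param margin_bits cutoff margin passed to [set_cutoff_from_seeds()]
#' @return named list of [domain_model()]
#' @export
build_domain_library <- function(seeds, manifest, margin_bits = NULL) {
  stats::setNames(lapply(manifest$name, function(nm) {
    seed <- seeds[[nm]]
    if (is.null(seed)) stopf("no seed alignment for domain '%s'", nm)
    hmm <- build_profile(seed, name = nm)
    hmm <- set_cutoff_from_seeds(hmm, seed_sequences(seed), margin_bits)
    rr <- manifest$reaction_ref[manifest$name == nm]
    domain_model(nm, hmm, manifest$category[manifest$name == nm],
                 if (is.na(rr)) NULL else rr)
  }), manifest$name)
}

#' Assemble gene clusters around detected CDPSs
#'
#' Each CDPS ORF defines a window `[start - window_bp, end + window_bp]`
#' (clipped at the contig ends when lengths are supplied); CDPSs whose
#' windows overlap are merged into one cluster.  Any ORF overlapping the
#' window is a member.
#'
#' @param cdps_hits data.frame from [detect_cdps()] (`protein_id` must
#'   match `orf_id` in `orfs`)
#' @param orfs [orf_calls()] for all ORFs on the same contigs
#' @param window_bp window half-width in bp (default 2500)
#' @param contig_lengths optional named vector for window clipping
#' @return list of `gene_cluster` objects, sorted by (contig, start), ids
#'   `cluster_<contig>_<index>`
#' @export
assemble_clusters <- function(cdps_hits, orfs, window_bp = 2500L,
                              contig_lengths = NULL) {
  if (!nrow(cdps_hits)) return(list())
  m <- match(cdps_hits$protein_id, orfs$orf_id)
  if (anyNA(m))
    stopf("CDPS hit '%s' has no matching ORF",
          cdps_hits$protein_id[is.na(m)][1L])
  cd <- orfs[m, , drop = FALSE]
  out <- list()
  for (contig in sort(unique(cd$contig_id))) {
    cc <- cd[cd$contig_id == contig, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    clen <- if (!is.null(contig_lengths)) contig_lengths[[contig]] else Inf
    ws <- pmax(0L, cc$start - window_bp)
    we <- pmin(clen, cc$end + window_bp)
    # merge overlapping windows (transitive)
    grp <- integer(nrow(cc)); g <- 0L; hi <- -1L
    for (i in seq_len(nrow(cc))) {
      if (ws[i] > hi) g <- g + 1L
      grp[i] <- g
      hi <- max(hi, we[i])
    }
    corfs <- orfs[orfs$contig_id == contig, , drop = FALSE]
    for (gi in seq_len(g)) {
      rows <- cc[grp == gi, , drop = FALSE]
      win <- c(min(ws[grp == gi]), max(we[grp == gi]))
      members <- corfs[corfs$end > win[1L] & corfs$start < win[2L], ,
                       drop = FALSE]
      out[[length(out) + 1L]] <- structure(
        list(cluster_id = sprintf("cluster_%s_%d", contig, gi),
             contig_id = contig,
             cdps_orfs = rows$orf_id,
             window = win,
             member_orfs = members,
             domain_hits = NULL,
             unannotated_orfs = character()),
        class = "gene_cluster")
    }
  }
  out
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("<gene_cluster> %s: %d CDPS, %d ORFs in %d..%d%s\n",
              x$cluster_id, length(x$cdps_orfs), nrow(x$member_orfs),
              x$window[1L], x$window[2L],
              if (is.null(x$domain_hits)) " (unannotated)" else ""))
  invisible(x)
}

#' Annotate tailoring and resistance domains within a cluster
#'
#' Every non-CDPS member ORF is scored against every library model; all
#' hits above each model's cutoff are logged, and the best-scoring model
#' per ORF is retained as primary.  ORFs with no hit are listed as
#' unannotated.
#'
#' @param cluster a `gene_cluster` from [assemble_clusters()]
#' @param library named list of [domain_model()]
#' @return the cluster with `domain_hits` (data.frame `orf_id, domain,
#'   category, bitscore, primary`) and `unannotated_orfs` filled
#' @export
annotate_domains <- function(cluster, library) {
  members <- cluster$member_orfs
  targets <- members[!members$orf_id %in% cluster$cdps_orfs, , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(targets))) {
    for (dm in library) {
      sc <- score_protein(dm$hmm, targets$protein[i])
      if (sc >= dm$hmm$bitscore_cutoff)
        hits[[length(hits) + 1L]] <- data.frame(
          orf_id = targets$orf_id[i], domain = dm$name,
          category = dm$category, bitscore = sc, primary = FALSE,
          stringsAsFactors = FALSE)
    }
  }
  dh <- if (length(hits)) do.call(rbind, hits) else
    data.frame(orf_id = character(), domain = character(),
               category = character(), bitscore = numeric(),
               primary = logical(), stringsAsFactors = FALSE)
  for (oid in unique(dh$orf_id)) {
    rows <- which(dh$orf_id == oid)
    dh$primary[rows[which.max(dh$bitscore[rows])]] <- TRUE
  }
  cluster$domain_hits <- dh
  cluster$unannotated_orfs <- setdiff(targets$orf_id, dh$orf_id)
  cluster
}

#' Domains present in a cluster (primary hits)
#' @param cluster annotated `gene_cluster`
#' @return character vector of domain names
#' @export
cluster_domains <- function(cluster) {
  if (is.null(cluster$domain_hits)) return(character())
  sort(unique(cluster$domain_hits$domain[cluster$domain_hits$primary]))
}

#' Tally domain co-occurrence across clusters
#'
#' Symmetric counts of clusters containing both domains; the diagonal is
#' the per-domain frequency, defined over unique clusters (never over
#' member genomes).
#'
#' @param clusters list of annotated `gene_cluster`
#' @return integer matrix (domain x domain); `0 x 0` for empty input
#' @export
tally_cooccurrence <- function(clusters) {
  doms <- sort(unique(unlist(lapply(clusters, cluster_domains))))
  m <- matrix(0L, length(doms), length(doms), dimnames = list(doms, doms))
  for (cl in clusters) {
    d <- cluster_domains(cl)
    for (a in d) for (b in d) m[a, b] <- m[a, b] + 1L
  }
  m
}

#' Export gene clusters as nested GFF3
#'
#' One `biosynthetic_gene_cluster` parent feature per cluster spanning its
#' window, with member CDS features as children (`Parent` attribute);
#' CDPS members are flagged `role=CDPS`, annotated members carry their
#' primary `domain`.
#'
#' @param clusters list of (annotated) `gene_cluster`
#' @param path output GFF3 file
#' @return `path`, invisibly
#' @export
write_cluster_gff <- function(clusters, path) {
  rows <- list()
  for (cl in clusters) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = cl$contig_id, start = cl$window[1L] + 1L,
      end = cl$window[2L], strand = "*",
      type = "biosynthetic_gene_cluster",
      ID = cl$cluster_id, Parent = NA_character_,
      role = NA_character_, domain = NA_character_,
      stringsAsFactors = FALSE)
    prim <- if (!is.null(cl$domain_hits))
      cl$domain_hits[cl$domain_hits$primary, , drop = FALSE]
    else cl$domain_hits
    for (i in seq_len(nrow(cl$member_orfs))) {
      o <- cl$member_orfs[i, ]
      dom <- if (!is.null(prim) && o$orf_id %in% prim$orf_id)
        prim$domain[prim$orf_id == o$orf_id] else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = cl$contig_id, start = o$start + 1L, end = o$end,
        strand = o$strand, type = "CDS",
        ID = paste0(cl$cluster_id, ":", o$orf_id), Parent = cl$cluster_id,
        role = if (o$orf_id %in% cl$cdps_orfs) "CDPS" else NA_character_,
        domain = dom, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$source <- "cdpsminer"
  S4Vectors::mcols(gr)$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  S4Vectors::mcols(gr)$role <- df$role
  S4Vectors::mcols(gr)$domain <- df$domain
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Predict the compound library for an annotated cluster
#'
#' Convenience bridge to the chemistry module: takes the two predicted
#' substrates plus the cluster's primary tailoring domains (mapped through
#' their `reaction_ref`) and returns the combinatorial library.
#'
#' @param cluster annotated `gene_cluster`
#' @param aa1,aa2 predicted substrates
#' @param library the domain library used for annotation
#' @param cap library cap
#' @return a `compound_library`
#' @export
cluster_compounds <- function(cluster, aa1, aa2, library, cap = 64L) {
  doms <- cluster_domains(cluster)
  rxns <- unlist(lapply(library[doms], function(dm) dm$reaction_ref))
  apply_tailoring(aa1, aa2, domains = unique(rxns %||% character()),
                  cap = cap)
}
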