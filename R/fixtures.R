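# fixtures: deterministic synthetic-data generators with machine-readable
# truth.  Families are consensus sequences with i.i.d. substitutions;
# subfamily motifs and pocket signatures are re-imposed after mutation, so
# the planted truth is exact.  Generation is a pure function of the spec,
# including its seed.

#' Specification of a synthetic protein family
#'
#' @param length consensus length in residues
#' @param n_sequences family size
#' @param mutation_rate per-site substitution probability (0..0.5)
#' @param motif_positions positions of the subfamily signature triad
#' @param subfamily_motifs named character vector, e.g.
#'   `c(NYH = "NYH", XYP = "AYP", SYQ = "SYQ")`; names are labels, values
#'   the residues planted at `motif_positions`.  `NULL` for none.
#' @param subfamily_sizes named integer vector (same names); `NULL` splits
#'   evenly
#' @param subfamily_divergence per-site substitution rate separating each
#'   subfamily's own consensus from the family consensus (the real
#'   subfamilies are phylogenetically distinct clades, not
#'   motif-only variants; 0 disables)
#' @param pocket_positions list with integer vectors `P1` and `P2`
#' @param pocket_classes named list: substrate label -> list(P1 =, P2 =)
#'   signature residue strings (one char per pocket position); `NULL` for
#'   none
#' @param seed integer RNG seed
#' @return object of class `family_spec`
#' @export
family_spec <- function(length = 240L, n_sequences = 20L,
                        mutation_rate = 0.05,
                        motif_positions = c(30L, 31L, 32L),
                        subfamily_motifs = NULL,
                        subfamily_sizes = NULL,
                        subfamily_divergence = 0.15,
                        pocket_positions = list(P1 = integer(),
                                                P2 = integer()),
                        pocket_classes = NULL,
                        seed = 1L) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 0.5,
            all(unlist(pocket_positions) <= length),
            all(motif_positions <= length))
  if (length(intersect(pocket_positions$P1, pocket_positions$P2)))
    stopf("P1 and P2 pocket positions must be disjoint")
  if (!is.null(subfamily_motifs) &&
      length(intersect(motif_positions, unlist(pocket_positions))))
    stopf("motif positions overlap pocket positions")
  structure(list(length = as.integer(length),
                 n_sequences = as.integer(n_sequences),
                 mutation_rate = mutation_rate,
                 motif_positions = as.integer(motif_positions),
                 subfamily_motifs = subfamily_motifs,
                 subfamily_sizes = subfamily_sizes,
                 subfamily_divergence = subfamily_divergence,
                 pocket_positions = lapply(pocket_positions, as.integer),
                 pocket_classes = pocket_classes,
                 seed = as.integer(seed)),
            class = "family_spec")
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

mutate_seq <- function(x, rate) {
  v <- chars(x)
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(a) sample(setdiff(AA20, a), 1L), "")
  }
  paste(v, collapse = "")
}

#' Generate a synthetic protein family with planted truth
#'
#' @param spec a [family_spec()]
#' @return list with `sequences` (named vector), `consensus`, `truth`
#'   (data.frame: id, subfamily, P1, P2, substrate), and `alignment`
#'   (a [seed_alignment()]; substitution-only evolution means the family
#'   alignment is the trivial ungapped one)
#' @export
gen_family <- function(spec) {
  with_seed(spec$seed, {
    consensus <- random_protein(spec$length)
    n <- spec$n_sequences
    fams <- names(spec$subfamily_motifs)
    sub <- if (is.null(fams)) rep(NA_character_, n) else {
      sizes <- spec$subfamily_sizes %||%
        stats::setNames(diff(round(seq(0, n, length.out = length(fams) + 1L))),
                        fams)
      rep(names(sizes), times = sizes)[seq_len(n)]
    }
    # each subfamily is its own clade: a diverged sub-consensus
    sub_consensus <- if (is.null(fams)) NULL else
      stats::setNames(lapply(fams, function(f)
        mutate_seq(consensus, spec$subfamily_divergence)), fams)
    cls <- names(spec$pocket_classes)
    cls_of <- if (is.null(cls)) rep(NA_character_, n)
              else rep(cls, length.out = n)
    ids <- sprintf("syn%03d", seq_len(n))
    seqs <- character(n)
    p1 <- character(n); p2 <- character(n)
    for (i in seq_len(n)) {
      anc <- if (is.na(sub[i])) consensus else sub_consensus[[sub[i]]]
      s <- chars(mutate_seq(anc, spec$mutation_rate))
      s[1L] <- "M"   # initiator Met so back-translated genes have a start
      if (!is.na(sub[i]))
        s[spec$motif_positions] <- chars(spec$subfamily_motifs[[sub[i]]])
      if (!is.na(cls_of[i])) {
        sig <- spec$pocket_classes[[cls_of[i]]]
        s[spec$pocket_positions$P1] <- chars(sig$P1)
        s[spec$pocket_positions$P2] <- chars(sig$P2)
      }
      seqs[i] <- paste(s, collapse = "")
      p1[i] <- paste(s[spec$pocket_positions$P1], collapse = "")
      p2[i] <- paste(s[spec$pocket_positions$P2], collapse = "")
    }
    names(seqs) <- ids
    list(sequences = seqs,
         consensus = consensus,
         subfamily_consensus = sub_consensus,
         truth = data.frame(id = ids, subfamily = sub,
                            P1 = p1, P2 = p2, substrate = cls_of,
                            stringsAsFactors = FALSE),
         alignment = seed_alignment(ids, seqs))
  })
}

#' Generate a labeled pocket-residue training set
#'
#' Residue vectors are sampled around per-class pocket signatures: each
#' position keeps the signature residue with probability `1 - jitter`,
#' otherwise a uniform random residue.  A `label_noise` fraction of labels
#' is then cyclically permuted (guaranteeing a wrong label when the classes
#' are distinct).
#'
#' @param signatures named list: substrate label -> signature residue string
#' @param n_per_class examples per class
#' @param label_noise fraction of labels permuted
#' @param jitter per-position probability of a random residue
#' @param site `"P1"` or `"P2"` (metadata only)
#' @param seed integer
#' @return a `training_set`: list(site, vectors = character matrix, labels)
#' @export
gen_training <- function(signatures, n_per_class = 5L, label_noise = 0,
                         jitter = 0.1, site = "P1", seed = 1L) {
  wd <- unique(nchar(unlist(signatures)))
  stopifnot(length(wd) == 1L)
  with_seed(seed, {
    labs <- rep(names(signatures), each = n_per_class)
    vecs <- t(vapply(labs, function(cl) {
      sig <- chars(signatures[[cl]])
      sub <- stats::runif(wd) < jitter
      sig[sub] <- sample(AA20, sum(sub), replace = TRUE)
      sig
    }, character(wd)))
    rownames(vecs) <- NULL
    if (label_noise > 0 && length(labs) > 1L) {
      nn <- round(label_noise * length(labs))
      if (nn > 0L) {
        pick <- sample(length(labs), nn)
        labs[pick] <- labs[c(pick[-1L], pick[1L])]
      }
    }
    training_set(site = site, vectors = vecs, labels = labs)
  })
}

#' Specification of a synthetic genome survey
#'
#' @param n_genomes number of genomes (before duplication)
#' @param duplicate_fraction fraction of emitted genomes that are exact
#'   copies of earlier ones (appended, ids suffixed `_dup`)
#' @param layouts list of cluster layouts, recycled across genomes.  Each
#'   layout: `list(n_cdps =, cdps_spacing_bp =, tailoring = c(...),
#'   gene_spacing_bp =, strand = )`
#' @param flank_bp plain intergenic sequence on each side of the cluster
#' @param seed integer
#' @return object of class `survey_spec`
#' @export
survey_spec <- function(n_genomes = 10L, duplicate_fraction = 0,
                        layouts = list(list(n_cdps = 1L,
                                            cdps_spacing_bp = 0L,
                                            tailoring = character(),
                                            gene_spacing_bp = 300L,
                                            strand = "+")),
                        flank_bp = 800L, seed = 1L) {
  structure(list(n_genomes = as.integer(n_genomes),
                 duplicate_fraction = duplicate_fraction,
                 layouts = layouts, flank_bp = as.integer(flank_bp),
                 seed = as.integer(seed)),
            class = "survey_spec")
}

backtranslate <- function(protein) {
  paste0(paste(ECOLI_CODON[chars(protein)], collapse = ""), STOP_CODON)
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

#' Generate synthetic genomes embedding CDPS clusters
#'
#' Proteins are back-translated with fixed most-frequent E. coli codons
#' (deterministic); genes are laid out per layout with the requested
#' spacings and strands, flanked by random intergenic sequence.  Exact
#' duplicate genomes are appended to exercise dereplication.
#'
#' @param spec a [survey_spec()]
#' @param cdps_family result of [gen_family()] supplying CDPS proteins
#' @param domain_families named list (domain name -> [gen_family()] result)
#'   supplying tailoring/resistance proteins
#' @return list with `genomes` (list of [genome_record()]), `truth_genes`
#'   ([orf_calls()]-shaped data.frame plus `role` and `domain` columns) and
#'   `truth_clusters` (one row per expected merged cluster)
#' @export
gen_genomes <- function(spec, cdps_family, domain_families = list()) {
  with_seed(spec$seed + 7L, {
    genomes <- list()
    tg <- list()
    tc <- list()
    cd_pool <- cdps_family$sequences
    cd_i <- 0L
    for (g in seq_len(spec$n_genomes)) {
      lay <- spec$layouts[[(g - 1L) %% length(spec$layouts) + 1L]]
      gid <- sprintf("genome%03d", g)
      strand <- lay$strand %||% "+"
      pieces <- character()
      pos <- 0L
      genes <- list()
      put_gene <- function(protein, role, domain, spacer_bp) {
        nt <- backtranslate(protein)
        if (strand == "-") nt <- revcomp(nt)
        spacer <- random_nt(spacer_bp)
        pieces <<- c(pieces, spacer, nt)
        start <- pos + spacer_bp
        pos <<- start + nchar(nt)
        genes[[length(genes) + 1L]] <<- list(start = start, end = pos,
                                             strand = strand,
                                             protein = protein, role = role,
                                             domain = domain)
      }
      put_gene_sp <- function(...) put_gene(...)
      # leading flank
      pieces <- c(pieces, random_nt(spec$flank_bp)); pos <- spec$flank_bp
      cdps_ids <- character()
      for (ci in seq_len(lay$n_cdps %||% 1L)) {
        cd_i <- cd_i %% length(cd_pool) + 1L
        sp <- if (ci == 1L) 0L else as.integer(lay$cdps_spacing_bp)
        put_gene(cd_pool[[cd_i]], "cdps", names(cd_pool)[cd_i], sp)
      }
      for (dn in lay$tailoring %||% character()) {
        fam <- domain_families[[dn]]
        if (is.null(fam)) stopf("no domain family named '%s'", dn)
        prot <- fam$sequences[[(g - 1L) %% length(fam$sequences) + 1L]]
        put_gene(prot, "tailoring", dn, as.integer(lay$gene_spacing_bp %||% 300L))
      }
      pieces <- c(pieces, random_nt(spec$flank_bp))
      seqnt <- paste(pieces, collapse = "")
      genomes[[gid]] <- genome_record(gid, seqnt, source = "synthetic")
      gdf <- data.frame(
        contig_id = gid,
        start = vapply(genes, `[[`, 0L, "start"),
        end = vapply(genes, `[[`, 0L, "end"),
        strand = vapply(genes, `[[`, "", "strand"),
        protein = vapply(genes, `[[`, "", "protein"),
        orf_id = sprintf("%s_gene%02d", gid, seq_along(genes)),
        caller = "truth",
        role = vapply(genes, `[[`, "", "role"),
        domain = vapply(genes, `[[`, "", "domain"),
        stringsAsFactors = FALSE)
      tg[[gid]] <- gdf
      # expected clusters: CDPS windows merged at 2.5 kb
      cd <- gdf[gdf$role == "cdps", , drop = FALSE]
      merged <- if (nrow(cd) > 1L &&
                    all(diff(cd$start) - diff(cd$start) * 0 +
                        (cd$start[-1L] - cd$end[-nrow(cd)]) <= 5000L)) 1L
                else nrow(cd)
      tc[[gid]] <- data.frame(
        contig_id = gid,
        n_cdps = nrow(cd),
        n_expected_clusters = merged,
        domains = paste(sort(gdf$domain[gdf$role == "tailoring"]),
                        collapse = ","),
        stringsAsFactors = FALSE)
    }
    # duplicates
    n_dup <- round(spec$duplicate_fraction * length(genomes))
    if (n_dup > 0L) {
      src <- names(genomes)[seq_len(n_dup)]
      for (s in src) {
        did <- paste0(s, "_dup")
        genomes[[did]] <- genome_record(did, genomes[[s]]$sequence,
                                        source = "synthetic-duplicate")
        d <- tg[[s]]; d$contig_id <- did
        d$orf_id <- sub(s, did, d$orf_id, fixed = TRUE)
        tg[[did]] <- d
      }
    }
    truth_genes <- do.call(rbind, tg)
    rownames(truth_genes) <- NULL
    truth_clusters <- do.call(rbind, tc)
    rownames(truth_clusters) <- NULL
    list(genomes = genomes, truth_genes = truth_genes,
         truth_clusters = truth_clusters)
  })
}
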