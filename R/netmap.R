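# netmap: dereplication of CDPS sequences, cd-hit-style greedy identity
# clustering, internal Smith-Waterman + Karlin-Altschul pairwise E-values
# (a pinned replacement for BLASTP, since version-dependent scoring would
# move edges at a 1e-100 knife-edge), and the E-value-thresholded sequence
# similarity network with named connected-component families.

# pinned alignment parameters, recorded in output metadata
NETMAP_PARAMS <- list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                      lambda = 0.267, K = 0.041)

#' Collapse exact duplicate sequences
#'
#' @param sequences named character vector of proteins
#' @return list with `representatives` (named vector, first-seen id wins)
#'   and `members` (named list representative -> all ids, itself included)
#' @export
dedup_exact <- function(sequences) {
  stopifnot(!is.null(names(sequences)))
  first <- !duplicated(unname(sequences))
  reps <- sequences[first]
  members <- lapply(seq_along(reps), function(i)
    names(sequences)[sequences == reps[[i]]])
  names(members) <- names(reps)
  list(representatives = reps, members = members)
}

#' Global-identity of two sequences (matches / alignment length)
#' @keywords internal
global_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Greedy incremental clustering at an identity threshold (cd-hit-like)
#'
#' Sequences are sorted by decreasing length; each is assigned to the
#' first existing representative with global identity at or above the
#' threshold, else it founds a new cluster.  The word-filter heuristics of
#' cd-hit are not reproduced, only its greedy longest-first algorithm.
#'
#' @param sequences named character vector
#' @param threshold identity fraction in (0, 1]
#' @return named list: representative id -> member ids
#' @export
cluster_at_identity <- function(sequences, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  ord <- order(-nchar(sequences), names(sequences))
  reps <- character(0)
  members <- list()
  for (i in ord) {
    id <- names(sequences)[i]
    placed <- FALSE
    for (r in reps) {
      if (identical(sequences[[r]], sequences[[id]]) ||
          global_identity(sequences[[r]], sequences[[id]]) >= threshold) {
        members[[r]] <- c(members[[r]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[id]] <- id
    }
  }
  members
}

#' Pairwise local-alignment E-value (internal BLASTP stand-in)
#'
#' Smith-Waterman under BLOSUM62 with affine gaps (open 11, extend 1),
#' converted to an E-value with Karlin-Altschul statistics
#' `E = K * m * n * db_size * exp(-lambda * S)`; computed in log10 space
#' so values far below double precision (the 1e-100 regime) remain exact.
#' Symmetric by construction.
#'
#' @param a,b protein sequences
#' @param db_size number of database sequences in the notional search
#'   (E-values scale linearly with it)
#' @return list with `log10_evalue`, `evalue` (0 when underflowed), and
#'   `score`
#' @export
pairwise_evalue <- function(a, b, db_size = 1L) {
  stopifnot(nzchar(a), nzchar(b))
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "local", scoreOnly = TRUE)
  p <- NETMAP_PARAMS
  log10e <- log10(p$K) + log10(nchar(a)) + log10(nchar(b)) +
    log10(db_size) - p$lambda * s / log(10)
  list(log10_evalue = log10e, evalue = 10^log10e, score = s)
}

#' Build the sequence similarity network
#'
#' All pairs are scored with [pairwise_evalue()]; an edge is present when
#' the E-value is at or below `threshold`.  Connected components are
#' computed and attached.
#'
#' @param sequences named character vector (deduplicate first:
#'   [dedup_exact()])
#' @param threshold E-value threshold for an edge (default 1e-100)
#' @param node_meta optional data.frame with an `id` column of node
#'   attributes carried into exports
#' @return object of class `similarity_network`: `nodes`, `edges`
#'   (data.frame a, b, log10_evalue), `threshold`, `components` (named
#'   membership vector), `params`
#' @export
build_network <- function(sequences, threshold = 1e-100, node_meta = NULL) {
  ids <- names(sequences)
  n <- length(ids)
  db <- max(1L, n)
  edges <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pe <- pairwise_evalue(sequences[[i]], sequences[[j]], db_size = db)
    if (pe$log10_evalue <= log10(threshold))
      edges[[length(edges) + 1L]] <- data.frame(
        a = ids[i], b = ids[j], log10_evalue = pe$log10_evalue,
        stringsAsFactors = FALSE)
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), log10_evalue = numeric(),
               stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  structure(list(nodes = ids, edges = edf, threshold = threshold,
                 components = comp[ids], node_meta = node_meta,
                 params = NETMAP_PARAMS),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d edges, %d components (E <= %g)\n",
              length(x$nodes), nrow(x$edges),
              length(unique(x$components)), x$threshold))
  invisible(x)
}

#' Name cluster families from network components
#'
#' A family name is the sorted domain-architecture signature of its
#' members' gene clusters, the majority genus, and the component index:
#' `"CDPS+CYP121|Streptomyces|c1"`.  Stable across runs.
#'
#' @param network a [build_network()] result
#' @param cluster_info data.frame mapping `id` (node) to `architecture`
#'   (e.g. `"CDPS+CYP121"`) and `genus`; unmapped nodes are named by
#'   component index only (with a warning)
#' @return data.frame `family`, `component`, `id`
#' @export
name_families <- function(network, cluster_info = NULL) {
  comp <- network$components
  rows <- lapply(sort(unique(comp)), function(ci) {
    ids <- names(comp)[comp == ci]
    nm <- if (!is.null(cluster_info) && any(ids %in% cluster_info$id)) {
      sub <- cluster_info[cluster_info$id %in% ids, , drop = FALSE]
      arch <- paste(sort(unique(sub$architecture)), collapse = ";")
      genus <- names(sort(table(sub$genus), decreasing = TRUE))[1L]
      sprintf("%s|%s|c%d", arch, genus, ci)
    } else {
      if (!is.null(cluster_info))
        warning(sprintf("component %d has no mapped cluster; named by index",
                        ci))
      sprintf("c%d", ci)
    }
    data.frame(family = nm, component = ci, id = ids,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a network as edge-list TSV, node table TSV, and GraphML
#'
#' @param network a [build_network()] result
#' @param prefix output path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_nodes.tsv`, `<prefix>.graphml`
#' @return invisibly, the paths written
#' @export
write_network <- function(network, prefix) {
  e_path <- paste0(prefix, "_edges.tsv")
  n_path <- paste0(prefix, "_nodes.tsv")
  g_path <- paste0(prefix, ".graphml")
  utils::write.table(network$edges, e_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- data.frame(id = network$nodes,
                      component = unname(network$components),
                      stringsAsFactors = FALSE)
  if (!is.null(network$node_meta))
    nodes <- merge(nodes, network$node_meta, by = "id", all.x = TRUE,
                   sort = FALSE)
  utils::write.table(nodes, n_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes))
  igraph::write_graph(g, g_path, format = "graphml")
  invisible(c(e_path, n_path, g_path))
}
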