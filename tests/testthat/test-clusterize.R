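mk_orfs <- function(df) {
  orf_calls(df$contig, df$start, df$end, df$strand %||% rep("+", nrow(df)),
            df$protein %||% rep("MKLV", nrow(df)),
            df$orf_id, rep("internal", nrow(df)))
}

hit_for <- function(ids) data.frame(protein_id = ids, model = "CDPS",
                                    bitscore = 100, env_start = 1L,
                                    env_end = 10L, stringsAsFactors = FALSE)

test_that("window merging: 2.0 kb merges, 30 kb splits, edges clip", {
  orfs <- mk_orfs(data.frame(
    contig = "c1",
    start = c(0L, 2700L, 40000L), end = c(700L, 3400L, 40700L),
    orf_id = c("a", "b", "far")))
  cl <- assemble_clusters(hit_for(c("a", "b", "far")), orfs,
                          window_bp = 2500L,
                          contig_lengths = c(c1 = 50000L))
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$cdps_orfs, c("a", "b"))   # 2.0 kb apart: merged
  expect_equal(cl[[2]]$cdps_orfs, "far")
  # window clipped at the contig start, no negative coordinates
  expect_equal(cl[[1]]$window[1L], 0L)
  expect_equal(cl[[1]]$window[2L], 5900L)
  # deterministic ids
  expect_equal(vapply(cl, `[[`, "", "cluster_id"),
               c("cluster_c1_1", "cluster_c1_2"))
})

test_that("every CDPS hit lands in exactly one cluster; order-free", {
  fam <- w_family()
  sim <- w_survey()
  hmm <- w_family_hmm()
  g <- sim$genomes[["genome004"]]          # two CDPSs 2.0 kb apart
  orfs <- call_orfs(g, 60L)
  hits <- detect_cdps(hmm, stats::setNames(orfs$protein, orfs$orf_id))
  expect_equal(nrow(hits), 2L)
  cl <- assemble_clusters(hits, orfs)
  expect_length(cl, 1L)
  expect_length(cl[[1]]$cdps_orfs, 2L)
  # permuting input hits yields identical clusters
  cl2 <- assemble_clusters(hits[rev(seq_len(nrow(hits))), ], orfs)
  expect_equal(cl, cl2)
  # membership partition over all hits
  all_ids <- unlist(lapply(cl, `[[`, "cdps_orfs"))
  expect_setequal(all_ids, hits$protein_id)
  expect_false(anyDuplicated(all_ids) > 0L)
  expect_error(assemble_clusters(hit_for("ghost"), orfs), "no matching ORF")
})

test_that("domain annotation finds the planted tailoring gene", {
  sim <- w_survey()
  hmm <- w_family_hmm()
  lib <- w_domain_library()
  g <- sim$genomes[["genome002"]]          # CDPS + CYP121 layout
  orfs <- call_orfs(g, 60L)
  hits <- detect_cdps(hmm, stats::setNames(orfs$protein, orfs$orf_id))
  cl <- annotate_domains(assemble_clusters(hits, orfs)[[1L]], lib)
  expect_equal(cluster_domains(cl), "CYP121")
  expect_true(all(cl$domain_hits$category[cl$domain_hits$primary] ==
                    "cdps_tailoring"))
  # unannotated ORFs listed, CDPS not scored against the domain library
  expect_false(any(cl$domain_hits$orf_id %in% cl$cdps_orfs))
  expect_true(all(cl$unannotated_orfs %in% cl$member_orfs$orf_id))
})

test_that("a lone CDPS cluster annotates to zero domains", {
  orfs <- mk_orfs(data.frame(contig = "c", start = 0L, end = 900L,
                             orf_id = "solo"))
  orfs$protein <- seed_sequences(w_family()$alignment)[[1L]]
  cl <- annotate_domains(assemble_clusters(hit_for("solo"), orfs)[[1L]],
                         w_domain_library())
  expect_equal(nrow(cl$domain_hits), 0L)
  expect_length(cl$unannotated_orfs, 0L)
})

test_that("an ORF matching two models keeps the best as primary", {
  doms <- w_domains()
  lib <- w_domain_library()
  # score a CYP121 family member against a library that also contains a
  # looser copy of the same model under another name
  loose <- lib$CYP121
  loose$name <- "CYP121_loose"
  loose$hmm$name <- "CYP121_loose"
  loose$hmm$bitscore_cutoff <- loose$hmm$bitscore_cutoff - 50
  lib2 <- c(lib, list(CYP121_loose = loose))
  orfs <- mk_orfs(data.frame(contig = "c", start = c(0L, 1200L),
                             end = c(900L, 1700L),
                             orf_id = c("cdps1", "tl1")))
  orfs$protein <- c(seed_sequences(w_family()$alignment)[[1L]],
                    doms$CYP121$sequences[[1L]])
  cl <- annotate_domains(assemble_clusters(hit_for("cdps1"), orfs)[[1L]],
                         lib2)
  hits <- cl$domain_hits[cl$domain_hits$orf_id == "tl1", ]
  expect_gte(nrow(hits), 2L)              # all hits logged
  expect_equal(sum(hits$primary), 1L)     # one primary
  expect_equal(hits$domain[hits$primary],
               hits$domain[which.max(hits$bitscore)])
})

test_that("co-occurrence tallies count unique clusters", {
  mk_cl <- function(id, doms) {
    structure(list(cluster_id = id, domain_hits = data.frame(
      orf_id = paste0(id, seq_along(doms)), domain = doms,
      category = "cdps_tailoring", bitscore = 50,
      primary = TRUE, stringsAsFactors = FALSE)),
      class = "gene_cluster")
  }
  cls <- list(mk_cl("c1", c("AlbA", "CYP121")),
              mk_cl("c2", c("AlbA", "CYP121")),
              mk_cl("c3", "AlbA"))
  m <- tally_cooccurrence(cls)
  expect_equal(m["AlbA", "CYP121"], 2L)
  expect_equal(m["AlbA", "AlbA"], 3L)     # per-domain cluster frequency
  expect_equal(m["CYP121", "CYP121"], 2L)
  expect_true(isSymmetric(m))
  expect_equal(dim(tally_cooccurrence(list())), c(0L, 0L))
})

test_that("cluster GFF3 export nests members under the cluster feature", {
  sim <- w_survey()
  hmm <- w_family_hmm()
  orfs <- call_orfs(sim$genomes[["genome002"]], 60L)
  hits <- detect_cdps(hmm, stats::setNames(orfs$protein, orfs$orf_id))
  cls <- lapply(assemble_clusters(hits, orfs), annotate_domains,
                library = w_domain_library())
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_cluster_gff(cls, tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  parent <- gr[mc$type == "biosynthetic_gene_cluster"]
  expect_length(parent, 1L)
  kids <- gr[mc$type == "CDS"]
  expect_true(all(vapply(S4Vectors::mcols(kids)$Parent, function(p)
    identical(as.character(p), cls[[1]]$cluster_id), TRUE)))
  # the CDPS child is flagged and the CYP121 annotation carried
  expect_true(any(S4Vectors::mcols(kids)$role %in% "CDPS"))
  expect_true(any(S4Vectors::mcols(kids)$domain %in% "CYP121"))
})

test_that("a synthetic survey reproduces the generator's domain truth", {
  sim <- w_survey()
  hmm <- w_family_hmm()
  lib <- w_domain_library()
  tc <- sim$truth_clusters
  # check the six distinct layouts (first cycle of genomes)
  for (g in sprintf("genome%03d", 1:6)) {
    orfs <- call_orfs(sim$genomes[[g]], 60L)
    hits <- detect_cdps(hmm, stats::setNames(orfs$protein, orfs$orf_id))
    cls <- lapply(assemble_clusters(hits, orfs), annotate_domains,
                  library = lib)
    expect_equal(length(cls), tc$n_expected_clusters[tc$contig_id == g],
                 label = g)
    doms <- sort(unique(unlist(lapply(cls, cluster_domains))))
    expect_equal(paste(doms, collapse = ","),
                 tc$domains[tc$contig_id == g], label = g)
  }
})
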