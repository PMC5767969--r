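test_that("exact dereplication collapses duplicates, keeps first ids", {
  seqs <- c(a = "MKLV", b = "MKLV", c = "MKLX", d = "MKLV", e = "MKLX",
            f = "MWWW")
  dd <- dedup_exact(seqs)
  expect_equal(names(dd$representatives), c("a", "c", "f"))
  expect_equal(dd$members$a, c("a", "b", "d"))
  expect_equal(dd$members$c, c("c", "e"))
  # every input id appears exactly once
  expect_setequal(unlist(dd$members), names(seqs))
  # idempotent
  dd2 <- dedup_exact(dd$representatives)
  expect_equal(dd2$representatives, dd$representatives)
  # all distinct: identity mapping
  ddu <- dedup_exact(c(x = "AA", y = "CC"))
  expect_equal(lengths(ddu$members), c(x = 1L, y = 1L))
})

test_that("planted duplicate groups are recovered from the survey", {
  sim <- w_survey()
  cdps <- sim$truth_genes[sim$truth_genes$role == "cdps", ]
  seqs <- stats::setNames(cdps$protein, cdps$orf_id)
  dd <- dedup_exact(seqs)
  # duplicated genomes contribute no new representative
  dup_ids <- cdps$orf_id[grepl("_dup", cdps$orf_id)]
  expect_false(any(dup_ids %in% names(dd$representatives)))
  expect_equal(length(dd$representatives), length(unique(cdps$protein)))
})

test_that("greedy identity clustering honours its threshold", {
  # two sequences differing at 1 of 100 positions cluster at 0.9
  base <- random_peptide(100L, seed = 41L)
  v <- strsplit(base, "")[[1]]
  v[50L] <- setdiff(AA20, v[50L])[1L]
  near <- paste(v, collapse = "")
  cl <- cluster_at_identity(c(s1 = base, s2 = near), 0.9)
  expect_length(cl, 1L)
  # threshold 1.0 equals exact dedup on duplicate-free inputs
  cl2 <- cluster_at_identity(c(s1 = base, s2 = near), 1.0)
  expect_length(cl2, 2L)
  # a synthetic family at ~85% mutual identity is all singletons at 0.9
  fam85 <- gen_family(family_spec(length = 200L, n_sequences = 6L,
                                  mutation_rate = 0.08, seed = 51L))
  cl3 <- cluster_at_identity(fam85$sequences, 0.9)
  expect_length(cl3, 6L)
  # ...and one cluster at a permissive threshold
  cl4 <- cluster_at_identity(fam85$sequences, 0.6)
  expect_length(cl4, 1L)
})

test_that("cluster count is monotone in the identity threshold", {
  sim <- w_survey()
  cdps <- sim$truth_genes[sim$truth_genes$role == "cdps", ]
  seqs <- dedup_exact(stats::setNames(cdps$protein, cdps$orf_id))$representatives
  n_at <- vapply(c(1.0, 0.95, 0.9, 0.8),
                 function(th) length(cluster_at_identity(seqs, th)), 0L)
  expect_true(all(diff(n_at) <= 0L))
})

test_that("pairwise E-values: self-hit deep, random shallow, db-linear", {
  prot <- seed_sequences(w_family()$alignment)[[1L]]  # 240-residue CDPS-like
  self <- pairwise_evalue(prot, prot, db_size = 100L)
  expect_lt(self$log10_evalue, -100)
  # independent random 250-mers are insignificant
  set.seed(61)
  logs <- vapply(1:25, function(i)
    pairwise_evalue(random_peptide(250L, seed = 2 * i),
                    random_peptide(250L, seed = 2 * i + 1L))$log10_evalue, 0)
  expect_gt(stats::median(logs), -3)
  expect_gt(mean(logs > -3), 0.9)
  # doubling db_size doubles the E-value exactly
  e1 <- pairwise_evalue(prot, prot, db_size = 50L)
  e2 <- pairwise_evalue(prot, prot, db_size = 100L)
  expect_equal(e2$log10_evalue - e1$log10_evalue, log10(2))
})

test_that("the network separates planted families into components", {
  famA <- gen_family(family_spec(length = 240L, n_sequences = 4L,
                                 mutation_rate = 0.03, seed = 71L))
  famB <- gen_family(family_spec(length = 240L, n_sequences = 4L,
                                 mutation_rate = 0.03, seed = 72L))
  seqs <- c(stats::setNames(famA$sequences, paste0("A", 1:4)),
            stats::setNames(famB$sequences, paste0("B", 1:4)))
  net <- build_network(seqs, threshold = 1e-100)
  expect_length(unique(net$components), 2L)
  expect_length(unique(net$components[paste0("A", 1:4)]), 1L)
  expect_false(net$components[["A1"]] == net$components[["B1"]])
  # no self loops, all edges within threshold
  expect_false(any(net$edges$a == net$edges$b))
  expect_true(all(net$edges$log10_evalue <= -100))
  # identical pair: one edge, one 2-node component
  two <- build_network(c(x = famA$sequences[[1]], y = famA$sequences[[1]]))
  expect_equal(nrow(two$edges), 1L)
  expect_equal(unname(two$components), c(1, 1))
  # empty input: empty network
  empty <- build_network(stats::setNames(character(), character()))
  expect_equal(nrow(empty$edges), 0L)
})

test_that("edges are order-invariant and threshold-monotone", {
  fam <- gen_family(family_spec(length = 200L, n_sequences = 5L,
                                mutation_rate = 0.05, seed = 81L))
  seqs <- fam$sequences
  n1 <- build_network(seqs)
  n2 <- build_network(rev(seqs))
  key <- function(n) {
    e <- n$edges
    sort(paste(pmin(e$a, e$b), pmax(e$a, e$b)))
  }
  expect_equal(key(n1), key(n2))
  # more stringent threshold never adds edges
  n3 <- build_network(seqs, threshold = 1e-150)
  expect_true(all(key(n3) %in% key(n1)))
})

test_that("families are named from architecture, genus, and component", {
  fam <- gen_family(family_spec(length = 240L, n_sequences = 3L,
                                mutation_rate = 0.02, seed = 91L))
  net <- build_network(fam$sequences)
  info <- data.frame(id = names(fam$sequences),
                     architecture = "CDPS+CYP121",
                     genus = c("Streptomyces", "Streptomyces", "Nocardia"),
                     stringsAsFactors = FALSE)
  famnames <- name_families(net, info)
  expect_equal(unique(famnames$family), "CDPS+CYP121|Streptomyces|c1")
  # singleton with no metadata: named by component, with a warning
  net1 <- build_network(c(z = fam$sequences[[1L]]))
  expect_warning(f1 <- name_families(net1, info[0, ]), "no mapped cluster")
  expect_equal(f1$family, "c1")
  # component partition covers every node exactly once
  expect_setequal(famnames$id, names(fam$sequences))
})

test_that("network export writes edge list, node table, and GraphML", {
  fam <- gen_family(family_spec(length = 200L, n_sequences = 3L,
                                mutation_rate = 0.02, seed = 95L))
  net <- build_network(fam$sequences)
  pre <- file.path(withr::local_tempdir(), "net")
  paths <- write_network(net, pre)
  expect_true(all(file.exists(paths)))
  edges <- utils::read.delim(paths[1L])
  expect_equal(nrow(edges), nrow(net$edges))
  nodes <- utils::read.delim(paths[2L])
  expect_setequal(nodes$id, net$nodes)
  expect_true(any(grepl("graphml", readLines(paths[3L], n = 3L))))
})
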