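test_that("Viterbi equals exhaustive path enumeration on toy models", {
  for (trial in 1:20) {
    hmm <- toy_profile(seed = trial, ncol = sample(2:6, 1L),
                       nrow = sample(2:6, 1L), gap_p = 0.3)
    prot <- random_peptide(sample(2:8, 1L), seed = 1000L + trial)
    expect_equal(score_protein(hmm, prot), oracle_viterbi(hmm, prot),
                 tolerance = 1e-12,
                 label = sprintf("trial %d", trial))
  }
})

test_that("build_profile emissions match hand-computed smoothed counts", {
  # a 10-row alignment whose first column holds 6 A, 3 C, 1 gap
  rows <- c("AK", "AK", "AK", "AK", "AK", "AR", "CK", "CR", "CK", "-K")
  hmm <- build_profile(seed_alignment(sprintf("s%02d", 1:10), rows),
                       gap_fraction_cutoff = 0.5, pseudocount_weight = 1)
  # (count + 1 * 1/20) / (9 + 1)
  expect_equal(unname(hmm$match_emissions[1L, "A"]), (6 + 0.05) / 10)
  expect_equal(unname(hmm$match_emissions[1L, "C"]), (3 + 0.05) / 10)
  expect_equal(unname(hmm$match_emissions[1L, "W"]), 0.05 / 10)
  expect_equal(sum(hmm$match_emissions[1L, ]), 1)
  # column 2: 8 K, 2 R over 10 residues
  expect_equal(unname(hmm$match_emissions[2L, "K"]), (8 + 0.05) / 11)
})

test_that("gap trimming drops saturated and all-gap columns", {
  rows <- c("A-CA", "A-C-", "A--A", "A-CA")   # col2 all gap; col4 25% gap
  hmm <- build_profile(seed_alignment(letters[1:4], rows),
                       gap_fraction_cutoff = 0.5)
  expect_equal(hmm$n_states, 3L)
  expect_equal(hmm$columns_kept, c(1L, 3L, 4L))
  # a column gapped beyond the cutoff goes too
  hmm2 <- build_profile(seed_alignment(letters[1:4], c("AC", "A-", "A-", "A-")),
                        gap_fraction_cutoff = 0.5)
  expect_equal(hmm2$n_states, 1L)
  expect_error(build_profile(seed_alignment("x", "--")), "no columns")
})

test_that("single-sequence seed gives smoothed point masses (SYQ case)", {
  hmm <- build_profile(seed_alignment("syq1", "SYQ"), name = "SYQ")
  expect_equal(unname(hmm$match_emissions[1L, "S"]), (1 + 0.05) / 2)
  expect_equal(unname(hmm$match_emissions[1L, "A"]), 0.05 / 2)
  # a protein equal to the seed attains the model's maximum score
  self <- score_protein(hmm, "SYQ")
  set.seed(1)
  others <- vapply(1:50, function(i)
    score_protein(hmm, random_peptide(3L, seed = i)), 0)
  expect_true(all(others <= self + 1e-9))
})

test_that("build_profile is invariant to seed row order", {
  fam <- w_family()
  al <- fam$alignment
  set.seed(7)
  perm <- sample(length(al$ids))
  h1 <- build_profile(al)
  h2 <- build_profile(seed_alignment(al$ids[perm], al$aligned[perm]))
  expect_equal(h1$match_emissions, h2$match_emissions)
  expect_equal(h1$transitions, h2$transitions)
})

test_that("scores are bits: doubling background odds shifts one bit", {
  em <- matrix(c(0.5, rep(0.5 / 19, 19)), 1L, 20L,
               dimnames = list(NULL, AA20))
  tr <- lapply(stats::setNames(nm = c("mm", "mi", "md", "im", "ii", "id",
                                      "dm", "dd", "di")),
               function(x) 1/3)
  h1 <- profile_hmm("one", em, tr, background = rep(1 / 20, 20))
  h2 <- profile_hmm("one", em, tr, background = rep(2 / 20, 20))
  expect_equal(score_protein(h1, "A") - score_protein(h2, "A"), 1)
})

test_that("seed-derived cutoffs separate family from shuffled decoys", {
  fam <- w_family()
  hmm <- w_family_hmm()
  seqs <- seed_sequences(fam$alignment)
  self <- vapply(seqs, function(s) score_protein(hmm, s), 0)
  # margin 0: every seed at or above the cutoff
  h0 <- set_cutoff_from_seeds(build_profile(fam$alignment), seqs,
                              margin_bits = 0)
  expect_true(all(self >= h0$bitscore_cutoff))
  # default margin: cutoff strictly below the weakest seed
  expect_lt(hmm$bitscore_cutoff, min(self))
  # 100 shuffled decoys, none detected
  set.seed(11)
  decoys <- vapply(1:100, function(i)
    paste(sample(strsplit(seqs[[(i %% 20) + 1L]], "")[[1]]), collapse = ""),
    "")
  names(decoys) <- sprintf("decoy%03d", 1:100)
  expect_equal(nrow(detect_cdps(hmm, decoys)), 0L)
  # seed member among decoys -> exactly one hit, sorted by bitscore
  hits <- detect_cdps(hmm, c(decoys[1:10], seqs[3L]))
  expect_equal(hits$protein_id, names(seqs)[3L])
})

test_that("classification picks the argmax passing model, NYH-first ties", {
  fam <- w_family()
  subs <- w_subfamily_seeds()
  models <- lapply(names(subs), function(nm)
    set_cutoff_from_seeds(build_profile(subs[[nm]], name = nm),
                          seed_sequences(subs[[nm]])))
  nyh_seq <- seed_sequences(fam$alignment)[fam$truth$subfamily == "NYH"][2L]
  cl <- classify_subfamily(models, nyh_seq)
  expect_equal(cl$label, "NYH")
  expect_equal(names(which.max(cl$per_model_bitscores)), "NYH")
  # below every cutoff: unclassified
  expect_equal(classify_subfamily(models, "MKLV")$label, "unclassified")
  # constructed exact tie resolves by model order
  m <- models[[1L]]
  m1 <- m; m1$name <- "NYH"
  m2 <- m; m2$name <- "XYP"
  tie <- classify_subfamily(list(m1, m2), nyh_seq)
  expect_equal(tie$label, "NYH")
})

test_that("model JSON serialization round-trips scoring behaviour", {
  hmm <- toy_profile(seed = 3L, ncol = 5L, nrow = 4L)
  hmm$bitscore_cutoff <- 1.5
  tmp <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(list(hmm, toy_profile(seed = 4L)), tmp)
  back <- read_hmm_json(tmp)
  expect_length(back, 2L)
  prot <- random_peptide(12L, seed = 77L)
  expect_equal(score_protein(back[[1L]], prot), score_protein(hmm, prot))
  expect_equal(back[[1L]]$bitscore_cutoff, 1.5)
  expect_error(read_hmm_json(test_path("fixtures", "mini_synthetic.gbk")))
})

test_that("HMMER3 text models import and score sanely", {
  path <- test_path("fixtures", "toy_hmmer3.hmm")
  hmm <- read_hmmer3(path)
  expect_s3_class(hmm, "profile_hmm")
  expect_equal(hmm$n_states, 16L)
  # the consensus-like sequence the model was built from outscores noise
  cons <- "MKLVVGGHELVVKGHH"
  expect_gt(score_protein(hmm, cons),
            score_protein(hmm, random_peptide(16L, seed = 2L)))
})
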