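# Shared fixtures, built lazily once per test run.  Everything is
# deterministic (seeded), so caching cannot leak state between tests.

.world <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (is.null(.world[[key]])) .world[[key]] <- force(make)
  .world[[key]]
}

w_family <- function() memo("family", demo_family())

w_subfamily_seeds <- function() memo("subseeds", {
  fam <- w_family()
  sp <- split(seq_along(fam$alignment$ids), fam$truth$subfamily)
  out <- lapply(sp, function(ix)
    seed_alignment(fam$alignment$ids[ix], fam$alignment$aligned[ix]))
  out[c("NYH", "XYP", "SYQ")]
})

w_family_hmm <- function() memo("family_hmm", {
  fam <- w_family()
  set_cutoff_from_seeds(build_profile(fam$alignment, name = "CDPS"),
                        seed_sequences(fam$alignment))
})

w_refdb <- function() memo("refdb", demo_refdb(w_family()))

w_training <- function() memo("training", demo_training())

w_domains <- function() memo("domains", demo_domain_families())

w_domain_library <- function() memo("domlib",
                                    demo_domain_library(w_domains()))

w_bundle <- function() memo("bundle", {
  fam <- w_family()
  cdps_bundle(
    family_seed = fam$alignment,
    subfamily_seeds = w_subfamily_seeds(),
    ref_alignment = fam$alignment,
    reference_id = fam$alignment$ids[1L],
    pockets = DEMO_POCKETS,
    training = w_training(),
    domain_seeds = lapply(w_domains(), `[[`, "alignment"),
    domain_manifest = demo_domain_manifest())
})

w_survey <- function() memo("survey",
  gen_genomes(demo_survey_spec(), w_family(), w_domains()))

# small random toy profile for oracle tests: a gapped alignment over a
# reduced column count
toy_profile <- function(seed, ncol = 4L, nrow = 5L, gap_p = 0.2) {
  set.seed(seed)
  rows <- replicate(nrow, {
    r <- sample(AA20, ncol, replace = TRUE)
    r[stats::runif(ncol) < gap_p] <- "-"
    paste(r, collapse = "")
  })
  rows[1L] <- paste(sample(AA20, ncol, replace = TRUE), collapse = "")
  build_profile(seed_alignment(sprintf("t%02d", seq_len(nrow)), rows),
                gap_fraction_cutoff = 0.9, name = "toy")
}

random_peptide <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}
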