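#!/usr/bin/env Rscript
# Regenerates the packaged data files under inst/extdata from the demo
# world (all synthetic; rerunnable, byte-stable).  Run from the repo root
# with the package loadable.
suppressPackageStartupMessages(devtools::load_all("."))

out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

jsonlite::write_json(default_physchem_clusters(),
                     file.path(out, "physchem_clusters.json"),
                     pretty = TRUE)

fam <- demo_family()
write_fasta(stats::setNames(fam$alignment$aligned, fam$alignment$ids),
            file.path(out, "ref_alignment_synthetic.fasta"))

jsonlite::write_json(c(list(reference_id = fam$alignment$ids[1L]),
                       DEMO_POCKETS),
                     file.path(out, "pockets_synthetic.json"),
                     auto_unbox = TRUE, pretty = TRUE)

tr <- demo_training()
write_training_tsv(tr$P1, file.path(out, "training_P1_synthetic.tsv"))
write_training_tsv(tr$P2, file.path(out, "training_P2_synthetic.tsv"))

utils::write.table(demo_domain_manifest(),
                   file.path(out, "domain_manifest.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

utils::write.table(demo_known_compounds(),
                   file.path(out, "known_compounds_synthetic.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("wrote", length(list.files(out)), "files to", out, "\n")
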