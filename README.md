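# cdpsminer

Genome mining of cyclodipeptide synthases (CDPSs) and their products.

CDPSs are small bacterial enzymes that condense two aminoacyl-tRNAs into
a cyclodipeptide — a 2,5-diketopiperazine (DKP) scaffold that tailoring
enzymes in the surrounding gene cluster elaborate into products such as
albonoursin, pulcherriminic acid, and mycocyclosin. Linking a CDPS found
in sequence data to its chemical product normally requires expert manual
annotation. `cdpsminer` automates the chain for anyone mining prokaryotic
genomes for this compound class:

1. **Detection** — a profile HMM over the CDPS family, scored by Viterbi
   local alignment in bits (`build_profile()`, `detect_cdps()`); the
   detection threshold derives from seed self-scores.
2. **Subfamily classification** — competing NYH / XYP / SYQ subfamily
   models, argmax above per-model cutoffs (`classify_subfamily()`).
3. **Active sites** — the query is aligned to a fixed reference
   alignment and the residues in the columns of the AlbC-style reference
   P1/P2 pocket positions are read off (`call_active_site()`).
4. **Substrates** — a per-site naive Bayes classifier over pocket
   residue vectors, `P(aa | pockets) ∝ P(aa) · Π_i P(pocket_i | aa)`,
   Laplace-smoothed, log-space (`nb_train()`, `nb_predict()`).
5. **Clusters** — all ORFs within ±2.5 kb of a CDPS, overlapping windows
   merged, tailoring/resistance domains annotated with a packaged HMM
   library (`assemble_clusters()`, `annotate_domains()`).
6. **Structures** — the DKP scaffold is cyclized from the two predicted
   substrates and domain-licensed tailoring transforms are applied, with
   combinatorial enumeration of ambiguous sites; libraries are scored
   against known products by circular-fingerprint Tanimoto
   (`build_dkp()`, `apply_tailoring()`, `score_prediction()`).
7. **Networks** — dereplication, cd-hit-style identity clustering, and
   an E ≤ 1e-100 sequence similarity network with named
   connected-component families (`dedup_exact()`, `build_network()`).

A deterministic synthetic-data module (`gen_family()`, `gen_training()`,
`gen_genomes()`, and the `demo_*()` world) generates planted-truth
fixtures so everything is testable offline. See the methods vignette
(`vignettes/cdpsminer-methods.Rmd`) for models, parameter choices, and
limitations.

## Worked example

Scan one synthetic genome carrying a planted CDPS + CYP121 cluster:

```r
library(cdpsminer)

fam  <- demo_family()                       # 20-member CDPS family
doms <- demo_domain_families()              # tailoring-domain seeds
sim  <- gen_genomes(demo_survey_spec(n_genomes = 2), fam, doms)

sp <- split(seq_along(fam$alignment$ids), fam$truth$subfamily)
subseeds <- lapply(sp, function(ix)
  seed_alignment(fam$alignment$ids[ix],
                 fam$alignment$aligned[ix]))[c("NYH", "XYP", "SYQ")]

bundle <- cdps_bundle(fam$alignment, subseeds, fam$alignment,
                      fam$alignment$ids[1], DEMO_POCKETS, demo_training(),
                      lapply(doms, `[[`, "alignment"),
                      demo_domain_manifest())

res <- cmd_scan(list(sim$genomes[["genome002"]]), bundle,
                run_config(), "results_demo")
cl <- res$results[[1]]$clusters[[1]]
cd <- cl$cdps[[1]]
```

Output actually printed by this run:

```
hit: genome002_orf002 bitscore: 827.1
cluster: cluster_genome002_1 window: 0 3176
subfamily: NYH
P1: FYWLPAGT -> substrate F (posterior 1.00)
P2: YFWLAPGS -> substrate F (posterior 1.00)
domains: CYP121
compounds:
                                       smiles provenance
1 C2(C1Cc4c(-c3c(CC(C(N1)=O)N2)cccc3)cccc4)=O     CYP121
2      C3(C(Cc1ccccc1)NC(C(Cc2ccccc2)N3)=O)=O
```

Reading this: the CDPS at ORF 2 scored 827 bits against the family
model; its cluster spans 0–3176 bp; it belongs to the NYH subfamily; the
eight residues lining each substrate pocket predict phenylalanine at
both sites (posterior 1.0 on this separable fixture); the neighbouring
gene matches the CYP121 aryl-coupling oxidase, so the predicted library
holds the plain cyclo(Phe-Phe) DKP plus its intramolecular aryl–aryl
coupled derivative.

Validation-style summaries (leave-one-out detection sensitivity,
subfamily accuracy, active-site accuracy, strict/relaxed substrate
accuracy with fold enrichment) come from `cmd_validate()`; a similarity
network over scan results from `cmd_network()`. A command-line wrapper
lives at `inst/cli/cdpsminer.R` (subcommands `build-models`, `scan`,
`network`, `simulate`).

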