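# demo_world: the package's canonical synthetic dataset.  These defaults
# are the desk-scale analogue of the pipeline's published validation
# inputs: a CDPS family with NYH/XYP/SYQ subfamilies in 13:6:1 proportion
# (the degenerate single-member SYQ mirrors the real subfamily built from
# one sequence), 5% per-site divergence, a 60-example substrate training
# table over 12 classes, and tailoring-domain families for the packaged
# domain library.  Everything is a pure function of its seed.

#' Pocket positions of the demo reference CDPS
#'
#' Eight P1 and eight P2 positions (1-based indices on the demo reference
#' sequence), the synthetic stand-in for curated pocket annotations.
#' @export
DEMO_POCKETS <- list(P1 = c(60L, 65L, 70L, 120L, 125L, 130L, 180L, 185L),
                     P2 = c(75L, 80L, 85L, 140L, 145L, 150L, 200L, 205L))

# 12 substrate classes with distinct 8-residue pocket signatures
DEMO_SIGNATURES <- list(
  P1 = c(L = "LIVAFGWS", F = "FYWLPAGT", W = "WFYHKRDE", Y = "YFWStNQH",
         A = "AGSTVLIc", E = "EDQNKRHS", C = "CSTAGPVm", S = "STNQAGCY",
         P = "PGAVLSTF", K = "KRHEDQNS", V = "VILAMGST", G = "GASPVCTN"),
  P2 = c(L = "IVLAGFWT", F = "YFWLAPGS", W = "FWYHRKED", Y = "FYWSTNQG",
         A = "GASTVLIC", E = "DEQNRKHT", C = "SCTAGPVM", S = "TSNQAGCW",
         P = "GPAVLSTY", K = "RKHEDQNT", V = "IVLAMGSC", G = "AGSPVCTQ"))

fix_sig_case <- function(x) toupper(x)

#' The demo CDPS family (subfamilies and pocket truth planted)
#'
#' 20 sequences of 240 residues at 5% per-site divergence from a random
#' consensus; subfamily motifs N-Y-H / A-Y-P / S-Y-Q at positions
#' 30-32; subfamily sizes 13 (NYH), 6 (XYP), 1 (SYQ); pocket positions
#' `DEMO_POCKETS`, substrate classes cycling through the 12 demo
#' signatures.
#'
#' @param seed RNG seed
#' @param n_sequences family size
#' @param mutation_rate per-site substitution rate
#' @return a [gen_family()] result
#' @export
demo_family <- function(seed = 101L, n_sequences = 20L,
                        mutation_rate = 0.05) {
  sizes <- round(n_sequences * c(NYH = 13, XYP = 6, SYQ = 1) / 20)
  sizes["NYH"] <- n_sequences - sizes["XYP"] - sizes["SYQ"]
  classes <- lapply(names(DEMO_SIGNATURES$P1), function(cl)
    list(P1 = fix_sig_case(DEMO_SIGNATURES$P1[[cl]]),
         P2 = fix_sig_case(DEMO_SIGNATURES$P2[[cl]])))
  names(classes) <- names(DEMO_SIGNATURES$P1)
  gen_family(family_spec(
    length = 240L, n_sequences = n_sequences,
    mutation_rate = mutation_rate,
    motif_positions = c(30L, 31L, 32L),
    subfamily_motifs = c(NYH = "NYH", XYP = "AYP", SYQ = "SYQ"),
    subfamily_sizes = sizes,
    pocket_positions = DEMO_POCKETS,
    pocket_classes = classes,
    seed = seed))
}

#' Reference database over the demo family
#'
#' The first family member plays the AlbC role (the structurally anchored
#' reference row); pocket indices are `DEMO_POCKETS` (the family is
#' generated without indels, so reference indices equal column indices).
#'
#' @param family a [demo_family()] result
#' @return a [reference_db()]
#' @export
demo_refdb <- function(family = demo_family()) {
  reference_db(family$alignment, family$alignment$ids[1L], DEMO_POCKETS)
}

#' Demo substrate training tables (both sites)
#'
#' 12 classes x 5 examples = 60 labeled pocket vectors per site, sampled
#' around the demo signatures.
#'
#' @param seed RNG seed
#' @param n_per_class examples per class
#' @param label_noise fraction of permuted labels
#' @param jitter per-position random-residue probability
#' @return list with `P1` and `P2` [training_set()]s
#' @export
demo_training <- function(seed = 202L, n_per_class = 5L, label_noise = 0,
                          jitter = 0.1) {
  out <- lapply(c(P1 = "P1", P2 = "P2"), function(site) {
    sig <- lapply(DEMO_SIGNATURES[[site]], fix_sig_case)
    gen_training(sig, n_per_class = n_per_class, label_noise = label_noise,
                 jitter = jitter, site = site,
                 seed = seed + (site == "P2"))
  })
  out
}

#' The packaged domain library manifest
#' @return data.frame `name`, `category`, `reaction_ref`
#' @export
demo_domain_manifest <- function() {
  data.frame(
    name = c("CYP121", "CDO_NOX", "AlbA", "Ndas_1145", "Ndas_1149",
             "Amir_4628", "NAT", "SULT", "GT1", "MFS"),
    category = c(rep("cdps_tailoring", 6L),
                 "generic_tailoring", "generic_tailoring",
                 "generic_tailoring", "resistance"),
    reaction_ref = c("CYP121", "CDO_NOX", "AlbA", "Ndas_1145",
                     "Ndas_1149", "Amir_4628", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Synthetic seed families for every domain model
#'
#' One independent 8-member, 150-residue family per domain (5% per-site
#' divergence), deterministic per domain name.  Synthetic stand-ins: real
#' tailoring-enzyme sequences are deliberately not shipped.
#'
#' @param seed base RNG seed
#' @return named list of [gen_family()] results
#' @export
demo_domain_families <- function(seed = 303L) {
  man <- demo_domain_manifest()
  fams <- lapply(seq_len(nrow(man)), function(i)
    gen_family(family_spec(length = 150L, n_sequences = 8L,
                           mutation_rate = 0.05,
                           motif_positions = c(10L, 11L, 12L),
                           seed = seed + i)))
  names(fams) <- man$name
  fams
}

#' The packaged domain library built over the synthetic seeds
#' @param families [demo_domain_families()] result
#' @return named list of [domain_model()]
#' @export
demo_domain_library <- function(families = demo_domain_families()) {
  build_domain_library(lapply(families, `[[`, "alignment"),
                       demo_domain_manifest())
}

#' The demo survey: 20 genomes exercising every cluster mechanic
#'
#' Layouts cycle through: a lone CDPS; CDPS + CYP121; CDPS + CDO_NOX;
#' two CDPSs 2.0 kb apart (merging into one cluster); two CDPSs 30 kb
#' apart (two clusters); CDPS + AlbA + Amir_4628.  A 20% duplicate
#' fraction exercises dereplication.
#'
#' @param seed RNG seed
#' @param n_genomes number of genomes before duplication
#' @param duplicate_fraction fraction of duplicated genomes appended
#' @return a [survey_spec()]
#' @export
demo_survey_spec <- function(seed = 404L, n_genomes = 20L,
                             duplicate_fraction = 0.2) {
  layouts <- list(
    list(n_cdps = 1L, tailoring = character(), gene_spacing_bp = 300L,
         strand = "+"),
    list(n_cdps = 1L, tailoring = "CYP121", gene_spacing_bp = 400L,
         strand = "+"),
    list(n_cdps = 1L, tailoring = "CDO_NOX", gene_spacing_bp = 500L,
         strand = "-"),
    list(n_cdps = 2L, cdps_spacing_bp = 2000L, tailoring = character(),
         gene_spacing_bp = 300L, strand = "+"),
    list(n_cdps = 2L, cdps_spacing_bp = 30000L, tailoring = character(),
         gene_spacing_bp = 300L, strand = "+"),
    list(n_cdps = 1L, tailoring = c("AlbA", "Amir_4628"),
         gene_spacing_bp = 350L, strand = "+"))
  survey_spec(n_genomes = n_genomes,
              duplicate_fraction = duplicate_fraction,
              layouts = layouts, seed = seed)
}

#' The five demo known cluster-compound pairs
#'
#' Structure-prediction validation panel: five clusters whose products
#' are known — the albonoursin-type bis-dehydro cyclo(Phe-Leu), the
#' pulcherriminic-acid-type di-N-oxide of cyclo(Leu-Leu), the
#' mycocyclosin-type coupled cyclo(Tyr-Tyr), and two plain DKPs.  Truth
#' SMILES are the package's own constructions of these products, verified
#' against an independent cheminformatics toolkit during development.
#'
#' @return data.frame `cluster_id`, `aa1`, `aa2`, `domains`
#'   (comma-separated), `smiles`
#' @export
demo_known_compounds <- function() {
  mk <- function(aa1, aa2, domains, pick = 1L) {
    lib <- apply_tailoring(aa1, aa2, domains = domains)
    tail_smi <- lib$smiles[lib$provenance != ""]
    if (length(tail_smi)) tail_smi[[pick]] else lib$smiles[[1L]]
  }
  data.frame(
    cluster_id = c("albonoursin", "pulcherrimin_precursor",
                   "mycocyclosin", "cyclo_WW", "cyclo_GG"),
    aa1 = c("F", "L", "Y", "W", "G"),
    aa2 = c("L", "L", "Y", "W", "G"),
    domains = c("AlbA", "CDO_NOX", "CYP121", "", ""),
    smiles = c(
      # albonoursin: both alpha,beta positions dehydrogenated (the third
      # rxn_dehydrogenate variant is the double application)
      write_smiles(rxn_dehydrogenate(build_dkp_mol("F", "L"))[[3L]]),
      mk("L", "L", "CDO_NOX"),
      mk("Y", "Y", "CYP121"),
      build_dkp("W", "W"),
      build_dkp("G", "G")),
    stringsAsFactors = FALSE)
}
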