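---
title: "cdpsminer: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cdpsminer: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cyclodipeptide synthases (CDPSs) are small bacterial enzymes that hijack
two aminoacyl-tRNAs and condense them into a 2,5-diketopiperazine (DKP),
the scaffold of a pharmacologically rich compound class (albonoursin,
pulcherriminic acid, mycocyclosin, nocazines). A CDPS gene rarely acts
alone: tailoring enzymes encoded within a few kilobases oxidize,
methylate, dehydrogenate, or couple the DKP into the final product.
`cdpsminer` turns a genome (or a set of called proteins) into: detected
CDPSs, their phylogenetic subfamily, the residues lining their two
substrate-binding pockets (P1 and P2), predicted substrates, the
surrounding gene cluster with tailoring/resistance annotation, predicted
product structures (with combinatorial libraries where a tailoring site
is ambiguous), and a sequence similarity network across surveys.

# Detection: profile HMMs scored by Viterbi

A profile is built from a seed alignment: columns with gap fraction
above 0.5 (default) are trimmed; surviving columns become match states
with emissions `(counts + w·q) / (n + w)` (pseudocount weight `w = 1`,
uniform background `q = 1/20`); transitions are estimated per column
with +1 smoothing. Seed sequences are weighted uniformly — Henikoff
weighting is deliberately omitted as the simplest defensible choice for
desk-scale seeds.

Scoring is best-path (Viterbi) *local* alignment in bits: a path enters
any match state with probability `1/k`, exits freely after any match
state, and flanking residues are emitted by the background (zero bits).
The architecture follows the Plan7 convention of excluding I↔D
transitions; the stored transition triples keep `id`/`di` fields (zero)
so serialized models have the documented shape. Choosing Viterbi over
Forward buys determinism and an exact independent oracle — the test
suite enumerates *every* path of toy models (≤ 6 states × ≤ 8 residues)
recursively and demands equality to 1e-12. Forward scoring could later
be added behind the same contract.

Detection cutoffs are not published for this enzyme family, so the
package derives them from the seeds. The original design default —
`cutoff = min(seed self-scores) − 10 bits` — was proven wrong during
implementation: a sequence withheld from its own profile loses tens of
bits relative to seeds that stay in the model (its private
substitutions hit pseudocount-only emissions), so a 10-bit margin fails
leave-one-out recovery *by construction* on any star-topology family,
while true decoys sit hundreds of bits lower. The shipped default is
therefore relative: `cutoff = min(seed self-scores) / 2`, which
separates both regimes with a wide moat; an explicit `margin_bits`
restores the fixed-margin behaviour. The policy in force is recorded in
serialized model metadata.

Subfamily calls (NYH / XYP / SYQ) take the highest-scoring subfamily
model among those passing their own cutoff, ties broken in fixed model
order (NYH first), matching the published tie policy for the one
recorded NYH/XYP tie. A subfamily whose seed has a single sequence (the
real SYQ case) yields a degenerate smoothed point-mass model; when that
lone sequence is withheld in LOOCV no model for the label exists and the
label is unrecoverable — the acceptance suite asserts exactly this 0%.

# Active sites: profile alignment to a fixed reference

The published procedure re-aligns each query together with the full
reference set and reads off the columns of the structurally anchored
reference CDPS (AlbC). Re-running a multiple aligner renumbers columns
between runs; `cdpsminer` instead aligns the query *to* the fixed
reference alignment (profile-to-sequence, full traceback), which keeps
reference columns immutable and results bit-reproducible. The contract —
report the query residues aligned to the annotated reference positions,
`-` when gapped — is unchanged.

Pocket definitions ship as a data file of reference-sequence indices
(8 positions per pocket by default) because the exact curated numbering
is not printed in our sources; the packaged file is a synthetic
stand-in (`pockets_synthetic.json`) and is fully configurable.
Accuracy scoring reports per-position breakdowns and an off-by-one
diagnostic (wrong residue that matches an adjacent pocket slot), the
shifted-alignment failure mode expected near divergent termini.

# Substrates: categorical naive Bayes

Per site (P1, P2), a naive Bayes classifier over 21 residue categories
(20 amino acids + gap) maps pocket vectors to substrate labels. Priors
are class frequencies; likelihoods are Laplace-smoothed with `alpha = 1`.
The reference implementation this mirrors defaults to *no* smoothing;
smoothing is required here because an unseen pocket residue must never
zero a posterior — a documented divergence. Posteriors are computed in
log space; ranking ties break alphabetically. Per-site models are
trained (matching the per-site accuracies the study reports); pooling is
possible by concatenating training tables.

Evaluation is strict (exact label) and relaxed (label within the same
physicochemical group). The published group table is cited but not
printed, so the package ships an editable stand-in partition:
{A,V,L,I,M}, {F,W,Y}, {S,T,N,Q}, {D,E}, {K,R,H}, {C}, {G}, {P}.
Relaxed accuracy can never be below strict accuracy (asserted as a
property). The overall accuracy is the arithmetic mean of the two
per-site relaxed accuracies — fed the study's printed 74.1 and 66.7 the
operation returns its printed 70.4, the one machine-checkable number.
Fold enrichment over "random expectation" is reported under two
baselines, uniform `1/K` and prior-matched `Σp²`, because the study does
not define its baseline; its printed 8.1×/7.3× imply a baseline near
1/12, consistent with the uniform policy over ~12 observed classes.

# Clusters and tailoring chemistry

Each detected CDPS seeds a window of ±2500 bp measured from the ORF
boundaries; overlapping windows merge (transitively), producing the
two-CDPS clusters the survey literature describes; ORFs overlapping the
window at all are members. Non-CDPS members are scored against a
packaged domain library — six cyclodipeptide tailoring enzymes
(CYP121, pulcherriminic-type N-oxygenase, AlbA, Ndas_1145, Ndas_1149,
Amir_4628) plus a small illustrative generic/resistance set (NAT, SULT,
GT1, MFS). All hits above a model's cutoff are logged; the best per ORF
is primary. Co-occurrence tallies count unique clusters, never member
genomes. The packaged seeds are *synthetic* families (so the package is
self-contained offline); real seed alignments drop in through the same
manifest format.

Structure prediction starts from the DKP scaffold (built for any of the
400 substrate pairs, proline closing onto its ring nitrogen) and applies
graph transforms keyed to annotated domains:

* CYP121 — intramolecular aryl–aryl C–C coupling; requires two aromatic
  side chains; the coupled carbon on each ring is chosen ortho to an
  oxygen-substituted ring atom (for tyrosine, the mycocyclosin
  regiochemistry), deterministically.
* N-oxygenase — N-oxide at both ring nitrogens (pulcherriminic type).
* AlbA — α,β-dehydrogenation at one or both residues; the site is
  ambiguous, so all placements are enumerated (cyclo(Phe-Leu) yields the
  two singles and the albonoursin-type double).
* Ndas_1149 — O-methylation of any free hydroxyl (one product per site).
* Amir_4628 — ring N-methylation, either or both NH.
* Ndas_1145 — lactim O-methyl ether at one amide plus N-methylation of
  the other nitrogen.

The exact regiochemistry of the two methyltransferases is not specified
in our sources; the rules above are curator-editable data, not code.
Libraries are deduplicated on canonical SMILES, ordered
lexicographically, capped at 64, and always retain the untailored
scaffold — tailoring is monotone (more domains, never fewer products).

No cheminformatics dependency exists in the supported R stack, so the
package implements a bounded SMILES subset parser, a CANGEN-style
canonicalizer, and an ECFP-style hashed circular fingerprint (radius 3,
2048 bits, pinned versioned hash). **Stereochemistry is deliberately not
emitted**: the fingerprints used for all scoring are stereo-insensitive,
so stereo descriptors would change no downstream number while adding
the largest defect surface in the module; stereo markers in inputs are
accepted and discarded. During development every frozen product
structure in the tests was verified chemically equivalent to hand-drawn
references with an independent toolkit (rdkit), and one live oracle
check remains in the suite. Prediction quality is scored as Tanimoto
between the truth structure and every library member; per-cluster
medians (mean of middle pair when even) are averaged across clusters
for the batch metric.

# Networks

Dereplication collapses exact duplicates (first-seen representative).
Identity clustering is the cd-hit greedy longest-first algorithm over
global alignment identity (matches / alignment length) without cd-hit's
word filters — the algorithmic behavior results depend on, minus the
heuristics. Pairwise significance replaces BLASTP with an internal
Smith–Waterman (BLOSUM62, gap open 11 / extend 1) converted by
Karlin–Altschul statistics, `E = K·m·n·db_size·e^(−λS)` with pinned
λ = 0.267, K = 0.041 — pinning matters because at a 1e-100 edge
threshold, version-dependent scoring would silently rewire the network.
E-values live in log10 space so the 1e-100 regime is exact. Edges are
undirected, self-loops excluded; families are connected components
named `architecture|genus|c<index>`.

# The synthetic world

The generator plants all truth it later grades against: a 20-member
CDPS family (240 residues, no indels) with subfamily sizes 13/6/1
mirroring the real 196/76/1 imbalance. Each subfamily is a clade: its
own consensus diverges from the family consensus at 15% of sites, and
members then accumulate 5% i.i.d. substitutions from their subfamily
consensus, with the signature triad re-imposed. The clade structure is
not optional realism — subfamilies distinguished *only* by a 3-residue
motif are unclassifiable in principle once subfamily seed sizes differ
(the larger subfamily's model wins on emission sharpness, ~0.15
bits/position × 240 positions, which dwarfs a 3-residue motif), whereas
the real subfamilies are phylogenetically distinct lineages. Further: 12 substrate classes with distinct 8-residue
pocket signatures; 60 training examples per site (the real table has
61); surveys of 20 genomes cycling six cluster layouts (lone CDPS,
CDPS+tailoring, two CDPSs at 2.0 kb — merged — and at 30 kb — split)
with 20% duplicated genomes. Back-translation uses fixed most-frequent
E. coli codons; proteins begin with a planted Met so genes carry a
start codon for the longest-ORF caller. Sequences evolve by
substitution only — no indels, no phylogeny, no composition bias — so a
green LOOCV establishes mechanical correctness of the rebuild-and-score
protocol, *not* field performance on real divergent CDPSs. The 2%-mutation
active-site LOOCV bound (≥ 0.9) is the one place the synthetic world is
deliberately made harder than the identity case.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, 1-based inclusive in
  GFF3; the conversion is a tested bijection.
* Ambiguity: `N` translates to `X`; `X` residues score as background
  (zero log-odds) in HMMs and are excluded from emission counts.
* Viterbi ties resolve toward match-continuation (envelope reporting
  may differ between equal-scoring paths; scores never do).
* The ORF caller reports, per stop-to-stop interval, the longest frame
  beginning ATG/GTG/TTG (initiator rendered M), table 11. It is a
  stand-in: externally called proteins/GFF are accepted and the caller
  is bypassed.
* All generators are pure functions of their spec including the seed;
  scan reruns are byte-identical.

# Known limitations

* Forward-algorithm scoring and E-value statistics for detection are
  not implemented (bitscore cutoffs only, as the detection contract
  requires).
* The greedy identity clustering is O(n²) alignments; fine for desk
  scale, not for 90k-genome surveys.
* The SMILES subset covers cyclodipeptide chemistry (organic subset,
  aromatics, charges, rings); it is not a general-purpose parser.
* Synthetic domain seeds mean domain annotations in the demo world are
  only meaningful within that world; users supply real seed alignments
  for production use.
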