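---
title: "Methods: genome-to-phenotype denitrification profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-to-phenotype denitrification profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Haloarchaea inhabit hypersaline, oxygen-poor environments, and many of them
respire nitrogen oxides through the denitrification chain
NO3- → NO2- → NO → N2O → N2, catalysed in order by respiratory nitrate
reductase (Nar), nitrite reductase (Nir), nitric oxide reductase (Nor) and
nitrous oxide reductase (Nos). Whether a species can run the whole chain,
and where its chain stops if not, is a genome-level question: the presence
or absence of the four marker enzymes determines a *theoretical* phenotype.
`halonitro` computes that phenotype for a cohort of proteomes and
summarises it at the taxonomic-family level.

The classification model is deliberately simple and fully enumerable:

* a species is a **potential denitrifier** when it encodes at least one of
  the four marker enzymes (`min_enzymes = 1`, configurable upward for
  stricter physiological definitions, under which single-enzyme genomes
  would not qualify);
* **completeness** is `non` / `partial` / `complete` for 0 / 1–3 / 4
  enzymes;
* the **end product** is the product of the most downstream enzyme present
  (Nar → nitrite, Nir → NO, Nor → N2O, Nos → N2). This rule reproduces
  every combination usually enumerated in genome surveys (Nar–Nir and
  Nir-only end in NO; Nar–Nir–Nor, Nar–Nor, Nir–Nor and Nor-only end in
  N2O) and extends deterministically to combinations such surveys do not
  list (e.g. {Nar, Nos} → N2); extrapolated rows carry a `rule_derived`
  flag so downstream users can treat them separately;
* species ending in NO or N2O are potential **gas emitters**; species
  carrying Nos are **N2 reducers** regardless of what else is present,
  since Nos presence is what defines the capacity to consume N2O.

All sixteen presence/absence combinations are asserted against brute-force
oracles in the test suite, including the contiguity check (`is_consecutive`,
true when the present enzymes occupy an unbroken interval of the chain;
empty profiles are contiguous by convention).

## Marker detection

Survey pipelines typically find candidate genes with a heuristic database
search and then accept matches above a percent-identity cutoff. `halonitro`
replaces the heuristic search with an exact, deterministic primitive: every
proteome sequence is globally aligned (Gotoh three-state dynamic
programming, implemented in C++) against every member of a reference panel
carrying one or more sequences per enzyme family (NarG, NarH, NirK, NirS,
Nor, NosZ). Decisions are made only on percent identity, never on the raw
score, so the scoring parameters (match +1, mismatch 0, gap open −10, gap
extend −1 per residue) are exposed but uncritical.

Numerical conventions, all of which are needed to make results exactly
reproducible:

* **Identity denominator.** Identity = matches / alignment columns,
  *excluding terminal gap overhangs*. A 300-residue domain aligned to a
  600-residue reference should not be halved in identity by the unmatched
  tail; excluding only the terminal overhangs (not internal gaps) achieves
  that without rewarding fragmentary alignments. Alternative denominators
  (query length, subject length) would be stricter; the chosen convention
  is the one the acceptance threshold was calibrated for.
* **Threshold.** A hit is accepted when identity ≥ 0.65, inclusive, and the
  comparison is made on the exact rational matches/columns with no
  pre-rounding — a homolog at exactly 65.0% is accepted.
* **Tie-breaks.** The traceback is deterministic (residue–residue columns
  preferred, then gaps in the subject, then gaps in the query; gap
  extension preferred over opening), and per (species, enzyme) the best hit
  is the highest identity with ties resolved by the lexicographically
  smaller protein id. The test suite verifies score and identity against an
  independently written dynamic-programming oracle on hundreds of short
  random pairs, and score equality against a second, external aligner.
* **Genetic context.** NarG is only counted when an accepted NarH hit lies
  on the same replicon within 2 ordinal gene positions (window
  configurable). This operationalises the manual practice of checking that
  the catalytic subunit sits in a plausible *nar* operon; haloarchaeal
  genomes contain other molybdopterin oxidoreductases that can resemble
  NarG in sequence, and some species known to reduce nitrate lack the NarH
  partner entirely — those are deliberately *not* called Nar-positive. A
  NarG gene id missing from the annotation table is an error rather than a
  quiet `FALSE`, because the two situations (verified absence vs broken
  bookkeeping) must not be conflated. The window default of 2 reflects
  that "adjacent" could reasonably mean strictly consecutive or
  same-operon-with-one-insertion; both interpretations are testable by
  changing one argument.
* **Nir typing.** NirK and NirS panels are disjoint; the accepted hit's
  panel family is the type. A single protein accepted by both panels is an
  ambiguity error (it would mean the panel itself cannot discriminate).

## Phylogeny

The 16S tree is neighbour joining on p-distances, re-implemented from first
principles so that every convention is explicit:

* **Distances** are raw mismatch proportions with *pairwise deletion*:
  columns with a gap or `N` in either sequence of a pair are excluded for
  that pair. No substitution-model correction is applied — NJ topology at
  within-class 16S divergences does not require one, and a model-free
  distance keeps the matrix assumption-free. A pair with no comparable
  columns is an error naming the pair.
* **Neighbour joining** follows the Saitou–Nei Q-criterion with the
  standard two-point branch-length formulas. Ties in Q are broken by the
  lexicographically smallest pair of cluster labels (a cluster is labelled
  by its smallest leaf label), which makes the output invariant to input
  ordering. Negative branch lengths are clamped to zero *without*
  redistributing the deficit to the sister edge: redistribution schemes
  change path lengths unpredictably, whereas clamping keeps every other
  edge exactly as estimated. On additive matrices no clamping triggers and
  the generating tree is recovered exactly (verified to 1e-9 over random
  trees with up to 8 leaves, and against an independent NJ implementation
  on random non-additive matrices).
* **Bootstrap** resamples alignment columns with replacement, alignment
  length preserved; the support of each internal edge of the *original*
  tree is the percentage of replicate trees containing the same leaf
  bipartition, rounded half-up to an integer. No consensus tree is built —
  supports annotate the single estimated topology, which is how such trees
  are usually presented. Replicate r seeds its own RNG substream with
  (seed + r) mod (2^31 − 1), so runs are reproducible and extending the
  replicate count does not change earlier replicates.
* **Rooting** places the root on the outgroup's pendant edge, split in
  half. Rooting changes no bipartition.

Multiple sequence alignment is accepted as input and not re-implemented: it
is a solved upstream problem (MUSCLE/MAFFT class tools), and none of the
decision rules here depend on how the alignment was produced.

## The synthetic-data generator

`generate_community()` exists so that every downstream stage can be tested
against known truth without any database access. It emulates the structure
of a genome-survey cohort:

* a family layout with per-family class mixes; the default is a
  four-family, 121-species cohort whose family sizes and
  non/partial/complete mixes follow the well-represented haloarchaeal
  families of the reference survey (e.g. 44 Natrialbaceae with a
  37.5/57.5/5 mix), with 17% of species lacking genomes (25/147);
* class counts within a family are allocated by **largest-remainder
  rounding**, so small families are exactly representable (4 species at
  25/50/25 give exactly 1/2/1);
* "partial" species draw a uniformly random non-empty, non-full subset of
  the four enzymes — all 14 such subsets occur in real cohorts, so none is
  privileged;
* true marker homologs are panel sequences mutated to a target identity
  (default 0.85) by substitutions at exactly `round(L·(1−t))` uniformly
  chosen positions; decoys are panel copies mutated to 0.30 by default.
  Because decoys descend from the panel itself, the acceptance threshold is
  genuinely exercised rather than trivially separating random strings;
  configurations with decoy identity above homolog identity are rejected at
  validation, since no threshold could separate them;
* the *narH* gene is placed immediately after *narG* in the gene order of
  every Nar-positive species;
* 16S sequences evolve along a random bifurcating tree under a uniform
  (Jukes–Cantor-style) substitution process, expected root-to-tip
  divergence 0.10 substitutions/site by default — within-class 16S
  divergence is of this order, and NJ on p-distances only needs the
  qualitative signal. No indels are simulated, so the sequences are aligned
  by construction.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: realistic amino-acid substitution
matrices (mutations are uniform over the 19 alternatives), indel evolution,
domain architecture, paralogs at intermediate identity, misannotation, or
rate heterogeneity across 16S sites. The recovery property the generator
underwrites is about the *decision machinery*: with homologs ≥ 5 points
above the threshold and decoys ≥ 10 points below, detection reproduces the
ground-truth profiles with zero errors. Real proteomes with homologs near
65% identity will be sensitive to the identity-denominator convention in a
way the synthetic cohort is not.

## The packaged cohort fixture

`load_cohort_fixture()` returns a 147-species synthetic cohort (122 with
genomes) whose *family-level* classification counts match a published
genome survey of the class *Halobacteria*: 36 non-, 71 partial and 15
complete denitrifiers overall, with the per-family splits (15/23/2
Natrialbaceae, 3/7/9 Haloarculaceae, 3/20/4 Haloferacaceae, ...). Since
such tables are family-marginal, the assignment of a particular enzyme
subset to a particular species is a free choice; the fixture's cohort-level
subset pool is pinned by the survey's end-product fractions instead — 11
NO-enders, 40 N2O-enders, one nitrate-only species and 34 Nos bearers among
86 denitrifiers — so that the emitter percentages (12.8/9.0, 46.5/32.8,
59.3, 39.5) recompute exactly. All nitrite reductases in the fixture are
NirK, matching the striking NirK-only observation in haloarchaea.

Percentages throughout the package are rounded half-up to one decimal and
always recomputed from integer counts and explicit denominators
(genome-available species, or potential denitrifiers — never total species,
which would silently include genomes nobody has examined). Survey reports
occasionally print derived percentages that cannot be recomputed from any
of their own printed counts; `halonitro` never caches or transcribes such
figures, so the gas-emitter union over genomes, for instance, is reported
as 41.8% (= 51/122), the value its components force.

## Problem sizes and runtime choices

The test suite and the acceptance script are sized to run comfortably on a
single CPU: oracle-equivalence alignments use ≤ 12-residue sequences (500+
random pairs), threshold-separation uses a 60-species community at
homolog/decoy identities 0.70/0.50, recovery uses 30 species at 0.85/0.30,
NJ exactness uses 50 (tests) / 25 (script) random trees of up to 8 leaves,
and bootstrap saturation uses an 8-taxon, 3,300-column alignment with 100
replicates. These sizes are the package's validation choices: the
properties being checked (exact DP equivalence, exact additive recovery,
exact class allocation) are size-independent, so small instances prove them
as well as large ones.

## Known limitations

* Presence of a gene is not expression: all phenotype calls are
  *potential* phenotypes. The package deliberately has no kinetic or flux
  component.
* Detection is percent-identity only — no profile HMMs, no E-values, no
  domain-architecture checks. Distant homologs below 65% identity are
  reported (as non-accepted best hits) but never counted.
* The NarH-adjacency rule is the only genetic-context check; *nir*/*nor*
  clustering, plasmid location and TAT-signal presence are out of scope.
* The NJ implementation targets cohorts of a few hundred 16S sequences;
  it is O(n^3) in pure R above the C++-backed alignment layer and is not
  meant for thousands of taxa.
* The fixture reproduces family-marginal counts, not the real per-species
  assignments; per-species agreement with any real cohort is neither
  claimed nor testable from the packaged data.
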