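---
title: "Homology-based miRNA precursor annotation with mirhom: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based miRNA precursor annotation with mirhom: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Canonical animal microRNAs are processed from ~60–120 nt precursor
hairpins: a stem–loop whose two arms carry the mature miR and its partner
miR\*. Homology search for such short, structured RNAs is difficult:
sensitive sequence searches (blastn, nhmmer, cmsearch) drown true homologs
in false positives, while the discriminating signal — a stable hairpin with
the matures in the right place, conforming to the family's conserved
structure — is invisible to a pure sequence search. `mirhom` therefore
separates *finding* candidates from *believing* them: a sensitive,
engine-agnostic homology stage proposes loci, and a structural validation
cascade decides which of them are credible canonical precursors.

## The workflow

1. **Homology acquisition.** Hits from up to three engines are ingested
   from their native tabular formats (BLAST outfmt 6, `nhmmer --tblout`,
   `cmsearch --tblout`) or, for blastn, produced by a live search. All
   coordinates are normalized at the parser to a single internal
   convention (0-based, half-open, explicit strand); minus-strand hits
   arriving as `from > to` are flipped once, at parse time.
2. **Per-engine filtering.**
   * pairwise/blast: E-value ≤ 0.01, HSP length ≥ 20 nt, query coverage
     ≥ 70% (all inclusive);
   * nhmmer: the model's own inclusion threshold plus E-value ≤ 0.01 (no
     coverage term);
   * covariance models: E-value ≤ 0.01, model coverage ≥ 70%, and
     bitscore > log2(2N) for genome size N — or the rescue rule
     nBit = bitscore/ge ≥ 0.32 when the family has a gathering cutoff ge.
3. **Aggregation.** Hits on the same sequence and strand that share at
   least one nucleotide are merged transitively into extended regions
   (the union interval, with all supporting hits retained). Overlapping
   candidates on opposite strands are disambiguated by the engines'
   quality measures — higher bitscore, then lower E-value, then higher
   coverage; the loser is reported as `rejected_strand`, never silently
   dropped. Regions from different engines are then unified, and each
   family's list is capped at the 100 best bitscores; the overflow is
   reported as *potential* candidates for manual inspection.
4. **Mature placement.** Each family mature is aligned semi-globally
   (global in the mature, free ends in the precursor; match +1,
   mismatch −1, gap −2) against the candidate. The best placement wins if
   it reaches 0.6 × mature length; otherwise the candidate is rejected
   with *no mature anchor*. A miR\* without an annotated sequence is
   predicted as the window base-paired to the miR in the MFE structure.
   The candidate interval is then trimmed/extended to span miR and miR\*
   plus a 10 nt flank.
5. **Structural validation.** The trimmed precursor must be ≤ 200 nt and
   fold (RNAfold) to MFE ≤ −10 kcal/mol; the placement must be
   arm-consistent with the fold (one hairpin loop between the matures,
   loop overlap ≤ 3 nt, matures on opposite arms). Survivors are
   *accepted* and assigned a confidence from the family-consensus
   comparison: **High** iff the augmented consensus is still valid and
   its tree edit distance to the default consensus is ≤ 7, otherwise
   **Medium**.

Every candidate ends in exactly one of three buckets — accepted,
discarded (with a machine-readable reason), or potential — and the filter
log records each threshold with its observed value, so any decision can
be audited after the fact.

## Tree edit distance and the structure encoding

Secondary structures are compared as ordered labeled trees: each base
pair is a `P` node containing everything it encloses, each unpaired base
a `U` leaf, all under a virtual root `R`. This *full expansion* makes the
distance sensitive to loop and bulge size changes, which is what a
threshold as small as 7 implies. Distances are computed by the
Zhang–Shasha ordered tree edit distance with unit costs
(insert = delete = relabel = 1), implemented in C++; the test suite
checks it exhaustively against an independent brute-force forest
recursion on small trees and on randomized pairs, and verifies the metric
axioms.

## The consensus rule

The confidence decision compares the family's consensus structure with
and without the candidate. The candidate is threaded into the family
alignment anchored on an alignment row (flanks trimmed, candidate
insertions dropped), and the consensus of an alignment is defined as: an
SS_cons anchor pair survives iff a **strict majority of the distinct
rows** can form a Watson–Crick or GU pair at its two columns.

Two properties motivated this rule over delegating to an alignment folder
(an RNAalifold adapter is provided as an option):

* *Duplication invariance.* Distinct-row counting means an exact copy of
  a family member can never change the consensus, so a duplicate always
  yields ted = 0 and High confidence — a property sequence-weighted
  energy folding does not guarantee.
* *Determinism.* The rule is a pure function of the alignment, with no
  subprocess and no version sensitivity.

The strict majority (rather than ≥ 50%) makes the rule decisive on tiny
families: adding a conflicting candidate to a single-member family
removes every unsupported pair. A consensus is considered *valid* if it
still contains at least one hairpin loop and retains at least half of the
default consensus pairs.

## Arm consistency: why loops are counted within the mature span

The validation requires a single hairpin loop — but it counts loops
within the miR..miR\* span rather than over the whole trimmed precursor.
Trimming adds ~10 nt of genomic flank on each side, and a random flank
occasionally folds into a marginal 2–3 bp stem of its own; such a stray
hairpin outside the duplex says nothing about Drosha/Dicer plausibility
and would otherwise reject structurally perfect precursors. A genuinely
branched structure between the matures is still classified `multiloop`,
a mature across the loop `loop_overlap` (with a 3 nt tolerance, since
processing is not nucleotide-exact), and matures on one side `same_arm`.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `evalue` | 0.01 | — | engine E-value ceiling (all engines) |
| `coverage` | 0.70 | fraction | query/model coverage floor (blast, cm) |
| `min_hsp` | 20 | nt | blast HSP length floor |
| `nbit_factor` | 0.32 | — | gathering-cutoff rescue factor |
| `candidate_cap` | 100 | loci | per-family cap by bitscore |
| `max_precursor_length` | 200 | nt | precursor length ceiling |
| `mfe_threshold` | −10 | kcal/mol | fold stability floor (inclusive) |
| `ted_threshold` | 7 | edits | High/Medium confidence boundary |
| `flank` | 10 | nt | trim flank around miR/miR\* |
| `mature_score_floor` | 0.6 | × mature length | placement anchor floor |
| `loop_overlap_tolerance` | 3 | nt | allowed mature/loop overlap |
| `min_pair_retention` | 0.5 | fraction | consensus validity floor |

The MFE boundary is applied inclusively (accept at exactly −10); the
boundary behavior is exposed as `mfe_inclusive` since the literature
prints both conventions. The flank, scoring scheme and score floor of the
mature-placement stage are implementation choices of this simplified
mature-anchoring stage and are deliberately exposed in the configuration.

## The synthetic generator

All tests run against self-contained synthetic worlds:

* **Hairpins** are stem + loop + reverse complement (stem 25–45 pairs,
  loop 4–15 nt), with ~10% of stem positions perturbed into GU wobbles or
  single-base bulges; the miR is a 22-nt window on the 5' arm and the
  miR\* its construction partner. Every generated hairpin is verified by
  folding (MFE ≤ −10, valid arm placement) and regenerated otherwise.
* **Families** are five siblings (the hairpin ± 3 substitutions each),
  aligned trivially, with SS_cons set to the construction structure.
* **Decoys** are Altschul–Erikson dinucleotide shuffles of the hairpins —
  identical dinucleotide composition, destroyed base-pairing
  relationships.
* **Worlds** implant hairpins and decoys at non-overlapping uniform
  positions on random strands in an i.i.d.-uniform background genome
  (1 Mb, 20 + 20 by default) and emit the truth GFF3 plus emulated
  blast-tab6 hits covering every implanted locus, so the full cascade is
  exercised without any engine.
* **Mutation series** apply nested point-mutation loads (exactly k
  substituted positions, accumulating along the series).

All randomness comes from R's Mersenne-Twister stream; a fixed seed gives
byte-identical worlds. Limitations worth keeping in mind: the background
is i.i.d. uniform, not Markov — decoy hardness comes from the shuffled
hairpins, not from genome composition; there are no repeats, no isomiR
variation, and no evolutionary correlation between families. Passing
tests on these worlds demonstrate the mechanics of the cascade, not its
performance on real genomes.

## Problem sizes used in the checks

The routine test and verification runs use a 1 Mb world with 20 hairpins
and 20 decoys for the end-to-end recovery check, 20 independent hairpins
for the mutation series (loads 0–20% of positions), exhaustive tree-pair
enumeration up to 7 structure characters plus thousands of randomized
pairs up to 15 nodes for the edit-distance oracle comparison, and a few
hundred randomized hit sets for the merging/conservation properties.

## Known limitations

* **Point mutations rarely trip the absolute structural filters.** At
  10–20% mutation load the fold of a stable hairpin changes substantially
  — its tree edit distance to the original structure typically exceeds 7
  — yet RNAfold usually still returns a *single stable hairpin* (MFE well
  below −10), the mature anchors still align, and so the absolute filters
  (length, MFE, arm consistency) retain many such variants; rejection
  rates at that load are on the order of 10–25%, also for a real human
  let-7 precursor under the same protocol. Detecting that kind of
  divergence requires the family-level comparison (the consensus/ted
  stage, which here only modulates confidence) or covariance-model
  re-anchoring of the locus, which is outside this package's simplified
  mature-anchoring stage. The mutation series is therefore best read
  through the edit-distance lens, not the accept/discard lens.
* The consensus rule is a documented approximation: it can only remove
  SS_cons anchor pairs, never introduce compensatory new ones; a family
  whose true consensus drifted away from its SS_cons annotation will be
  scored against the annotation.
* Candidate insertions relative to the family alignment are dropped at
  threading; a candidate with a large novel insertion inside the hairpin
  is evaluated on its conserved columns only.
* cmsearch is consumed from `--tblout` files; the package does not build
  or calibrate covariance models.
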