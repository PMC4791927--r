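---
title: "Methods: fragment-based exhaustive synthesis of target-focused libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-based exhaustive synthesis of target-focused libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esynth)
```

## The model

`esynth` treats an organic molecule as a set of *rigid fragments* joined by
*flexible linkers*. The assumption is structural: the only bonds worth
severing and re-forming are genuine torsions, so the decomposition and the
synthesis operate on the same bond class and are inverse to one another.

**Rotatable bonds.** A bond is rotatable when it is (a) a single bond not
in a ring, (b) flanked on both sides by atoms with at least two heavy
neighbours (cutting next to a terminal atom creates no torsion), and
(c) not an amide C(=O)–N bond. This is the convention AutoDock-family
ligand preparation uses to assign ROOT/BRANCH blocks; we state it
explicitly because the decomposition inherits its semantics from that kind
of tooling. Under this rule the central bond of biphenyl *is* rotatable,
and toluene has no rotatable bond at all.

**Fragments.** After severing every rotatable bond, connected components
with ≥ 4 heavy atoms (configurable, `min_rigid_atoms`) and no rotatable
bonds become rigids; the remainder is linker material, and linker pieces
adjacent through a severed bond are re-merged into a single longer linker
(so carboxylic acid — three heavy atoms — is a linker, and a lone CH2 can
be one too). Every fragment is hydrogen-saturated at the severed positions
and keeps the SYBYL atom types it had in its parent. Supported chemistry
is the closed SYBYL set (C, N, O, P, S types and halogens); anything else
is rejected at input with a logged warning.

**Connectivity.** A rigid attachment atom stores the set of partner SYBYL
types it was originally bonded to; a linker atom stores how many bonds it
may form. Linkers come in two modes: *saturated* (capacity = hydrogens of
the saturated atom, i.e. all chemically possible bonds) and *unsaturated*
(only as many connections as were seen in parent molecules). Unsaturated
linkers shrink the search space dramatically, which is why benchmarking
defaults to them.

**Compose and levels.** A *k*-molecule is composed of *k* fragment
instances. `Compose(m1, m2)` enumerates every legal new single bond:
linker–linker bonds are forbidden, a rigid attachment accepts a partner
only if the partner's type is in its allowed set (rigid–rigid bonds need
mutual acceptance), and each bond consumes one hydrogen and one open
connection per side. New bonds are always single — only single bonds were
severed. Exhaustive synthesis completes level *k* (all products of level
*k* − 1 molecules with single fragments) before starting level *k* + 1, up
to `max_level`; completeness holds because any connected fragment assembly
has a fragment whose removal leaves a connected, valid intermediate, so
every product is reachable by single-fragment extension.

## Deduplication and completeness

Product identity is the Open Babel canonical SMILES (`can` output) of the
heavy-atom graph. We standardize on this single dialect everywhere: keys
are byte-comparable across the whole package, and a permutation stress
test (100+ random atom orders) guards the invariance.

Two design points deserve emphasis:

* **Intermediate states are not plain molecules.** Two isomorphic
  intermediates can carry different remaining-connection states and hence
  grow into different product sets. `synthesize_exhaustive()` therefore
  deduplicates *intermediates* by canonical key **plus** a canonical
  open-state signature (per-atom kind/count/allowed-set strings read in
  canonical atom order), and only the final output by plain key. Matching
  canonical order makes the signature sound: equal signatures imply a
  state-preserving isomorphism; unequal signatures for truly equal states
  merely cost a little extra work. The bounded variant instead follows the
  streaming design exactly — plain SMILES keys through Bloom filters — and
  is an under-approximation by construction (its output is always a subset
  of the exhaustive set).
* **Symmetry pruning.** `Compose` enumerates one attachment atom per
  symmetry class of the state-annotated graph (iterated Weisfeiler–Lehman
  colour refinement seeded with element, SYBYL type, charge, hydrogen
  count and open-connection state). Attaching at state-equivalent
  positions yields isomorphic products, so only representatives are
  tried. WL classes can in principle be coarser than true orbits, but not
  for the tree-plus-small-ring graphs this chemistry produces; the
  brute-force oracle test (20 random libraries, exact key-set equality)
  exercises precisely this assumption.

The same class-level reasoning drives consolidation: duplicate fragments
are aligned through the canonical atom ordering, and merged annotations
are spread across each symmetry class (union of allowed types for rigids,
per-atom maximum for linker counts). Without the class-level merge the
result would depend on which automorphism the canonicalizer happened to
pick per copy; with it, consolidation is provably independent of input
order and idempotent. For duplicate linkers with different original
connection patterns we take per-atom (per-class) maxima rather than
retaining the set of distinct patterns — the simpler choice; it can only
widen, never narrow, the unsaturated search space.

## Bloom filters

The bounded synthesizer streams canonical keys through one filter per
level plus a global filter (so the same SMILES reached with different
fragment counts is still redundant). Sizing uses the standard closed
forms b = −n·ln p/(ln 2)² and h = b·ln 2/n; at the printed design point
(n = 10⁸, p = 0.01) these give 9.585 × 10⁸ bits and h = 7 (6.64 rounds to
7 under nearest and ceiling alike; we use nearest). Defaults are
n = 10⁷ keys per filter at p = 0.01, configurable. Hashing is double
hashing over two independent polynomial string hashes (bases 131/137,
moduli two primes below 2³¹, exact in double arithmetic); h bit positions
per key, masks folded per byte so coincident positions are never lost.
Filters are plain in-memory bit arrays — no counting, no deletion, no
persistence.

## Drug-likeness

HBA is counted as N+O atoms and HBD as N–H/O–H groups (classic Lipinski
counting); MW comes from standard atomic weights; logP uses Open Babel's
atomic-contribution model so fragment estimates and whole-molecule values
stay commensurable. Raw estimates are fragment sums; they overshoot MW by
exactly 2 × 1.008 Da per formed bond (a mass-balance identity the tests
assert) and overshoot HBD because saturation hydrogens can donate. A
per-descriptor least-squares calibration maps estimates onto exact
values; the packaged default model is fitted on a 25-parent synthetic
panel (seed 1) by `scripts/fit-default-calibration.R` and shipped as JSON.
On that panel MW and HBA calibrate essentially perfectly (PCC 1.00), HBD
is the weak descriptor (PCC ≈ 0.67), and logP sits between (PCC ≈ 0.96) —
the same ordering reported for fragment-estimated descriptors at database
scale.

Filtering is staged. Before a candidate is expanded, only calibrated MW,
HBD and HBA are checked against the thresholds (modified cutoffs
MW ≤ 570, HBD ≤ 5, HBA ≤ 10, logP ≤ 7.2; classic 500/5/10/5 available);
logP is deliberately excluded from the gate because it is sign-indefinite
— attaching a hydrophilic moiety can pull a non-compliant intermediate
back into range — and is only applied to final products. All comparisons
are inclusive. Estimator quality is evaluated by rank-statistic ROC AUC
(ties 0.5), validated against exhaustive pair counting in the tests.

## Similarity and benchmarking

1D-TC is the Tanimoto of hashed path-based FP2 fingerprints; identical
fingerprints do not imply identical structures, which is precisely why
the cross-validation protocol rescores with a structural measure. 2D-TC
is |MCS| / (|a| + |b| − |MCS|) over heavy atoms of a maximum common
connected substructure found by exact backtracking search with
SYBYL-type-equal atom matching and adjacency-preserving extension, under
a configurable per-pair time budget (default 5 s); a timeout reports NA
rather than an underestimate. Clustering is deterministic greedy leader
clustering: compounds visited in sorted-canonical-key order join the
first cluster whose founder is within the TC threshold (default 0.7).
The original subset-selection tool's ordering heuristics are unpublished,
so fixing sorted-key order is our reproducibility choice.

The self-benchmark decomposes each active, synthesizes from its own
consolidated fragments (bounded, unsaturated linkers, level capacity
50000 — the capacity scale used in the tool's own command-line examples —
`max_level` 6), and reports the best product-to-parent 1D-TC; molecules
that are a single fragment cannot be decomposed, so no synthesis runs and
they count as failures. Cross-validation holds out each cluster, builds
the library from the rest, prefilters products at 1D-TC ≥ 0.5 (maximum
over products per held-out compound — the stricter reading), rescores
survivors by 2D-TC, and also reports the fraction of held-out compounds
whose rigid inventory was present at all (a conservative upper bound:
missing linkers or incompatible connectivity can still block rebuilding).

## The fixture generator

`make_fixtures()` assembles deterministic parents (2–6 fragments) from a
panel of four aromatic rigids and five small linkers, alternating
rigid/linker along a chain, with single-atom linkers only in bridging
positions so that every junction is a genuine torsion. Each draw must
(a) decompose back to exactly its generating kind/key multiset and
(b) pass the modified Rule-of-Five both exactly and in raw-estimate form
— by construction, every intermediate of a compliant parent then passes
the pre-synthesis gate, so reconstruction cannot be blocked by the
filter. The panel emulates the *structure* of drug-like actives
(aromatic cores, short flexible bridges, acid/sulfonamide decorations) at
desk scale. It does not emulate stereochemistry, charged species, fused
or macrocyclic ring systems, long high-connectivity linkers, or the
scale and redundancy of a real actives database — so passing benchmarks
demonstrate algorithmic correctness (exact reconstruction, containment,
determinism), not screening-scale recovery rates.

## Numerical and degenerate-input choices

* Valences: C 4; N 3 (+charge); O 2 (−charge); S {2, 4, 6}; P {3, 5};
  halogens 1. Saturation takes the smallest allowed valence that
  accommodates existing bonds; charged junction atoms keep their formal
  charge and are filled to the charge-adjusted valence (the protonation
  state of severed charged groups is genuinely ambiguous; we saturate to
  the neutral-H completion and document it here).
* A whole-molecule rigid has no attachment annotations and therefore can
  never bond — it passes through synthesis as its own 1-molecule.
* An empty compose result is a value, not an error; an empty library, a
  single-cluster cross-validation, or a single-class ROC input are
  errors.
* Wall-time expiry in the bounded synthesizer returns the partial result
  with a `truncated` flag instead of failing; `wall_time_limit = 0`
  yields exactly the level-1 set.
* Two fingerprint-empty molecules compare at TC 1 (documented FP2
  limitation).

## Problem sizes used by the shipped tests

Oracle-equivalence sweeps use 20 libraries of ≤ 4 fragments with ≤ 6 open
connections at `max_level` 3; the reconstruction benchmark uses the
10-parent fixture panel (seed 42); Bloom behaviour is checked with 10⁴–
5 × 10⁴ keys against the n = 10⁴, p = 0.01 design point. These sizes keep
every protocol exact (oracle comparisons are key-for-key) while the
worked example — two rigids, two linkers, parent regenerated at level 4 —
exercises the full pipeline end to end.

## Known limitations

Rings are never severed, stereochemistry is not tracked, and 3D geometry
is out of scope during synthesis (graphs only). The MCS is exact only
within its time budget; on large dissimilar pairs it reports NA.
Synthetic-accessibility scoring is a documented post-processing hook, not
implemented. Execution is serial by design: the chemistry-toolkit layer
is treated as a singleton resource, and the worklist contract would admit
a producer/consumer parallel mode that this package does not provide.
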