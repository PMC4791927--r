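# esynth

Fragment-based, graph-exhaustive synthesis of target-focused virtual
screening libraries in R.

Generic screening collections contain mostly compounds with a negligible
chance of binding any one protein target. A practical alternative is to
grow a *target-focused* library out of the ligands already known to bind
the target: decompose those actives into chemically meaningful building
blocks, then recombine the blocks into new molecules that stay inside the
pharmacologically relevant region of chemical space. `esynth` implements
that whole pipeline for organic, drug-like molecules:

* **Decomposition.** Every acyclic single bond that is a genuine torsion
  (both ends with ≥ 2 heavy neighbours, amide C(=O)–N excluded) is severed.
  Connected sets of ≥ 4 heavy atoms free of such bonds become **rigid
  fragments**; everything else becomes **linker** material, with adjacent
  linker pieces re-merged into longer linkers (a single atom can be a
  linker). Fragments are hydrogen-saturated and carry connectivity
  annotations: a rigid attachment atom records the SYBYL types of the
  partners it was bonded to; a linker atom records how many bonds it may
  form — either its saturated hydrogen capacity or only the connections
  observed in the parents ("unsaturated" mode).
* **Consolidation.** Identical fragments (same canonical SMILES within a
  kind) from different parents are merged into one library entry whose
  connection sets are unioned (rigids) or taken as per-atom maxima
  (linkers), with symmetry-equivalent atoms sharing the merged annotation.
* **Synthesis.** A *k*-molecule is a molecule built from *k* fragments.
  `Compose(m1, m2)` enumerates every legal single bond between open
  attachment atoms (linker–linker bonds prohibited; rigid attachments
  accept only listed partner types; each bond consumes one hydrogen per
  side). `synthesize_exhaustive()` completes level *k* before level
  *k* + 1 up to a user bound `MAX` and is provably complete on small
  instances; `synthesize_bounded()` adds per-level worklist capacities, a
  wall-time budget, Bloom-filter deduplication and a pre-synthesis
  drug-likeness gate, guaranteeing termination at scale.
* **Deduplication.** Canonical SMILES keys stream through one Bloom filter
  per level plus a global filter, sized analytically: a filter holding
  n = 10⁸ molecules at a 1 % false-positive rate needs
  b = −n·ln p/(ln 2)² = 9.585 × 10⁸ bits (~120 MB) and h = b·ln 2/n = 7
  hash functions. No false negatives, ever.
* **Drug-likeness.** Lipinski descriptors of a candidate are estimated
  additively from pre-computed fragment values, linearly calibrated, and
  gated against a modified Rule-of-Five (MW ≤ 570, HBD ≤ 5, HBA ≤ 10,
  logP ≤ 7.2); logP is only used on final products because intermediates
  can swing back into range.
* **Benchmarking.** A self-benchmark rebuilds each compound from its own
  fragments and scores the best FP2-fingerprint Tanimoto against the
  parent; a leave-one-cluster-out cross-validation (greedy leader
  clustering at TC 0.7) rebuilds held-out compounds from the fragments of
  chemically dissimilar ones, prefilters products at 1D-TC ≥ 0.5 and
  rescores survivors with a maximum-common-substructure 2D-TC. A
  deterministic fixture generator supplies Rule-of-Five-compliant
  multi-fragment parents so every protocol runs without external data.

Chemistry I/O (SDF/SMILES, canonical SMILES, SYBYL mol2 typing, FP2
fingerprints, atomic-contribution logP) is delegated to Open Babel via
ChemmineOB.

## Worked example

The classic four-fragment example: a parent assembling thiophene and
2,5-dimethylfuran rigids with sulfonamide and carboxylic-acid linkers.

```r
library(esynth)

parent <- smiles_to_molecule("Cc1oc(C)c(C(O)=O)c1NS(=O)(=O)c1cccs1", "parent")
dec <- decompose(parent)
dec
#> <decomposition> parent: 2 rigid(s), 2 linker(s), 3 junction(s)

lib <- consolidate(dec, linker_mode = "unsaturated")
res <- synthesize_exhaustive(lib, synthesis_config(max_level = 4,
                                                   linker_mode = "unsaturated"))
res
#> <synthesis> 15 unique molecule(s); per level: 1:4 2:3 3:5 4:3

synthesis_levels(res)[canonical_key(parent)]
#> Cc1oc(c(c1NS(=O)(=O)c1cccs1)C(=O)O)C
#>                                    4
```

The parent is regenerated exactly, first appearing at level 4 — one
instance of each of its four fragments. The three-atom C.3–C.3–N.3 linker
of the connectivity example reports its saturated capacity as

```r
lnk <- consolidate(list(new_fragment("linker", smiles_to_molecule("CCN"))),
                   linker_mode = "saturated")
max_connections(lnk$fragments[[1]])
#> [1] 7     # 3 on the terminal C.3 + 2 on the middle C.3 + 2 on the N.3
```

A command-line front end over the same functions is installed at
`inst/scripts/esynth.R`
(`esynth.R fragment | library | synth | filter | calibrate | fixtures | benchmark`).

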