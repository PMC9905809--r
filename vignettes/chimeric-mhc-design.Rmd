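---
title: "Designing chimeric MHC class I molecules on a fixed backbone"
author: "chimeraMHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing chimeric MHC class I molecules on a fixed backbone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraMHC)
```

## The model

A class I MHC heavy chain folds its first ~180 residues (the α1/α2 domains)
into two helices over a β-sheet floor: the peptide-binding groove. Peptides of
8–15 residues bind with their anchor side chains (typically P2 and P9) buried
in the B and F pockets, while T-cell receptors dock on top, contacting mostly
the helix faces. The package's working assumption — supported by contact
statistics over structure collections — is that the peptide-facing and
TCR-facing position sets barely overlap, so the groove of a *template* allele
can be grafted onto the TCR framework of a *base* allele by substituting only
groove residues. A second assumption is rigidity: the grafted groove is
evaluated on the template's backbone ("fixed-backbone" design), justified by
the observation that correctly designed chimeras bind their target peptide in
essentially the template conformation (sub-Ångström peptide-backbone overlay
RMSD).

The workflow, in order:

1. **Template preprocessing** (`preprocess_template`). The heavy chain is cut
   to its first `groove_span` residues (default 180) and renumbered from 1;
   the peptide is renumbered from 1; β2m, the α3 domain, waters and cofactors
   are removed. The 180-residue convention operationalises "the α1/α2
   domains"; templates with expression tags can skip leading residues.
2. **Surface classification** (`contact_frequency`, `classify_position`). A
   position contacts a partner in one structure when its minimum heavy-atom
   distance is ≤ 4 Å. Frequencies are percentages over the collection;
   positions with both peptide and TCR frequencies above 10% are PTB, single-
   partner contacts are PB or TB, and when both frequencies sit below the
   cutoff the larger one decides.
3. **Groove definition** (`define_groove`): template positions with a heavy
   atom within 5 Å of the peptide. Minimum distances are kept for *all*
   positions because the minimal-set stage re-tests PTB positions at 3.5 Å.
4. **Substitution construction** (`align_pair`, `build_substitutions`):
   global Needleman–Wunsch alignment (BLOSUM62, gap open 10, extend 0.5 — the
   defaults of the standard pairwise alignment service) maps template groove
   positions onto the base; each polymorphic groove position yields one
   base→template substitution, reported in base numbering (`"G62Q"` style).
5. **Exhaustive sampling** (`enumerate_variants`, `score_all`): all 2^N
   subsets of the substitution set are threaded and scored; variants are
   ranked by binding energy, ties by ascending mask integer.
6. **Enrichment and minimal set** (`enrichment`, `minimal_set`): over the top
   2.5% of variants (pool size `max(1, ceiling(0.025 M))`), the enrichment of
   a substitution is the fraction of pool members carrying it.

## The scoring stand-in

The reference workflow delegates threading, relaxation and interface-energy
analysis to an external all-atom suite. This package deliberately replaces
that stage with a deterministic residue-class contact potential so that the
combinatorial stage is dependency-free, desk-scale and exactly testable; this
is the package's single largest design departure and the adapter contract
(`make_command_scorer`) restores the external route for users who have an
all-atom scorer installed — per-variant failures are recorded and skipped,
and identical scores produce identical downstream rankings.

The potential acts on one interaction center per residue: the Cβ atom when
present, Cα for glycine, otherwise an ideal Cβ rebuilt from N/CA/C (bond
1.53 Å, angles 110.5°, L-chirality). Center pairs within 8 Å score by the
class of the two residues — salt bridges (+/−) −2.0, like charges +2.0,
hydrophobic–hydrophobic −1.0, polar–polar and polar–charged −0.5,
hydrophobic–charged +0.5, everything involving Gly/Pro and hydrophobic–polar
0 — and pairs closer than 3 Å pay a +10 clash penalty. Binding energy sums
peptide×groove pairs; total energy adds intra-chain pairs at sequence
separation ≥ 3. Units are arbitrary: the method consumes rankings, never
absolute energies. Nonstandard residues (`X`, e.g. photolabile positions)
score zero everywhere — they are carried geometrically but never scored.

Because the backbone (and hence every center) is fixed, the binding energy is
*additive* over substituted positions, and the total energy adds at most
pairwise corrections where two substitutable positions fall in one contact
shell. `score_all` exploits this decomposition; the test suite proves it
bit-identical to naively re-threading every variant.

Two properties worth noting. First, locality: a substitution whose center
lies outside every peptide contact shell cannot change the binding energy,
so such "decoy" substitutions tie with the base and their enrichment is
driven purely by the deterministic tie-break (≈0.5 in large pools). Second,
directionality: placing an aspartate under a lysine anchor strictly lowers
the binding energy, which is the charge-complementarity logic the design
aims to capture.

Threading always uses the template (groove-allele) structure. The reference
description is ambiguous between threading onto the template and onto the
base; the template conformation is the design target — the peptide is wanted
in *that* pose — so it is the frame every variant is evaluated in.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| contact threshold | 4.0 | Å | classification contact frequencies |
| groove cutoff | 5.0 | Å | groove membership |
| PTB stringent distance | 3.5 | Å | minimal-set gate for dual positions |
| classification cutoff | 10 | % | PB/TB/PTB boundaries |
| top fraction | 0.025 | — | enrichment pool |
| θ_enrich | 0.5 | — | minimal-set enrichment threshold |
| energy contact cutoff | 8.0 | Å | center-pair interaction range |
| clash cutoff / penalty | 3.0 / +10 | Å / a.u. | steric veto |
| pseudocount α | 0.05 | — | PSSM regularisation |

A frequency exactly at the classification cutoff is neither "greater" nor
"less" than it; such boundary positions fall through to the larger-frequency
rule, and nonzero ties classify PB (peptide binding is the design target, so
ambiguity resolves toward the groove). Both choices are pinned by tests.

The minimal-set rule keeps a substitution when it changes chemical character
(charged for neutral or vice versa — always included) *or* its enrichment
reaches θ_enrich. The chemical partition is positive {K,R,H}, negative
{D,E}, polar {S,T,N,Q,Y,C}, hydrophobic {A,V,L,I,M,F,W}, special {G,P};
"class change" requires a charged class on at least one side. An optional
`exclude_similar` flag additionally drops same-class swaps regardless of
enrichment — the stricter reading of "similar residues excluded" — but the
default lets a strongly enriched conservative swap (e.g. Leu→Ile at 0.9)
survive, since high enrichment is direct evidence the variant pool wants it.
PTB positions are only ever substituted when they carry a heavy atom within
3.5 Å of the peptide, limiting collateral damage to the TCR surface.

θ_enrich = 0.5 sits halfway between the two informative extremes (a
substitution required by every low-energy variant scores 1, a destabilising
one 0) and above the ≈0.5 expectation of an energetically silent
substitution under the tie-break ordering, so silent swaps do not drift into
the minimal set by chance in small pools.

## Consensus, motifs and the TCR surface

`consensus_scores` maps each allele onto a reference frame by pairwise
global alignment (replacing a full multiple alignment — reporting is
reference-indexed anyway, and class I α1/α2 domains are indel-free in
practice) and reports the modal-residue frequency per position; variability
is 100 − consensus. Gaps leave the denominator rather than counting as a
21st state; a position covered by no sequence is `NA`, not 0.

`build_pssm`/`information_content` compute the standard Shannon logo
transform: `ic = log2 20 + Σ f log2 f` bits, heights `f × ic`. The package
computes logos from a user-supplied binder list; it performs no binding
prediction and no graphical rendering.

`tcr_surface_distance` is the p-distance over TB positions;
`nj_tree` runs standard Saitou–Nei neighbor joining (delegated to ape) and
clamps any negative branch to zero, moving the deficit to its sister branch
so total tree length is preserved. Neighbor joining is exact on additive
matrices — the tests exploit this with constructed trees — and is an
adequate, deterministic substitute for model-selection-based tree building
when the goal is similarity clustering of TCR surfaces.

## Synthetic fixtures: what they do and do not show

`make_toy_complex` builds idealised complexes: straight (zig-zag) Cα traces
at 3.8 Å spacing for groove, peptide and optional TCR chains, with
side-chain pseudo-atoms placed at *exactly* the planned contact distances
and machine-readable ground truth emitted alongside. The seed applies a
rigid transform only, so planted distances are exact under any seed and
identical specs produce byte-identical PDB output. `make_design_scenario`
plants a charge-complementary P9-lysine/Asp pocket plus an out-of-shell
decoy, with hand-computed variant energies as ground truth.

These fixtures emulate contact *geometry*, which is the only structural
property any implemented computation consumes. They do not emulate real
secondary structure, side-chain packing, backbone flexibility or the
statistics of real structure databases — so passing tests demonstrate the
correctness of the algorithms (counting, classification, alignment,
enumeration, decomposition, superposition), not the biological accuracy of
the contact potential on real complexes. Reproducing database-scale contact
maps or published substitution tables requires the corresponding PDB entries
and allele sequences as inputs; the functions accept them unchanged.

## Numerical choices and degenerate inputs

- Altloc records resolve to the highest occupancy (ties: first in file);
  insertion codes re-sequence a chain monotonically from its first residue
  number.
- Superposition pairs atoms by renumbered residue id + atom name, drops
  unpaired atoms pairwise with a warning, requires ≥ 3 fit atoms, and always
  returns a proper rotation (SVD with determinant correction).
- Groove cutoff 0 is an error (a degenerate groove means a misassigned
  peptide chain), cutoff ∞ returns every position.
- Enumeration is capped at 22 substitutions (~4M variants) for the in-memory
  scorer; larger sets should be pre-reduced or routed to an external scorer.
- Pool size rounds up (`ceiling`) with a floor of one variant; 512 variants
  at 2.5% give a pool of 13.
- Ties in modal residues break alphabetically; ties in variant energies
  break by ascending mask integer, making every stage deterministic.
- All energies are evaluated in double precision with no randomness;
  re-running a configuration is bit-identical, which the pipeline verifies
  by hashing its artifacts.

Problem sizes in the shipped tests and acceptance script are deliberately
desk-scale — grooves of 20–60 residues, substitution sets of ≤ 9, variant
spaces of ≤ 512 — chosen so every expected value is computable by hand or by
an independent brute-force loop within the suite itself.

## Known limitations

- The contact potential is a ranking heuristic, not a physical energy; it
  ignores rotamers, solvation, backbone strain and entropy. Absolute values
  are meaningless and only comparisons within one template are used.
- Fixed-backbone threading cannot capture groove plasticity; alleles whose
  grafted groove requires backbone adjustment will be scored on the wrong
  conformation (the external-scorer adapter is the escape hatch).
- Indels between template and base are handled by skipping gapped groove
  positions with a warning, not by modelling them.
- Classification inherits the composition of the structure collections the
  user supplies; disordered positions count as non-contacting, keeping
  denominators constant but deflating frequencies of flexible regions.

## A minimal session

```{r example, eval = FALSE}
s <- make_design_scenario(seed = 1)
res <- run_pipeline(s$model, s$base_allele,
                    groove_allele = s$groove_allele,
                    out_dir = tempdir(),
                    config = default_config(groove_span = 60))
substitution_string(res$minimal_set)   # "S30D": the planted anchor
```
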