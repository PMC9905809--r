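# chimeraMHC

Fixed-backbone design of chimeric MHC class I molecules in R.

## The problem

MHC class I (HLA) molecules present 8–15-mer peptides to T cells. The
heavy-chain positions that bind the peptide and those that contact the T-cell
receptor (TCR) form largely separate surfaces of the α1/α2 domain: across
collections of pMHC-I and pMHC-TCR structures, each of the first 180 heavy-chain
positions can be classified as peptide-only binding (**PB**), TCR-only binding
(**TB**) or dual peptide-TCR binding (**PTB**) from its 4 Å heavy-atom contact
frequencies, with a 10% cutoff separating the classes. Because the two surfaces
barely overlap, the peptide-binding groove of one allele (the *template*) can be
grafted onto the TCR-contact framework of another (the *base*), producing a
chimeric HLA that presents the template's peptide repertoire while keeping the
base's TCR surface — a tool for probing TCR cross-reactivity and for
peptide-centric receptor engineering.

This package implements that design workflow for structural immunologists:

1. **Preprocess** a template pMHC-I structure: retain the α1/α2 region (first
   180 residues, renumbered from 1) and the bound peptide; drop β2m, the α3
   domain, waters and cofactors.
2. **Classify** positions PB/TB/PTB from contact frequencies over structure
   collections, and measure per-position sequence consensus/variability over an
   allele set.
3. **Define the groove** as all template positions with a heavy atom within
   5 Å of the peptide, and build the base→template substitution set at
   polymorphic groove positions (global alignment, BLOSUM62, gap 10/0.5).
4. **Enumerate** all 2^N substitution combinations (N polymorphic groove
   positions → 2^N variants; e.g. 2^9 = 512), thread each chimeric sequence
   onto the fixed template backbone, and score its peptide:MHC binding energy.
5. **Rank** variants by binding energy and compute, over the top 2.5% pool, the
   per-position **enrichment score** — the fraction of low-energy variants
   carrying the template residue. Enrichment 1.0 marks substitutions required
   for binding; 0 marks destabilising ones.
6. **Reduce** to a minimal substitution set: chemistry-changing swaps (charged
   for neutral and vice versa) are always kept, others need enrichment ≥ 0.5,
   and PTB positions are only touched when they have a heavy atom within a
   stringent 3.5 Å of the peptide.

Scoring uses a deterministic residue-class contact potential evaluated on Cβ
interaction centers of the fixed backbone (salt bridges −2, like charges +2,
hydrophobic packing −1, clashes +10; arbitrary units — rankings, not physical
ΔG, drive the method). An adapter contract (`make_command_scorer()`) lets an
external all-atom scorer take over the energy stage variant by variant. The
package also provides peptide-specificity summaries (PSSM → Shannon
information content → logo heights) and TCR-surface phylogenetics (p-distance
over TB positions → neighbor-joining newick tree), plus deterministic
synthetic-complex generators with planted ground truth so the whole workflow
runs and is tested without any structure downloads.

## Worked example

The built-in design scenario plants a lysine anchor at peptide position P9
over a groove position that is aspartate in the template allele but serine in
the base, plus an energetically silent decoy substitution (Leu→Ile) outside
the contact shell:

```r
library(chimeraMHC)
s <- make_design_scenario(seed = 1)
res <- run_pipeline(s$model, s$base_allele, groove_allele = s$groove_allele,
                    out_dir = "demo", config = default_config(groove_span = 60))
res$substitutions
#>   position template_position from_aa to_aa min_dist class_change
#> 1       30                30       S     D      3.4         TRUE
#> 2       40                40       L     I      4.5        FALSE
as.data.frame(res$ranked)
#>   mask     label E_bind E_total
#> 1    1      S30D   -1.5    -1.5
#> 2    3 S30D+L40I   -1.5    -1.5
#> 3    0      base   -0.5    -0.5
#> 4    2      L40I   -0.5    -0.5
as.data.frame(res$enrichment)
#>   position from_aa to_aa score
#> 1       30       S     D     1
#> 2       40       L     I     0
substitution_string(res$minimal_set)
#> [1] "S30D"
```

Reading the numbers: introducing Asp at position 30 creates the
charge-complementary contact with the P9 lysine and lowers the binding energy
of every variant that carries it (−1.5 vs −0.5), so the two best-ranked masks
both contain `S30D` and its enrichment over the low-energy pool is 1.0. The
decoy `L40I` changes nothing energetically, ties are broken by mask order, its
enrichment in the default pool is 0, and the minimal set reduces to the anchor
substitution alone.

A command-line front end wraps the same functions
(`exec/chimeramhc preprocess | contacts | design | run | logo | tree |
fixtures`), reading structures from PDB/mmCIF, alleles from FASTA and
thresholds from a YAML config.

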