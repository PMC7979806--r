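---
title: "Methods: mapping cancer-associated PIKK mutations onto conservation and structure"
author: "pikkmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping cancer-associated PIKK mutations onto conservation and structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pikkmap)
```

## Scientific background

ATM and ATR are giant serine/threonine kinases of the PIKK family that
coordinate the DNA damage response; somatic mutations in either gene are
found across many cancer types. Because these proteins are 2,600–3,000
residues long, with 40–50 HEAT repeats (organized into spiral, bridge and
FAT regions) followed by a C-terminal kinase domain, the functional reading
of any individual missense change is rarely obvious. A productive strategy
is to triage the thousands of tumor-derived substitutions by asking three
questions in sequence:

1. **Where are they?** Catalog the mutations per gene and cancer type, and
   reduce them to the set of protein residues mutated to a different
   residue.
2. **Are they ancient?** Keep residues whose amino acid is conserved down
   to the budding-yeast orthologs Mec1 (the ATR ortholog) and Tel1 (the
   ATM ortholog); conservation over ~1 billion years of divergence is a
   strong prior for functional relevance.
3. **Where do they sit in the enzyme?** Map the conserved residues onto
   cryo-EM models of the dimeric enzyme complexes, classify them as
   solvent-exposed or buried, and test whether they concentrate in
   particular domains (e.g. the kinase domain, or regulatory motifs such
   as TRD3 and the PRD) or form spatial clusters suggestive of a binding
   interface.

pikkmap implements this pipeline end to end, together with a synthetic-data
layer that generates cohorts, ortholog families and toy structures with
known ground truth, so that every stage is validated offline.

## Mutation catalog

Input is the tab-separated export dialect used by cBioPortal-style cohort
browsers (`gene`, `sample_id`, `cancer_type`, `protein_change`; common
export headers such as `Hugo_Symbol` and `HGVSp_Short` are accepted as
synonyms). Protein changes are classified by a fixed grammar, applied in
order: a stop (`*`) or frameshift (`fs`) marks a truncation; `del`, `ins`
or `dup` without a frameshift an in-frame change; a single substitution
`[A-Z][0-9]+[A-Z]` with two distinct standard residues a missense change;
everything else (splice notation, unparseable strings) is *other* and
carries no position. This mirrors the consequence categories used by the
cohort browsers themselves.

Two conventions matter downstream and are fixed deliberately:

* **Per-gene frequency counts samples, not mutations.** A sample with
  three ATM mutations contributes once to the ATM frequency. The cohort
  size is a required input (samples without mutations are invisible in an
  export) and printed frequencies are rounded to one decimal, half-up.
* **Mutated-residue sets default to missense records.** "Mutated to a
  different residue" is a statement about substitutions; truncations and
  in-frame indels can be included through the `consequences` argument when
  a broader definition is wanted, because published per-residue counts do
  not always state which classes they include.

## Conservation calling

Residue correspondence between a human protein and an ortholog comes from
a global alignment. The package implements Needleman–Wunsch with affine
gap penalties (Gotoh's three-state recursion) in compiled code, with
BLOSUM62, gap open 10 and gap extend 1 as defaults. The gap convention
charges `open` for the first position of a gap run and `extend` for each
additional one, so a run of length $L$ costs $\mathrm{open} + (L-1)\,
\mathrm{extend}$. Traceback ties are broken deterministically
(substitution, then gap in the second sequence, then gap in the first) so
alignments are bit-reproducible. Externally computed multiple alignments
(Clustal or aligned FASTA) are accepted as authoritative when supplied;
the internal aligner is pairwise only, deliberately — re-implementing a
progressive MSA would add nothing the pipeline needs.

A residue is called **conserved** when the aligned column carries the
identical amino acid in at least one designated ortholog. This strict
identity rule matches how conservation is typically assessed manually for
individual residues; a similarity mode (positive BLOSUM score) exists but
is off by default, because "chemically similar" judgements vary between
matrices while identity does not.

Percent identity is reported under both common denominators (alignment
columns, and shorter-sequence length), since published identity figures
("~24% identity between Mec1 and ATR") rarely state their convention.
Correspondingly they are treated here as approximate context, never as
exact expectations.

## Structure mapping and solvent accessibility

PDB coordinate files (e.g. the cryo-EM models 5NPO for dimeric ATM, 5YZO
for ATR–ATRIP, 5X6O for Mec1–Ddc2) are parsed via bio3d: first MODEL only,
HETATM and waters dropped, hydrogens excluded by default, and among
alternate-location conformers the highest-occupancy one kept (ties resolve
to altloc A). Disordered stretches are inferred from gaps in the author
numbering and are always reported explicitly — a mutated residue falling
in a disordered loop is a finding, not a lookup failure. Author numbering
is assumed to equal protein numbering (true for the models above); a
per-chain integer offset covers other structures.

Solvent-accessible surface area uses the Shrake–Rupley method: each atom's
expanded sphere (van der Waals radius + 1.4 Å water probe) is sampled at
960 points placed on a golden-spiral lattice — a deterministic
construction, so SASA values are bit-stable across runs — and a point is
accessible when outside every other atom's expanded sphere. Van der Waals
radii are pinned to a Bondi-type set (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80, H 1.20 Å); unknown elements are an error unless a default radius
is supplied. Per-residue SASA is normalised by the residue type's
theoretical maximum accessible area (Tien-style Gly-X-Gly values) to give
relative SASA, and a residue is classified **surface** at relative SASA ≥
0.25. The threshold is configurable because "visible on the surface" in a
rendered figure is a qualitative criterion; 0.25 is a conventional
midpoint between common surface cutoffs. Burial is always computed in the
full assembly (both protomers of a dimer present), so a residue at the
dimer interface counts as buried — matching the biological question of
accessibility in the functional enzyme complex.

Distances default to Cα–Cα, with a minimum-heavy-atom mode alongside,
because published figure distances (e.g. a 15.7 Å separation between the
two S2339 residues of a Mec1 dimer) do not state the atoms measured.
Spatial clusters are single-linkage: connected components of the graph
joining residue pairs within a cutoff (24 Å default in the pipeline,
after the scale of reported surface-patch separations).

## Enrichment and overlap statistics

Domain enrichment compares the fraction of tested residues inside a domain
with the domain's share of protein length: with $k$ of $n$ residues in a
domain covering fraction $f$, the fold is $(k/n)/f$ and the headline
p-value is the exact one-sided binomial tail $P(X \ge k)$, $X \sim
\mathrm{Bin}(n, f)$ — computed by exact summation, never a normal
approximation. The binomial model treats residue positions as independent
draws; a hypergeometric alternative (sampling positions without
replacement from the finite protein) is reported whenever integer lengths
are supplied. No multiple-testing correction is applied by default, as
only a handful of pre-specified domains are ever tested; Benjamini–
Hochberg can be applied downstream when many domains are scanned.
Cancer-type specificity is reported descriptively (per-type residue sets
and their exact overlaps), not inferentially — the tissue comparison in
this design is exploratory.

## The synthetic-data layer

The generators define the validation conditions of the package and are
first-class, tested code.

**Cohorts.** A cohort spec plants per-cancer-type hotspot residues and
draws, for every sample, Bernoulli hits at its type's hotspots (always
missense, so hotspot recovery through the default residue-set filter is
exact) plus optional uniform background mutations with a configurable
consequence mix. The default validation cohort is three cancer types of
70/70/60 samples, five hotspots per type at per-sample probability 0.2,
and zero background — noiseless, so planted sets are recoverable exactly;
with ~65 samples per type the chance that any planted hotspot goes unhit
is below $10^{-5}$. The defaults are desk-scale deliberately: they
exercise every code path in seconds while keeping exact recovery a
meaningful test.

**Orthologs.** Divergence is simulated by substituting a computed number
of uniformly chosen unprotected sites so that realized identity lands
within one percentage point of the target; protected positions (the
"conserved core") are never touched and a substitution never reproduces
the original residue. Validation uses orthologs at 25% and 90% identity —
roughly the yeast and mouse ends of the real divergence spectrum.

**Toy structures.** Cα-only poly-alanine arrangements with geometric
burial ground truth: an ideal α-helix (rise 1.5 Å, 100°/residue, radius
2.3 Å; every residue surface) and a cubic-lattice ball grown site by site
outward from the origin, where a residue is ground-truth buried iff all
six lattice neighbors are occupied. The default lattice spacing is 4.5 Å,
chosen analytically so the six-neighbor rule is *exact* for the SASA
classifier rather than approximate: with expanded Cα spheres of radius
1.7 + 1.4 = 3.1 Å, face neighbors at 4.5 Å occlude (4.5 < 6.2) while
diagonal neighbors at 4.5·√2 ≈ 6.36 Å cannot (> 6.2), so occlusion comes
from face neighbors alone. Each present face neighbor then removes a
spherical cap of fraction $(1 - 4.5/6.2)/2 \approx 0.137$, putting a
six-neighbor residue at relative SASA ≈ 0.17 (buried) and a five-neighbor
residue at ≈ 0.30 (surface), cleanly separated by the 0.25 threshold. At
a protein-like 3.8 Å spacing the six-neighbor rule would *not* match any
threshold, because a single missing face neighbor opens only a narrow
channel; the spacing is therefore part of what makes the fixture's ground
truth valid, not a tuning knob.

**What the generators do not emulate:** mutational signatures, sequencing
noise, realistic indel processes in orthologs (indels are optional and
uniform), side chains, or cryo-EM coordinate error. Passing the recovery
tests therefore demonstrates correctness of the computational pipeline on
clean inputs — it does not validate biological conclusions drawn from any
particular real cohort or structure.

## Numerical and design choices

* Percentages print with one decimal, half-up (`floor(10x + 0.5)/10`),
  matching how cohort browsers print frequencies.
* The aligner's score and traceback are exact integers for integer
  matrices; the enumeration oracle in the test suite scores every
  monotone alignment path of short sequences independently.
* Degenerate inputs are first-class: empty catalogs produce zero-count
  reports, empty residue lists produce empty cluster tables, residues
  unresolved in a model are an explicit class excluded from denominators,
  and an all-unresolved subset flags its surface fraction as undefined
  rather than returning 0.
* The pipeline writes one TSV per result table plus a JSON summary whose
  every number also appears in a TSV; identical configurations produce
  byte-identical outputs.
* This package's command surface is its functions (`run_pipeline()` and
  the per-stage functions); no shell wrapper is shipped, since the
  intended use is scripted analysis from R.

## Validation scale and known limitations

The shipped validation runs at desk scale: 200-sample cohorts,
200-residue proteins, 960 sphere points, alignment oracles at sequence
lengths ≤ 8 and clustering oracles at ≤ 12 residues. These sizes were
chosen so the whole suite re-runs in well under a minute while every
oracle remains exhaustive or analytic.

Several published anchor values require external data and are therefore
documented as integration checks rather than tests: conserved-residue
counts over a real 46,588-sample cohort export (233 of 961 ATM and 147 of
746 ATR mutated residues conserved in yeast) need the cohort export and
NCBI sequences; inter-residue distances on deposited models (the 15.7 Å
S2339 pair) and surface counts from rendered figures ("~14 of 46")
additionally depend on measurement conventions the figures do not state;
and cross-species identity percentages depend on aligner parameters. The
package exposes both distance modes and both identity denominators so any
of these can be reproduced once the external inputs are in hand.

Further limitations: no mmCIF parsing, no superposition/RMSD, no
electrostatics, no rendering; the internal aligner does not build
progressive multiple alignments; and the enrichment model treats residues
as exchangeable, ignoring sequence autocorrelation of mutation rates.
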