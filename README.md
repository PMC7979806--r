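# pikkmap

Conservation and structural mapping of cancer-associated mutations in
PIKK-family kinases (ATM, ATR and their budding-yeast orthologs Mec1 and
Tel1).

## The problem

Tumor-sequencing cohorts report thousands of somatic mutations in ATM and
ATR, but these kinases are 2,600–3,000 residues long and the functional
impact of any one missense change is rarely obvious. A practical triage
runs in three steps: (1) reduce a cohort export to the set of protein
residues mutated to a different residue, per gene and per cancer type;
(2) keep the residues whose amino acid is identical in a deeply diverged
ortholog (yeast Mec1/Tel1), a strong prior for functional relevance; and
(3) map those residues onto cryo-EM models of the dimeric enzyme
complexes, classify them as solvent-exposed or buried, measure spatial
clustering, and test domain enrichment. pikkmap implements this pipeline,
plus a synthetic-data layer (cohorts with planted hotspots, orthologs
diverged to a target identity with protected cores, toy structures with
geometric burial ground truth) so the whole analysis is testable with no
downloads.

## Methods at the core

* **Catalog** — cBioPortal-style TSV ingestion; consequence grammar
  (missense / truncation / in-frame / other); per-gene frequency
  `100 · |samples with ≥1 mutation| / cohort size`, one-decimal half-up.
* **Conservation** — affine-gap Needleman–Wunsch (Gotoh three-state DP;
  BLOSUM62, gap open 10, extend 1, a gap run of length *L* costing
  `open + (L−1)·extend`), residue correspondence with strict
  monotonicity, conservation = identity in ≥1 designated ortholog.
* **Structure** — PDB parsing (bio3d) with explicit unresolved-gap
  tracking; Shrake–Rupley SASA on a deterministic golden-spiral lattice
  (960 points, probe 1.4 Å); relative SASA against theoretical per-residue
  maxima; surface iff relative SASA ≥ 0.25; Cα and min-heavy-atom
  distances; single-linkage clusters as threshold-graph components.
* **Stats** — fold enrichment `(k/n)/f_dom` with exact one-sided binomial
  tail `P(X ≥ k)`, hypergeometric alternative; exact residue-set overlaps.

See `vignettes/pikkmap-methods.Rmd` for the full model description,
parameter rationale and limitations.

## Worked example

```r
library(pikkmap)

# a synthetic 200-sample cohort with planted per-cancer-type hotspots
spec <- cohort_spec(gene = "ATM", protein_length = 3056, seed = 7)
sim  <- simulate_cohort(spec)
print(sim$catalog)
#> mutation_catalog: 189 records, 133 samples with a mutation, cohort size 200

fr <- gene_mutation_frequency(sim$catalog, "ATM")
sprintf("ATM mutation frequency: %d/%d samples = %.1f%%",
        fr$mutated_samples, fr$cohort_size, fr$frequency_pct)
#> "ATM mutation frequency: 133/200 samples = 66.5%"

# residues mutated in colorectal samples: exactly the 5 planted hotspots
mutated_residues(sim$catalog, "ATM", cancer_type = "colorectal")
#>   gene position cancer_types n_records              alt_residues
#> 1  ATM      476   colorectal        18 A,E,H,I,L,M,N,P,Q,R,S,T,Y
#> 2  ATM     1491   colorectal        10             F,K,M,P,T,V,W
#> 3  ATM     1807   colorectal        16   A,C,D,E,F,G,K,L,P,R,S,W
#> 4  ATM     2266   colorectal        15   C,D,E,F,I,K,L,M,N,S,V,W
#> 5  ATM     2754   colorectal        18   C,D,F,I,K,M,P,Q,R,T,V,W

# kinase-domain enrichment: 139 of 336 conserved mutated residues in a
# domain covering ~15% of the protein
domain_enrichment(139, 336, f_dom = 0.15)
#> enrichment: 139/336 residues in domain (41.4%), domain share 15.0%
#>   -> fold 2.76, binomial P = 2e-31

# burial classification on a toy structure with known ground truth
ball <- simulate_structure(toy_structure_spec("lattice_ball",
                                              n_residues = 100))
cls  <- classify_burial(shrake_rupley(ball$model))
c(surface = attr(cls, "n_surface"), resolved = attr(cls, "n_resolved"))
#>  surface resolved
#>       72      100
mean((cls$class == "surface") == ball$truth$surface)
#> [1] 1
```

The frequency line reads: 133 of the 200 cohort samples carry at least one
ATM mutation (a sample counts once however many mutations it has). The
enrichment line reads: 41.4% of tested residues fall in a domain spanning
15% of the protein, a 2.76-fold enrichment whose exact binomial tail
probability is ~2×10⁻³¹. The burial line shows perfect agreement between
the Shrake–Rupley surface calls and the lattice ball's geometric ground
truth.

Full runs go through `run_config()` + `run_pipeline()`, which execute
catalog → conservation → structure → stats and write one TSV per result
table plus a `summary.json`; stages whose inputs (structures, alignments)
are absent are skipped, so the pipeline runs on a mutation table alone.

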