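# MetalSiteFinder

Residue-level prediction of metal ion–binding sites (Ca²⁺, Cu²⁺, Fe³⁺,
Mg²⁺, Mn²⁺, Zn²⁺) in protein structures, for structural biologists and
bioinformaticians who want to flag putative coordination sites in a new
structure from a library of known ones.

## Method

Metal-coordinating residues are conserved in identity and in local
geometry: they cluster in space around the ion even when distant in
sequence.  MetalSiteFinder turns each known site into a **template** — all
residues with a non-hydrogen atom within 3.5 Å of the ion center, kept
when the site has more than two such residues — and aligns a query
structure to every template with the **fragment transformation method**:

1. Each residue is reduced to its backbone **triplet** (N, Cα, C), a local
   frame carrying no torsion information, so matching is independent of
   sequence order.
2. All m×n query/template triplet pairs are superposed by Kabsch
   (proper rotations only), giving a rigid transform `M_ij` per pair.
3. Pairs whose transforms map each other's triplets to within `d_c = 2 Å`
   (RMSD, both directions) are merged by single-linkage clustering; each
   cluster is an aligned substructure with a one-to-one residue
   correspondence.
4. Clusters are scored by structure and sequence jointly:

       s_str = max(0, 1 − RMSD_Cα / 3)          (fresh Cα superposition, < 3 Å required)
       s_seq = Σ B62(q_p, t_p) / Σ B62(t_p, t_p)  (> θ required, default 0.30)
       combined = s_str · s_seq

5. Per residue, combined scores are summed over all qualifying clusters
   and all templates, then z-normalized per chain (population SD):
   `Z_i = (r_i − μ)/s`.  Residues with `Z` at or above the per-metal
   threshold (Ca 1.6, Cu 1.8, Mg 1.8, Fe 1.0, Mn 1.0, Zn 2.2) are called
   binders.

Evaluation is leave-one-out — templates from the query's own structure are
excluded — with ACC/TPR/FPR at a threshold chosen so FPR ≤ 5%, plus ROC
and AUC per metal.  A deterministic synthetic generator (ideal backbones,
planted sites, coordinate noise, rigid motions) provides fully labelled
benchmarks without any downloads.

## Worked example

```r
library(MetalSiteFinder)

# 4 structures, each a noisy rigidly-moved copy of one chain with a planted
# Zn site (residues 10,11,13,14) and Ca site (35,36,38)
bench <- makeBenchmark(nStructures = 4, nResidues = 60, seed = 11)
lib <- buildLibrary(bench$structures)
lib
#> TemplateLibrary: 8 template(s)
#>   CA: 4
#>   ZN: 4

pred <- predictBindingSites(bench$structures[[1]], lib, "ZN",
                            excludeSource = TRUE)
pred
#> PredictionResult for B001 [ZN]: 60 residue(s), 4 called (Z >= 2.20),
#>   3 template(s) compared (1 excluded by LOO)

subset(scoresTable(pred), call)
#>  chainId resNo insCode resName   ref      raw        Z call
#>        A    10             CYS A:10: 2.844046 3.741657 TRUE
#>        A    11             CYS A:11: 2.844046 3.741657 TRUE
#>        A    13             HIS A:13: 2.844046 3.741657 TRUE
#>        A    14             CYS A:14: 2.844046 3.741657 TRUE

evaluateLibrary(bench$structures, lib)
#> Leave-one-out evaluation
#>  metal nTemplates threshold TP  TN FP FN ACC TPR FPR AUC
#>     ZN          4  1.737198 16 224  0  0   1   1   0   1
#>     CA          4  2.064742 12 228  0  0   1   1   0   1
#> overall (pooled): ACC 1.000 TPR 1.000 FPR 0.000
```

Each of the four planted Zn-binding residues accumulates a raw score of
~2.84 (three templates, each contributing a near-perfect combined score),
which z-normalizes to 3.74 on a 60-residue chain — far above the Zn call
threshold of 2.2 — while all 56 decoy residues stay at 0.  The
leave-one-out evaluation recovers every planted residue of both metals
with no false positives.

A command-line wrapper with `simulate`, `build-templates`, `predict` and
`evaluate` subcommands is installed under `inst/scripts/metalsitefinder`.

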