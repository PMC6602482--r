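# epitope3d

Per-residue prediction of **conformational (spatial) B-cell epitopes** on
3D antigen structures, with explicit micro-environment features for
**N-linked glycoprotein antigens**.

## The problem

Antibodies bind antigens at surface patches — conformational epitopes —
that are discontinuous in sequence and shaped by the local 3D
micro-environment. On glycoproteins the picture is further complicated by
N-linked glycosylation: sequon sites (Asn-X-Ser/Thr, X ≠ Pro) cluster
non-randomly with respect to epitope regions and alter the local
physico-chemical field. `epitope3d` scores every surface residue of a
parsed PDB chain for antigenicity by combining six micro-environment
classifiers:

| feature | meaning |
|---|---|
| `avg` | propensity index: mean log-odds `log((f_epi+ε)/(f_surf+ε))` of the residue's unit-triangle subgroup patterns |
| `apref` | relative ASA preference: mean rASA over the residue's triangle patch |
| `cc` | local clustering coefficient of the surface contact graph (15 Å) |
| `index` | consolidated general AAindex over the contact neighborhood |
| `glytri` | consolidated glycosylation-triangle score: ANN over weights `W_ri = ratio_i · N_occur(i)`, with `ratio_i = N_epi_glytri_i / N_glytri_i` |
| `glyindex` | consolidated shell-model glycosylation AAindex: ANN over iteratively filtered layer means (radius 10 Å, step 2 Å → 5 layers × 4 indexes = 20 candidates) |

A unit triangle is three mutually proximal (≤ 15 Å minimum heavy-atom
distance) surface residues; a *glycosylation triangle* (glytri) contains
a sequon asparagine; an *epitope glytri* additionally contains ≥ 2
epitope residues. The six features are integrated by a weighted ridge
logistic regression into a raw score, which is then **calibrated** by the
neighborhood average

```
adjust_score_r = Σ raw_score_i / N      (surface residues within 5 Å of r)
```

to suppress isolated false positives, and thresholded into epitope calls
(shipped server default threshold 0.089; retrained models store the
threshold maximizing training balanced accuracy).

The package contains the full training pipeline (ratio/propensity
tables, two "two-layer, ten-node" ANN consolidators, greedy iterative
filtering of the 20 shell features, logistic fit, threshold selection), a
structure-level cross-validation harness, evaluation metrics (ROC AUC,
balanced accuracy, FPR), and a seeded synthetic antigen/complex
generator so everything is testable offline.

## Worked example

```r
library(epitope3d)

# a seeded synthetic training corpus: 8 antigens, planted epitope caps,
# sequons enriched 5x inside the cap
corpus <- generate_corpus(8, synth_spec(n_residues = 70), seed = 5)
model  <- train_epitope_model(corpus$entries, seed = 11)
print(model)
#> epitope_model (general): 91 glytri patterns, shells [LAWE840101_L3,
#>   KIMC930101_L3, ROBB760113_L4, RICJ880102_L4, LAWE840101_L4],
#>   threshold 0.448

# score one antigen
pred <- predict_epitopes(corpus$entries[[1]]$structure, model)
pred[pred$is_surface][1:3]
#>    res_index seq_id icode aa is_surface raw_score adjusted_score predicted_epitope
#> 1:         1      1        I       TRUE 0.2112627      0.2423236             FALSE
#> 2:         2      2        V       TRUE 0.2733845      0.2776287             FALSE
#> 3:         3      3        A       TRUE 0.3482389      0.4687841              TRUE

# held-out performance, folds split by structure
cv <- cv_auc(generate_corpus(20, synth_spec(n_residues = 80), seed = 1)$entries,
             folds = 10, seed = 1)
cv$auc
#> [1] 0.7593691
```

`raw_score` is the logistic probability from the six features;
`adjusted_score` is its 5 Å neighborhood average (the final antigenic
score); `predicted_epitope` applies the model threshold to the adjusted
score of surface residues. The CV AUC above is on the synthetic planted
corpus — the generator's statistical analogue of real antigen data, not
a claim about PDB-scale performance.

## Command line

```sh
Rscript inst/cli/epitope3d synth --n 70 --seed 2 --corpus 10 --out fixtures/
Rscript inst/cli/epitope3d train --manifest fixtures/train_manifest.tsv \
        --seed 3 --out model.json
Rscript inst/cli/epitope3d predict --in antigen.pdb --chain A \
        --model model.json --out out/
Rscript inst/cli/epitope3d evaluate --pred out/antigen_A_scores.tsv \
        --truth fixtures/SYN001_truth.tsv --out report/
```

Outputs per antigen: a per-residue score TSV, an annotated PDB with the
adjusted score in the B-factor column, and a sequence summary where
uppercase/lowercase mark surface/core residues and `E` flags predicted
epitopes. Exit codes: 0 success, 1 usage error, 2 data error.

## Scope notes

AAindex values for the four glycosylation-related accessions
(KIMC930101, LAWE840101, RICJ880102, ROBB760113) are bundled as
**synthetic stand-ins** (`inst/extdata/aaindex_glyco_synthetic.tsv`);
all computation z-scores them, so the published values can be dropped in
via `load_aaindex(path = ...)`. See the methods vignette
(`vignettes/methods.Rmd`) for the model, its assumptions, the synthetic
world and known limitations.
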