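---
title: "Methods: spatial epitope scoring with glycosylation micro-environment features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial epitope scoring with glycosylation micro-environment features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`epitope3d` scores each surface residue $r$ of an antigen chain for
antigenicity in six steps:

1. **Surface determination.** Solvent-accessible surface area is computed
   by Shrake–Rupley sphere sampling (probe 1.4 Å, 960 deterministic
   golden-spiral points per atom) and normalized by the Tien et al.
   theoretical maximum per residue type into relative SASA (rASA). A
   residue is *surface* when rASA ≥ 0.15 (configurable).
2. **Unit triangles.** All triples of surface residues whose pairwise
   minimum heavy-atom distances are ≤ 15 Å. Each triangle is typed by the
   multiset of its members' *functional subgroups* — 13 groups over the
   20 amino acids, bundled as a replaceable table.
3. **Six classifiers per residue.**
   - *Propensity* `avg`: mean over the residue's triangles of
     $\log\frac{f_{epi}(t)+\varepsilon}{f_{surf}(t)+\varepsilon}$, with
     corpus frequencies of pattern $t$ among epitope triangles (≥ 2
     epitope members) and all surface triangles, $\varepsilon = 10^{-6}$.
   - *Patch exposure* `apref`: mean rASA over the union of the residue's
     triangles (itself included).
   - *Clustering coefficient* `cc` of the 15 Å surface contact graph.
   - *Consolidated AAindex* `index`: mean z-scored general AAindex
     (Kyte–Doolittle, Hopp–Woods) over the contact neighborhood.
   - *Glycosylation triangles* `glytri`: sequons Asn-X-Ser/Thr (X ≠ Pro)
     define glycosylation triangles (glytri = triangle containing a
     sequon Asn). For each pattern $i$ with training ratio
     $ratio_i = N_{epi\_glytri_i}/N_{glytri_i}$, the residue's weight is
     $W_{ri} = ratio_i \cdot N_{occur}(i)$; a small neural network (one
     hidden layer, 10 sigmoid units, sigmoid output) consolidates the
     weight vector to a scalar in (0,1).
   - *Glycosylation AAindex* `glyindex`: neighbors are binned into five
     half-open shells [0,2), …, [8,10) Å by minimum heavy-atom distance;
     per shell and per glyco-AAindex table the mean z-scored value gives
     20 candidate features (4 × 5), greedily filtered by cross-validated
     probe AUC and consolidated by a second small network.
4. **Integration.** A weighted ridge logistic regression (class weights
   inverse to frequency, L2 penalty $\lambda = 10^{-4}$, features
   z-scored with training statistics) yields the raw score.
5. **Calibration.** The adjusted score is the mean raw score over surface
   residues within 5 Å, the target included — suppressing isolated false
   positives at the cost of smearing score mass across patch boundaries.
6. **Thresholding.** Adjusted score ≥ threshold ⇒ predicted epitope. The
   shipped default 0.089 is meaningful only for a model trained on a
   full-scale antibody–antigen corpus; models trained here recompute the
   threshold maximizing training balanced accuracy.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| surface rASA threshold | 0.15 | fraction | conventional exposure cutoff; the lineage of this method defines everything on surface residues |
| triangle / contact radius | 15 | Å | defines unit triangles and the contact graph |
| shell model | radius 10, step 2 | Å | five layers capture the decay of glycan influence with distance |
| calibration radius | 5 | Å | one contact shell; larger radii oversmooth small epitopes |
| epitope contact cutoff | 4.0 | Å | conventional heavy-atom antibody-contact definition |
| ANN size | 10 hidden units | — | literal reading of a "two-layer, ten-node" consolidator |
| logistic penalty | 1e-4 | — | numerical stability only; not a tuning knob |

## Design choices where the design was open

- **Reconstructed features.** The formulas for `avg`, `apref` and
  `index` are re-specified here (corpus log-odds, patch-mean rASA,
  neighborhood-mean AAindex) because the upstream versions are only
  cited, not printed. Each has a config hook so alternatives can be
  substituted.
- **Consolidators are trained separately** against residue epitope
  labels, then frozen before the logistic fit; joint training is not
  attempted. Seeded initialization plus full-batch Adam with early
  stopping on a validation fold makes them bit-reproducible.
- **Self-inclusion in calibration.** The neighborhood average includes
  the target residue, guaranteeing $N \ge 1$ and making constant fields
  exact fixed points. A config flag (`include_self`) exposes the
  alternative.
- **Counting convention.** Each unique triangle is counted once per
  structure in ratio and propensity tables, regardless of how many
  centers can reach it. Triangles containing an unknown residue (`X`)
  are excluded from pattern statistics but still count toward triangle
  totals.
- **Thresholded call convention.** Score ≥ threshold is positive, so the
  boundary case is a call.
- **Fold unit.** Cross-validation splits by structure, never by residue:
  residues of one antigen are strongly dependent.
- **SASA rigid-motion invariance.** Sampling directions are fixed in a
  canonical molecular frame (centroid-centered principal axes, signs
  fixed by third moments, right-handed), so rotating or translating the
  input changes SASA by nothing beyond floating-point noise. Degenerate
  symmetric structures could make the frame ambiguous; this does not
  arise for real or generated structures.
- **Iterative filter stop rule.** Greedy forward selection stops when
  the cross-validated probe AUC improves by < 1e-3. On pure-noise
  candidates this admits an occasional spurious second or third feature,
  because CV-AUC estimation noise at desk-scale n (~0.01) exceeds the
  margin; a strict one-feature guarantee under this rule would require
  unrealistically large corpora. The tests assert the truthful behavior.

## The synthetic world

The generator (`synth_spec()`, `generate_antigen()`,
`generate_complex()`, `generate_corpus()`) emulates exactly the
statistical structure the method exploits, and nothing more:

- residues on a jittered 4.5 Å cubic-lattice ball (one pseudo C-alpha +
  1–3 dummy carbon side-chain atoms), giving buried cores, exposed
  shells and realistic rASA variation;
- a contiguous surface cap as the planted epitope, trimmed to the
  SASA-derived surface so the labeling invariant (positives are surface)
  holds by construction;
- sequons planted with probability boosted `sequon_epitope_enrichment`-fold
  (default 5) inside the cap — the analogue of the enrichment of
  N-glycosylation sites in epitope regions that motivates the glyco
  features — plus a mild composition bias (default 3×, toward Tyr/Trp/
  Lys/Arg) inside the cap so pattern-based features carry signal;
- a pseudo-antibody chain with one dummy atom 3.75 Å above each cap
  residue and > 4.5 Å from every non-cap surface residue, so contact
  labeling at the conventional 4 Å cutoff recovers the planted cap
  exactly. (A stricter "> 8 Å from all others" placement is
  geometrically impossible at lattice spacing; 4.5 Å preserves the
  property that matters — exact recovery.)

What the generator does **not** emulate: real backbone geometry,
rotamers, side-chain chemistry, actual glycans, antibody shape, or the
size and diversity of curated antibody–antigen corpora. A green
end-to-end test therefore establishes that the pipeline learns planted
glyco-epitope structure from data shaped like its assumptions — not
PDB-scale accuracy. The published headline AUCs of the original
web-server-scale model are out of reach by design (its 832-complex
training snapshot and weights are unavailable), and no number reported
by this package should be read as reproducing them.

## Numerical choices

- ε = 1e-6 pseudo-frequency in log-odds; empty shells, absent patterns
  and triangle-less residues all yield 0-valued features, never missing
  values.
- Half-open distance bins everywhere ([lo, hi)); a neighbor at exactly
  10.0 Å is outside the shell model.
- Minimum heavy-atom distance is the inter-residue metric throughout.
- IRLS for the ridge logistic with unpenalized intercept, tolerance
  1e-10; a tiny extra ridge (1e-8) is added only if the weighted normal
  matrix is singular.
- AAindex tables are z-scored over the 20 residues at load; `X` maps to
  the mean (0).
- Ties in greedy selection break in candidate order; which.max
  semantics, documented and tested.

## Known limitations

- The bundled glyco-AAindex values are synthetic stand-ins (see
  `?load_aaindex`); the real accession values should be supplied for
  production use on real antigens.
- Calibration can raise false positives at patch boundaries when the
  decision threshold sits below the smeared boundary level; the FPR
  reduction it is designed for concerns isolated high-score speckles.
- The 13-subgroup mapping is a chemically sensible stand-in for a
  grouping whose published form is not available; it is a data file, not
  code.
- No support for mmCIF, NMR multi-model averaging, structure repair or
  O-glycosylation.
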