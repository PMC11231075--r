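# mpxassort

Per-node polarity scoring and protein colocalization analysis for
Molecular Pixelation (MPX) single-cell surface-proteome graphs.

MPX encodes the spatial neighborhood structure of antibody-tagged surface
proteins on a single cell as a bipartite graph: A-pixels and B-pixels are
DNA-tagged spatial zones, and every antibody–oligonucleotide molecule
contributes a counted, marker-labelled edge between them. Events such as
uropod formation on migrating T cells or rituximab-induced capping of CD20
on B cells show up in this data as *polarized* markers — molecule counts
concentrated on one contiguous region of the cell graph — and as groups of
markers whose polarized regions coincide. `mpxassort` quantifies both.

## The method

For each cell the bipartite graph is projected onto its A-nodes (two
A-pixels are adjacent iff they share a B-pixel; counts move from edges to
nodes). On the projection, every marker *x* gets a per-node **local
assortativity** score in the style of Peel et al.: with personalized
PageRank weights *w(ℓ)* around focal node *ℓ* (restart probability α) and
degree-weighted edge-end moments μₑ, σₑ² of the marker counts,

    r(ℓ) = ( Σ_v w_v(ℓ) · x_v · ( Σ_{u∼v} x_u / d_v ) − μₑ² ) / σₑ²

Raw scores are not comparable across cells, so they are **adjusted** by
the bounded transform ϱ = h∘g∘f:

* *f* — signed normalization: positives divided by the positive sum,
  negatives by the absolute negative sum (each sign block gets unit mass,
  zero stays the score of uniform mixing);
* *g* — unit-energy standardization: division by √(Σ x̃²);
* *h* — signed log: sgn(z)·ln(|z| + 1).

Every adjusted score then lies in **[−ln 2, +ln 2]**. Two per-cell filters
precede scoring: a marker must reach the cell's **isotype threshold**
(the maximum molecule total among the isotype-control antibodies) and be
present on **more than 10 vertices**; otherwise its field is zeroed.

On top of the adjusted fields:

* **pairwise colocalization** — Spearman correlation of two markers'
  fields (exactly 0 when either field is all-zero);
* **higher-order colocalization** — the multiple-site similarity
  C = (T/(T−1))·(1 − |∪Aᵢ|/Σ|Aᵢ|) of the markers' positive-score node
  sets, which reduces to the Sørensen index at T = 2;
* **differential colocalization** — mean score difference between two
  samples with a two-sided Wilcoxon rank-sum p-value, displayed as 0–3
  significance dots (boundaries 0.01 / 0.001 / 0.0001).

A seeded synthetic generator produces MPX-like cells (A-pixels on a unit
sphere, B-pixels bonding locally, Poisson molecule counts) with plantable
co-polarized caps, so the entire pipeline is testable without external
data.

## Worked example

```r
library(mpxassort)

panel <- mpx_panel(c("CD50", "CD162", "CD37", "CD44",
                     "mIgG2b", "mIgG1", "mIgG2a"),
                   isotype_markers = c("mIgG2b", "mIgG1", "mIgG2a"))

# one synthetic cell with CD50 and CD162 co-polarized on a 20% cap
cfg <- synthetic_cell_config(panel, n_a_pixels = 150, n_b_pixels = 300,
                             baseline_rate = 3,
                             polarized_markers = c("CD50", "CD162"),
                             cap_fraction = 0.2, enrichment_fold = 8)
cell <- simulate_cell(cfg, cell_id = "cell_1", seed = 42)
an   <- project_to_anodes(cell)
an
#> <mpx_anode> cell cell_1: 150 A-nodes, 643 edges, 7 markers

isotype_threshold(an, panel)
#> [1] 12

scores <- score_cell(an, panel)
round(range(as.numeric(scores$CD50)), 3)
#> [1] -0.100  0.167

pairwise_colocalization(scores$CD50, scores$CD162)   # planted pair
#> [1] 0.982
pairwise_colocalization(scores$CD50, scores$CD44)    # uniform marker
#> [1] -0.182

higher_order_colocalization(scores, c("CD50", "CD162", "CD37"))
#>   cell_id         markers order     score
#> 1  cell_1 CD162+CD37+CD50     3 0.6327014
```

The planted pair's near-ceiling Spearman score (0.98) against the
baseline pair's noise-level score (−0.18) is the method's core readout;
the trio score is pulled toward the Sørensen overlap of the two planted
markers' caps with the unpolarized CD37 region.

The same analysis runs from the shell over delimited edge-list tables:

```sh
exec/mpxassort simulate --out data/ --n-cells 20 --seed 1
exec/mpxassort score    --edges data/edges.csv --panel data/panel.csv --out data/scores.csv
exec/mpxassort coloc    --scores data/scores.csv --out data/coloc.csv --tuples "CD50+CD162+CD37"
exec/mpxassort diff     --coloc data/coloc.csv --samples data/samples.csv \
                        --out data/diff.csv --condition-a stimulated --condition-b control
```

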