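# cytoradial

Quantitative subcellular positioning of organelle markers in multi-channel
fluorescence microscopy. The package asks, and answers numerically, three
questions biologists of membrane traffic ask of their images:

* **Where does a punctate marker sit radially?** Concentric annuli are
  built around each segmented nucleus as level sets of the Euclidean
  distance transform, clipped to the cell-envelope mask. Annulus *k* of
  *n* collects cytoplasm pixels with distance-from-nucleus
  *d* ∈ ((k−1)·d_max/n, k·d_max/n], where d_max is the cell's
  nucleus-to-periphery distance, so r_norm = 1 is the periphery in every
  cell. Each annulus reports its area, its **intensity fraction** (share
  of the cell's total background-subtracted signal; fractions sum to 1)
  and its intensity density.
* **How does lysosomal pH track position?** Puncta segmented from a
  pH-insensitive channel get a per-particle ratio of channel means
  (pH-sensitive / pH-insensitive), a relative radial position
  u = d_nuc/(d_nuc + d_pm) between the nuclear membrane (0) and the
  plasma membrane (1), a quartile label (bins [0,.25], (.25,.5],
  (.5,.75], (.75,1] → 0.25/0.50/0.75/1.0), and per-cell per-quartile mean
  ratios.
* **Do two channels co-occur?** Masked Pearson correlation
  Σ(a−ā)(b−b̄)/√(Σ(a−ā)²·Σ(b−b̄)²) over the pixels of an optional mask.

A synthetic-scene generator with exact analytic ground truth (circular
cells, Beta-distributed punctum radii, a linear position-dependent
channel-ratio model, Poisson + Gaussian noise) backs every stage with
known answers. Inputs are multi-page TIFFs with an explicit role→page
channel map; outputs are deterministic CSV tables and TIFF label maps.

## Worked example

Simulate the two packaged study conditions — `"wt"` (perinuclear puncta,
u ~ Beta(2,5)) and `"ko"` (peripheral puncta, u ~ Beta(5,2)), 20 cells ×
500 puncta each — then profile, position and colocalize them:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_radial_profile.R
Rscript analysis/03_lysosome_ph.R
Rscript analysis/04_colocalization.R
```

which prints (seed 1/2 scenes):

```
wt: 20 cells, intensity-weighted mean r_norm = 0.344
ko: 20 cells, intensity-weighted mean r_norm = 0.749
wt: per-quartile mean ratio  0.589  0.680  0.781  0.871
ko: per-quartile mean ratio  0.591  0.681  0.791  0.910
wt: PCC(ratio pair) = 0.993, PCC(envelope~nuclear) = 0.406
ko: PCC(ratio pair) = 0.994, PCC(envelope~nuclear) = 0.405
```

Reading the numbers: the KO-like condition's signal mass sits far
peripherally (mean r_norm 0.749 vs 0.344 — the analytic means of the two
Beta densities are 5/7 and 2/7 plus a half-bin offset), the quartile mean
ratios rise monotonically toward the periphery in both conditions and
track the generative model ratio(u) = 0.5 + 0.5·u (conditional means
0.5625…0.9375), and the two ratio channels — which share every punctum —
are near-perfectly correlated while the envelope/nuclear pair is not.

The same machinery runs on real images via
`run_pipeline(list(command = "profile", inputs = "*.tif", channel_map =
list(envelope = 1, nuclear = 2, signal = 3), ...))` or the individual
functions (`segment_cell_mask()`, `segment_nuclei()`,
`assign_territories()`, `build_annuli()`, `measure_radial_profile()`,
`lysosome_pipeline()`, `pearson_coloc()`).

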