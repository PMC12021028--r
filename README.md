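# ciliacoat

Quantitative analysis of the ciliary glycocalyx of *Chlamydomonas
reinhardtii* — the scale-like outer coat of mucin-like FMG1
glycoproteins on the ciliary membrane — and of its functional readouts,
for structural biologists and cell biologists working with
cryo-electron tomograms, chain models of repeat proteins, and
light-microscopy motility assays.

The package provides four connected toolsets, each paired with a
synthetic-data generator with known ground truth:

* **Membrane shell masking** — fit closed periodic splines to membrane
  points in each tomographic slice, sweep them into a tube model, and
  rasterize the band between two outward offsets `[d_in, d_out]` into a
  boolean shell mask via a Euclidean distance transform (robust to
  concave contours; `d_out = Inf` gives a half-space mask).
* **Coat particle mapping** — rotation-searched, locally normalized
  cross-correlation (Roseman-style, FFT-based) of a particle template
  inside the shell mask, with missing-wedge-aware scoring
  (`match_template`), greedy peak extraction, full-resolution sub-voxel
  refinement, and the greedy overlap-exclusion filter that re-simulates
  accepted densities into an occupancy volume and rejects
  lower-scoring particles whose binarized footprint would overlap more
  than a threshold fraction (`map_coat`, `overlap_filter`).
* **Structural repeats** — segment a chain model into tandem ~110
  residue Ig-like repeats by seed-and-scan trimmed Kabsch RMSD
  (`segment_repeats`), build a structure-guided alignment with
  sequence-monotone residue pairing (`structure_guided_msa`), compute
  all-vs-all RMSD matrices (`pairwise_rmsd_matrix`), find conserved
  cysteine columns and intra-domain disulfides, and compute global
  pairwise sequence identities (Needleman–Wunsch, BLOSUM62).
* **Motility and adhesion** — kymograph construction and event tracing
  with the velocity > 0 inclusion rule (`build_kymograph`,
  `trace_events`), Mann–Whitney U with exact enumeration for small
  samples, Otsu frame binarization, normalized occupancy detachment
  curves under the stepwise flow schedule (3.77–51.94 mL/min), and
  Student t comparisons at fixed timepoints (`compare_curves`).

At the core of the coat mapper is the locally normalized
cross-correlation score: for a unit-norm, mean-subtracted rotated
template t under a footprint M, `score(p) = <t, V(p+.)> / sqrt(n_M) sigma_M(p)`,
maximized over a near-uniform SO(3) grid, so all scores lie in [-1, 1].

## Worked example

End-to-end coat mapping on the standard phantom: a 128³ tomogram
(10 Å/voxel) with 50 coat particles on a tubular membrane, Gaussian
noise at 0.3× the template peak and a ±60°/2° missing wedge, mapped
with a 20° rotation grid (about two and a half minutes on one CPU):

```r
library(ciliacoat)

spec <- tomo_phantom_spec(seed = 1)      # the standard 128^3 phantom
ph   <- simulate_tomogram(spec)
sh   <- fit_shell_from_points(phantom_membrane_points(spec),
                              spec$d_in, spec$d_out, spec$shape,
                              spec$voxel_size)
pt   <- map_coat(ph$volume, sh$mask, spec$template, angular_step = 20,
                 min_spacing = spec$min_spacing, wedge = spec$wedge)
coat_recovery(pt, ph$truth, max_dist = 2)[c("recall", "fdr")]
#> $recall
#> [1] 1
#> $fdr
#> [1] 0.01960784
```

All 50 planted particles are recovered within 2 voxels (mean
localization error 0.88 voxels), with one duplicate detection among 51
picks: the particle table `pt` holds their positions, ZYZ orientations
and scores.

Repeat analysis of a synthetic mucin-like chain (5 noisy ~110-residue
repeats at 22% target pairwise identity, Cys pair planted at domain
positions 60 and 91):

```r
chain <- simulate_repeat_chain(repeat_chain_spec(n_repeats = 5, seed = 7))
seg <- segment_repeats(chain$model)
msa <- structure_guided_msa(chain$model, seg)
repeat_stats(seg, msa)
#> $count           [1] 5
#> $mean_length     [1] 110
#> $sd_length       [1] 0
#> $mean_pairwise_identity  [1] 22.7
find_conserved_columns(msa, "C", min_frequency = 1)
#> [1] 60 91
nrow(detect_disulfides(chain$model))
#> [1] 5
```

The segmentation finds all five repeats at their true boundaries, the
structure alignment localizes the perfectly conserved cysteine pair to
columns 60 and 91, and each repeat carries exactly one disulfide.

Gliding analysis of a simulated TIRF movie (one spot at 0.97 µm/s,
10 frames/s, 0.16 µm pixels):

```r
ev  <- data.frame(start_frame = 20, duration_s = 12,
                  velocity_um_s = 0.97, x0 = 10, y0 = 24)
sim <- simulate_motility_movie(motility_phantom_spec(events = ev, seed = 7))
ky  <- build_kymograph(sim$stack, c(2, 24, 190, 24), width = 3)
tr  <- trace_events(ky)
tr[tr$included, c("velocity_um_s", "distance_um")]
#>   velocity_um_s distance_um
#> 1     0.9705631     11.5497
```

The recovered velocity is within 0.1% of the planted 0.97 µm/s;
stationary spots are reported but flagged excluded under the
velocity > 0 rule.

A thin command-line wrapper is installed at
`system.file("scripts", "ciliacoat", package = "ciliacoat")` with
subcommands `simulate`, `map-coat`, `analyze-repeats`,
`analyze-motility` and `analyze-detachment`; every stage logs its
parameters, seed and input hashes.

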