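# isletscope

Quantitative longitudinal imaging of insulin content in pancreatic islets.

`isletscope` turns tiled, burst-captured 12-bit fluorescence time-lapse
images of a pancreas — real or simulated — into per-islet insulin-content
traces and population response statistics. It targets experiments that use
a fluorescent C-peptide reporter (a superfolder-GFP fused to C-peptide,
co-stored and co-secreted with insulin) whose integrated fluorescence
density is a proxy for the insulin stored in each islet: when an islet
secretes, its fluorescence drops, and following every islet across a
glucose challenge reveals whether the organ responds homogeneously (as
isolated islets do in culture) or heterogeneously (as islets do in vivo).

## What the pipeline does

For each acquisition the package runs five stages:

1. **Frame selection** (`select_frames`): each stage position is captured
   as a rapid burst of frames so that at least one falls in a motionless
   part of the breathing cycle; the sharpest frame per field is chosen by
   the variance-of-Laplacian focus score, `Var[∇²I]`.
2. **Stitching** (`register_pair`, `compose_mosaic`): tiles acquired at
   15 % overlap are registered by phase correlation of their overlap
   regions and composed with a Voronoi seam — every mosaic pixel is copied
   verbatim from exactly one camera frame, so measured intensities are
   never blended or rescaled.
3. **Segmentation** (`subtract_background`, `make_mask`,
   `measure_objects`): rolling-ball background subtraction (grayscale
   opening by a disc of radius 200 px by default), thresholding into a
   mask, and *redirected* measurement: each islet's **integrated density**
   `ID_i = Σ raw pixel values` is summed on the original, unaltered image
   under the mask. Objects smaller than
   `round(π (d_min / 2 / 0.54 µm)²)` pixels (269 px at the 10 µm in vivo
   detection floor) are discarded.
4. **Tracking** (`link_objects`, `build_traces`, `apply_exclusions`):
   objects are linked across time points by minimum-cost bipartite
   assignment gated on displacement (≤ 30 px) and area ratio (≤ 2×);
   traces touching the field edge, containing saturated pixels, or missing
   time points are excluded from statistics (and kept for audit).
5. **Response statistics** (`percent_trace`, `summarize_experiment`,
   `size_response_relation`, `compare_heterogeneity`): per-islet percent
   traces `P_i(t) = 100 · ID_i(t) / ID_i(t_ref)` (reference = stimulation
   time: t15 for the in vitro protocol, t0 in vivo), the whole-experiment
   total response
   `100 · (Σ ID_i(t_ref) − Σ ID_i(t_end)) / Σ ID_i(t_ref)`,
   the Spearman size–response relation, and the **heterogeneity SEM** —
   the standard error of the per-islet percentages, which separates the
   tight in vitro response from the wide in vivo one (Shapiro–Wilk
   normality check, then t-test or Mann–Whitney).

A synthetic-acquisition module (`sim_preset`, `generate_experiment`,
`render_frame`) generates complete experiments with ground truth — label
maps, latent per-islet content traces, tile offsets, blur flags — under
presets mirroring the reference experiments: a four-phase in vitro GSIS
protocol (low glucose → 26 mM glucose → low → 30 mM KCl; 10 % release in
high glucose, 12.5 % cumulative), a heterogeneous in vivo challenge
averaging an 8 % total response, a 200-islet full-pancreas capacity
setting, and an unstimulated stability control.

## Worked example

```r
library(isletscope)

cfg <- sim_preset("invitro_gsis", rng_seed = 1)   # 50 islets, 4 phases
exp <- generate_experiment(cfg)
res <- run_pipeline(exp, seg = seg_params(min_diameter_um = 20))
res
#> <islet_pipeline> 13 time point(s), 50 trace(s) (50 retained)
#> <gsis_summary> n = 50 islets, t_ref = 15 min, t_end = 30 min
#>   total response: 9.92%  mean per-islet decline: 9.93%  SEM of P_i: 0.010
```

The simulated islets were configured to release 10 % of their content
during the 15-minute high-glucose phase; the pipeline, working only from
the rendered images, recovers a mean per-islet decline of 9.93 % with all
50 traces complete and retained. Extending the window over the whole
protocol (`summarize_experiment(res$traces, 15, 60)`) recovers the
cumulative ~12.4 % loss after the KCl phase.

Datasets can also be written to and read from disk (TIFF frames + JSON
manifest) and driven from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "isletscope", package = "isletscope"))')
Rscript "$CLI" simulate --preset invitro_gsis --seed 1 --out data/
Rscript "$CLI" run --manifest data/manifest.json --out results/
Rscript "$CLI" report --results results/
```

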