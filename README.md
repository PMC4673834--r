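# cobindseq

Consensus ChIP-seq binding-site detection, two-factor co-occupancy
classification and composite-motif analysis, with a fully ground-truthed
synthetic-data generator.

## Who this is for

ChIP-seq tells you where a DNA-binding protein sits on the genome, but any
single peak caller's output is noisy, and questions about *two* factors —
do they co-occupy the same sites, and do co-occupied sites carry a
composite sequence signature? — need a reproducible pipeline rather than
ad-hoc scripts. cobindseq packages that pipeline for researchers studying
transcription-factor co-occupancy (for example, corepressors such as ETO2
and IRF2BP2 acting within the LDB1 erythroid complex):

1. **Consensus binding sites** — regions supported by ≥ 2 peak callers
   (per-base summed occupancy ≥ 2 over ≥ 150 bp), scored against an IgG
   control with a negative-binomial background model and filtered at
   read count ≥ 10, fold change ≥ 2, BH-adjusted *q* ≤ 0.01.
2. **Co-binding classification** — two factors' sites are merged (centers
   within 250 bp pair up), IgG-subtracted coverage in ±500 bp is averaged
   in 25-bp sub-windows, z-scored per site, and partitioned by K-means
   (K = 3) into factor-A-only, factor-B-only and shared classes.
3. **Composite-motif scanning** — repeat-mask-filtered 200-bp site
   sequences are scanned for bipartite IUPAC patterns with a variable
   spacer (default `CTG N(6–8) WGATAR`, the E-box/GATA signature), on both
   strands, reporting the fraction of motif-containing sites per class.
4. **Nearest-TSS annotation** — each site is assigned to the single
   nearest transcription start site within 1 Mb and classified proximal
   (< 5 kb) or distal.

The statistical core: read counts `x` in a candidate region are tested
against a negative binomial with mean
`mu = max(scale * control_count, m * width / bin_size)` and dispersion
`phi` (variance `mu + phi mu^2`), where `scale` equalizes the two
libraries' background levels and `(m, phi)` are method-of-moments estimates
from background bins; the p-value is the upper tail `P(X >= x)`, Poisson in
the `phi = 0` limit.

All interval data are plain tibbles in BED-style 0-based half-open
coordinates, so results compose with dplyr; fitted objects support broom's
`tidy()`/`glance()` and ggplot2's `autoplot()`.

## Worked example

The bundled demo config simulates a two-chromosome 1-Mb genome with 200
planted sites (60% shared, 20% per-factor-only), three imperfect peak
callers, negative-binomial background for factor and IgG tracks, composite
motifs embedded at shared/A-only sites, and 30 genes — then runs every
stage:

```r
library(cobindseq)
demo <- system.file("extdata", "demo_config.txt", package = "cobindseq")
res <- run_pipeline(demo, "demo_out")
#> stage inputs: simulating dataset
#> stage consensus (A)
#>   A: 157 candidates -> 157 passing sites
#> stage consensus (B)
#>   B: 153 candidates -> 153 passing sites
#> stage cobinding
#>   197 combined sites; cluster labels: A_only/B_only/shared
#> stage motif
#> stage annotate
#> done: 10 output files, manifest at demo_out/manifest.json
```

The fitted background for factor A (`glance(res$background$A)`) reports a
mean of 0.97 read-equivalents per kb bin, dispersion 0.049 and
control-to-sample scale 0.96 over 712 background bins — matching the
simulated 1 read/kb background and equal-depth IgG. The first passing
sites show the funnel's effect:

```r
res$sites_a[1:3, c("chrom", "start", "end", "read_count", "fold_change", "q_value")]
#>   chrom start   end read_count fold_change  q_value
#> 1 chr1   4351  4950         34        12.0 2.44e-23
#> 2 chr1   6648  7214         25        26   5.69e-28
#> 3 chr1  21206 21713         23        12.2 3.11e-20
```

Motif proportions per co-binding class recover the planted structure (the
composite motif was embedded at 90% of shared and A-only sites and at none
of the B-only sites):

```r
res$motif_summary
#>   label  n_total n_with_motif fraction n_hits
#> 1 A_only      40           36    0.9       37
#> 2 B_only      31            0    0          0
#> 3 shared     109          101    0.927    102
```

and the TSS-distance summary (`tss_distance_summary(res$annotation)`)
classifies 62 of 197 combined sites (31.5%) as proximal and 135 (68.5%) as
distal, reflecting the simulated gene density. `autoplot(res$cobinding$z,
clusters = res$cobinding$clusters)` draws the cluster-sorted two-track
z-score heatmap; `plot_motif_proportions(res$motif_summary)` and
`plot_tss_distance(...)` chart the two summaries.

Every stage is also callable on its own
(`consensus_binding_sites()`, `classify_cobinding()`,
`motif_site_proportion()`, `assign_nearest_gene()`, ...), and a thin CLI
wrapper lives at `inst/cli/cobindseq.R`
(`Rscript cobindseq.R <run|simulate|consensus|cobind|motif|annotate>`).

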