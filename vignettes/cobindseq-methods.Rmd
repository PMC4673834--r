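---
title: "Methods: consensus binding sites, co-occupancy classification and composite motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus binding sites, co-occupancy classification and composite motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobindseq)
```

cobindseq detects transcription-factor binding sites from ChIP-seq data by
consensus over multiple peak callers, scores them against an IgG control
under a negative-binomial background, classifies two-factor co-occupancy
patterns by K-means clustering of z-scored coverage profiles, scans
binding-site sequences for bipartite degenerate motifs with a variable
spacer, and annotates sites by nearest transcription start site (TSS). This
vignette describes the statistical model behind each stage, the parameters
that matter, and the design choices made where more than one reasonable
option existed.

All coordinates are 0-based half-open (BED convention) throughout; any
1-based input would have to be converted at the boundary. Coverage tracks
are dense per-base vectors: the package targets desk-scale genomes (a few
Mb, real chromosomes work but cost memory), and dense vectors keep every
per-base computation exactly testable against brute-force recomputation.

## Consensus binding-site detection

ChIP-seq peak callers disagree, particularly on broad or weak sites, so a
single caller's output is a noisy representation of occupancy. The
consensus stage takes the peak sets of two or more callers and keeps only
regions supported by at least two of them:

1. Uniquely mapped reads are extended to 200 bp in the 3' direction
   (`extend_reads()`), approximating the sequenced fragment; extended reads
   are clipped at chromosome ends (the alternative — dropping boundary
   reads — discards signal for no benefit, and clipping keeps the coverage
   conservation property testable away from edges).
2. Each caller's peak set is converted to a per-base 0/1 occupancy track
   and the tracks are summed (`binarize_occupancy()`,
   `sum_binary_tracks()`).
3. Maximal runs with summed occupancy ≥ `min_support` (default 2) and
   length ≥ `min_length` (default 150 bp, roughly a nucleosome footprint)
   become candidate consensus regions (`call_consensus_regions()`).

### Negative-binomial significance against the IgG control

Read counts in unbound genomic bins are overdispersed relative to Poisson
(chromatin accessibility, mappability and copy-number all vary), so the
background is modelled as negative binomial with mean `m` and dispersion
`phi` (variance `m + phi m^2`; `phi = 0` recovers Poisson). The model is
fitted genome-wide on fixed bins (default 1 kb) that intersect neither the
candidate regions nor any single caller's peaks — a site reported by one
caller falls short of consensus but still carries enrichment, and leaving
such bins in the background badly inflates the dispersion (and with it the
p-values) of everything else:

* the control-to-sample **scale** is the ratio of total sample to total
  control counts over background bins — this equalizes the *background*
  level of the two libraries rather than their total depth, so enrichment
  at true sites does not deflate the scaling. (An ordinary zero-intercept
  regression slope over bins is not used: when bin noise is independent
  between the libraries it is attenuated toward zero by errors-in-variables
  and systematically inflates fold changes.);
* **mean** and **dispersion** come from method of moments on the sample's
  background bins, `phi = max(0, (var - mean) / mean^2)`. Method of moments
  is preferred to maximum likelihood here because it is closed-form,
  deterministic and accurate at the thousands of bins typically available;
  the dispersion estimate is floored at 0 so sparse data degrade gracefully
  to Poisson.

Bin counts are expressed in read-equivalents (bin coverage sums divided by
the track's mean read length), which makes the fitted mean directly
comparable with the per-region read counts used in scoring.

Each candidate region is then scored (`score_regions()`):

* `read_count` — extended sample reads overlapping the region by ≥ 1 bp,
  each read counted once (a count, not base coverage);
* expected count — `max(scale * control_count, mean * width / bin_size)`;
  flooring at the genome-wide rate prevents regions with an empty control
  from getting an arbitrarily small expectation;
* `fold_change = (read_count + 1) / (scale * control_count + 1)`, the
  pseudocount of 1 read avoiding division by zero;
* `p_value` — upper tail `P(X >= read_count)` of the negative binomial at
  the expected mean and fitted dispersion (exact Poisson tail when
  `phi = 0`).

P-values are Benjamini–Hochberg adjusted once across all candidates of one
factor (not per chromosome — a single experiment gets a single FDR
control), and sites must pass `read_count >= 10`, `fold_change >= 2`,
`q <= 0.01` jointly (`filter_binding_sites()`). All three thresholds are
parameters; the defaults are the standard operating point of the method.

## Two-factor co-binding classification

Binding sites of factors A and B are combined: sites whose centers lie
within `pairing_distance` (default 250 bp) become one `paired` site at the
midpoint of the two centers; the rest stay `A_only` / `B_only`
(`merge_factor_sites()`). Multi-overlaps are resolved by greedy
nearest-center matching so each original site contributes to exactly one
combined site — this conserves sites (|A_only| + |B_only| + 2·|paired| =
|A| + |B|) and is order-independent. The midpoint (rather than one
factor's summit) is used as the paired profile center because neither
factor is privileged.

For each combined site, IgG-subtracted coverage (`subtract_control()`,
clamped at zero — negative ChIP signal has no physical reading; an
unclamped mode exists for numerical checks) is averaged in 25-bp
sub-windows across ±500 bp for both factor tracks, giving an n × 80 profile
matrix. Each row is z-scored and the matrix is partitioned by K-means with
K = 3 (`kmeans_cluster()`: k-means++ seeding, Lloyd iterations via
`stats::kmeans`, best of 10 restarts, fully determined by the seed).
Clusters are named `A_only` / `B_only` / `shared` from their centroid mean
raw signal per track: largest log2 A:B ratio → `A_only`, smallest →
`B_only`, remainder → `shared`; a degenerate ranking is flagged and falls
back to strict ordering so labels stay a bijection.

### Which z-score?

"Z-scores per individual binding site" admits three readings, and the
choice matters. `zscore_rows()` implements all three:

* **row** (default): each site's whole 80-column, two-track row is
  standardized. Removes between-site ChIP-efficiency scale while
  preserving the *relative* amplitude of the two tracks within a site.
* **segment**: each track's 40-column segment is standardized separately.
  This makes pure per-track shape the signal — but it also equalizes a
  bound track and an unbound track, so in sparse data a single background
  read in the unbound track is amplified into a peak-shaped z-profile. In
  our synthetic experiments this mislabels a visible fraction of
  single-factor sites as co-occupied; it is kept as an option because with
  deep, dense coverage the effect shrinks.
* **column**: each sub-window column is standardized across sites
  (amplitude-driven; between-site efficiency differences dominate).

The row mode is the default because it is the only variant that is both
per-site (as the method requires) and robust to sparse background noise in
the unbound track.

## Composite-motif scanning

The motif stage asks what fraction of binding sites in each co-binding
class contains a bipartite signature such as the E-box/GATA composite
`CTG N(6-8) WGATAR` bound by the LDB1 complex (E-box half by TAL1/E
proteins, GATA half by GATA1). Sequences are 200 bp centered on each site,
taken from a soft-masked FASTA; sites with ≥ 150 masked bp (lowercase or N)
are removed before scanning, since repeat-dominated windows produce
untrustworthy matches. Optionally, classes are down-sampled to fixed-size
random subsets (`sample_sites()`) so proportions are compared on equal
footing.

`scan_sequence()` reports **every** (offset, spacer length, strand)
combination compatible with the pattern; minus-strand hits are found by
scanning the forward sequence with the reverse-complemented pattern and are
reported in forward coordinates. Matching rules: case-insensitive (soft
masking is handled by the filter above, not by the matcher); standard IUPAC
degeneracy in the pattern (`W` = A/T, `R` = A/G, ...); an `N` in the
*subject* matches nothing except a pattern `N`, so masked N runs cannot
fabricate composite hits. Per-site proportions collapse hit multiplicity —
a site with two spacer variants of the same match counts once — with the
instance count reported alongside.

## Nearest-TSS annotation

Each site is assigned to the gene with the nearest TSS on the same
chromosome (TSS = interval start on `+`, end − 1 on `-`), if within 1 Mb;
distance is signed (`center − TSS`, unstranded). Ties resolve to the
smaller TSS coordinate, then the lexicographically smaller gene id, making
the assignment fully deterministic. Sites with |distance| < 5 kb are
`proximal`, assigned sites beyond that `distal`, the rest `unassigned`.
This is the single-nearest-gene reading of regulatory-domain assignment;
basal-plus-extension domains and enrichment statistics are out of scope.

## The synthetic-data generator

`simulate_dataset()` produces complete, ground-truthed inputs so every
stage is testable without external data. Its defaults are the package's
reference study conditions and are not tuned per analysis:

| parameter | default | what it emulates |
|---|---|---|
| genome | 2 × 2 Mb | desk-scale reference coordinate space |
| `n_sites` | 1,500 | planted binding sites, ≥ 2 kb apart |
| `class_fractions` | 0.6 / 0.2 / 0.2 | shared-heavy co-occupancy structure typical of factors acting in one complex |
| `enrichment` | 30 reads/site | per-factor Poisson read yield at bound sites |
| `background_rate` | 1 read/kb | unbound-genome sequencing background |
| `nb_dispersion` | 0.2 | overdispersion of background bin counts |
| `caller_sensitivity` | 0.9 | per-caller detection probability |
| `caller_fp_rate` | 2 /Mb | spurious peaks per caller |
| `caller_jitter_sd` | 30 bp | peak-boundary uncertainty |
| `motif_prob` | 0.9 / 0.9 / 0 | composite motif embedded at shared and A-only sites, absent from B-only |
| `repeat_fraction` | 0.1 | soft-masked repeat stretches (mean ≈ 500 bp) |

Site reads are placed Normal(center, 60 bp) and all reads are emitted
directly as 200-bp extended intervals — read-level sequencing error,
fragment-length variation and alignment are upstream of this package's
scope and are deliberately not modelled. Background counts are drawn per kb
from the same negative-binomial family the scoring stage assumes. Every
artifact is a pure function of `(config, seed)`: each stage draws from its
own stream derived from the master seed, so regenerating any one artifact
is reproducible in isolation.

What passing tests on this generator do **not** show: robustness to
mappability artifacts, copy-number variation, chromatin-state-dependent
background, caller-specific systematic biases, or replicate structure —
none of which the generator emulates. Results on real data depend on those
factors; the synthetic tests establish correctness of the computation, not
field performance.

## Numerical choices and degenerate inputs

* NB upper tails use `pnbinom(k − 1, size = 1/phi, mu, lower.tail = FALSE)`;
  `phi = 0` switches to the exact Poisson tail (verified against direct
  mass-function summation to 1e-10 relative error).
* Z-scores use the population SD; zero-variance rows/segments/columns map
  to zeros rather than NaN.
* `observed = 0` scores `p = 1` and fold change ≤ 1; empty peak sets,
  empty genomes and empty site sets either produce valid empty results or
  fail fast with a named-stage error, never silently.
* Background fitting refuses to proceed with fewer than 30 background bins
  or an all-zero control.
* K-means requires at least `k` rows and is restarted if a degenerate
  initialization empties a cluster.

## Problem sizes

The test suite and the acceptance script run the full method at the
reference conditions above: recovery and false-discovery rates over
multiple independent simulations of 1,500 planted sites on 4-Mb genomes,
calibration on 20 null simulations, exhaustive oracle comparisons for
consensus calling (per-base brute force), motif scanning (offset × spacer ×
strand enumeration on 1,000 random sequences) and nearest-TSS assignment
(all-pairs), and byte-level determinism of the bundled demo pipeline. These
sizes were chosen so the whole suite re-runs in minutes on a laptop while
keeping every statistical check adequately powered.

## Known limitations

* Dense per-base tracks make mammalian-genome-scale inputs memory-hungry;
  the intended use is method development and desk-scale analyses.
* The background model is genome-wide; local (PeakSeq-style per-window)
  background estimation is not implemented.
* Only two factors are classified jointly; three-factor co-occupancy must
  be composed from pairwise runs.
* Motif scanning is match/no-match on IUPAC patterns; no position-weight
  scoring.
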