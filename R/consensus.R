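# Consensus binding regions and negative-binomial significance.
#
# The binding-site model: regions supported by >= 2 independent peak callers
# are candidates; each candidate's extended-read count is tested against an
# expected count from the scaled IgG control under a negative-binomial
# background (Poisson in the zero-dispersion limit), p-values are BH-adjusted
# across all candidates of one factor, and sites must pass read-count,
# fold-change and q-value thresholds.

#' Call consensus regions from a summed caller-occupancy track
#'
#' Extracts maximal runs of bases covered by at least `min_support` callers
#' and keeps runs of at least `min_length` bp.
#'
#' @param summed_track Coverage track of summed binary caller occupancy.
#' @param min_support Minimum number of supporting callers (default 2).
#' @param min_length Minimum region length in bp (default 150).
#' @return Interval tibble (`chrom`, `start`, `end`, `name`, `support`),
#'   sorted and non-overlapping; `support` is the maximum summed occupancy
#'   inside the region.
#' @export
call_consensus_regions <- function(summed_track, min_support = 2,
                                   min_length = 150) {
  if (min_support < 1) abort("`min_support` must be >= 1")
  if (min_length < 1) abort("`min_length` must be >= 1")
  pieces <- lapply(names(summed_track), function(chrom) {
    v <- summed_track[[chrom]]
    r <- rle(v >= min_support)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_length
    if (!any(keep)) return(NULL)
    s <- starts[keep]
    e <- ends[keep]
    support <- vapply(seq_along(s),
                      function(i) max(v[(s[i] + 1L):e[i]]), numeric(1))
    tibble(chrom = chrom, start = as.integer(s), end = as.integer(e),
           support = as.integer(support))
  })
  out <- bind_rows(pieces)
  if (nrow(out) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), support = integer()))
  }
  out$name <- sprintf("region_%d", seq_len(nrow(out)))
  out[, c("chrom", "start", "end", "name", "support")]
}

#' Fit the negative-binomial background model
#'
#' Tiles the genome into fixed-size bins, discards bins intersecting
#' `exclude` (typically the candidate regions), converts bin coverage sums to
#' read-equivalents via each track's mean read length, and estimates:
#' the control-to-sample scale as the ratio of total sample to total control
#' background counts (the value that equalizes the two libraries' background
#' levels; an ordinary zero-intercept regression slope is attenuated toward
#' zero by independent bin noise and would inflate fold changes), and the
#' background mean and overdispersion of sample bin counts by method of
#' moments
#' (`dispersion = max(0, (var - mean) / mean^2)`; 0 is the Poisson limit).
#'
#' @param sample,control `coverage_track`s on the same genome.
#' @param exclude Optional interval tibble of regions excluded from the
#'   background (candidate binding regions).
#' @param bin_size Bin size in bp (default 1000).
#' @return An object of class `nb_background`: list with `bin_size`, `mean`,
#'   `dispersion`, `scale`, `n_bins`.
#' @export
fit_background_model <- function(sample, control, exclude = NULL,
                                 bin_size = 1000) {
  check_same_genome(sample, control)
  rl_s <- attr(sample, "read_length")
  rl_c <- attr(control, "read_length")
  if (is.null(rl_s) || is.na(rl_s)) rl_s <- 200
  if (is.null(rl_c) || is.na(rl_c)) rl_c <- 200

  bin_counts <- function(track, read_length) {
    unlist(lapply(names(track), function(chrom) {
      v <- track[[chrom]]
      n_bins <- length(v) %/% bin_size
      if (n_bins == 0L) return(numeric(0))
      m <- matrix(v[seq_len(n_bins * bin_size)], nrow = bin_size)
      .colSums(m, bin_size, n_bins) / read_length
    }), use.names = FALSE)
  }
  sc <- bin_counts(sample, rl_s)
  cc <- bin_counts(control, rl_c)

  # drop bins intersecting excluded regions
  keep <- rep(TRUE, length(sc))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    bins <- bind_rows(lapply(names(sample), function(chrom) {
      n_bins <- length(sample[[chrom]]) %/% bin_size
      if (n_bins == 0L) return(NULL)
      tibble(chrom = chrom,
             start = as.integer((seq_len(n_bins) - 1L) * bin_size),
             end = as.integer(seq_len(n_bins) * bin_size))
    }))
    keep <- !overlaps_any(bins, exclude)
  }
  sc <- sc[keep]
  cc <- cc[keep]
  if (length(sc) < 30L) abort("fewer than 30 background bins remain")
  if (sum(cc) == 0) abort("control track has no background signal")

  scale <- sum(sc) / sum(cc)
  m <- mean(sc)
  v <- var(sc)
  if (m <= 0) abort("background mean is zero; cannot fit model")
  structure(
    list(bin_size = bin_size, mean = m,
         dispersion = max(0, (v - m) / m^2),
         scale = scale, n_bins = length(sc)),
    class = "nb_background"
  )
}

#' @export
print.nb_background <- function(x, ...) {
  cat(sprintf(
    "<nb_background> mean %.3f reads/%d bp, dispersion %.4f, scale %.4f (%d bins)\n",
    x$mean, x$bin_size, x$dispersion, x$scale, x$n_bins))
  invisible(x)
}

nb_upper_tail <- function(observed, expected, dispersion) {
  # P(X >= observed); NB parameterized by mean and dispersion phi
  # (var = mu + phi mu^2); phi = 0 is the Poisson limit.
  if (dispersion > 0) {
    pnbinom(observed - 1, size = 1 / dispersion, mu = expected,
            lower.tail = FALSE)
  } else {
    ppois(observed - 1, lambda = expected, lower.tail = FALSE)
  }
}

#' Score consensus regions against the IgG control
#'
#' For each region: `read_count` is the number of extended sample reads
#' overlapping it by at least 1 bp (each read counted once);
#' `control_count` likewise from the control reads; the expected count is
#' `max(scale * control_count, mean * region_length / bin_size)` (floored at
#' the genome-wide background rate); the fold change is
#' `(read_count + pseudocount) / (scale * control_count + pseudocount)`; and
#' the p-value is the negative-binomial upper tail `P(X >= read_count)` at
#' that expected mean with the fitted dispersion. q-values are BH-adjusted
#' across all regions supplied.
#'
#' @param regions Interval tibble of candidate consensus regions.
#' @param sample_reads,control_reads Extended-read interval tibbles.
#' @param bg A fitted `nb_background`.
#' @param pseudocount Pseudocount for the fold change (default 1).
#' @return `regions` with columns `read_count`, `control_count`,
#'   `fold_change`, `p_value`, `q_value` appended.
#' @export
score_regions <- function(regions, sample_reads, control_reads, bg,
                          pseudocount = 1) {
  if (!inherits(bg, "nb_background")) {
    abort("`bg` must be a fitted nb_background model")
  }
  out <- as_tibble(regions)
  out$read_count <- count_overlapping(regions, sample_reads)
  out$control_count <- count_overlapping(regions, control_reads)
  width <- out$end - out$start
  expected <- pmax(bg$scale * out$control_count,
                   bg$mean * width / bg$bin_size)
  out$fold_change <- (out$read_count + pseudocount) /
    (bg$scale * out$control_count + pseudocount)
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    nb_upper_tail(out$read_count[i], expected[i], bg$dispersion)
  }, numeric(1))
  out$q_value <- adjust_pvalues_bh(out$p_value)
  out
}

#' Benjamini--Hochberg adjustment
#'
#' Standard step-up FDR adjustment; input order is preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
adjust_pvalues_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Filter scored regions into a binding-site set
#'
#' Applies the selection thresholds: read count, fold change over the scaled
#' IgG control, and BH-adjusted q-value.
#'
#' @param scored Scored region tibble from [score_regions()].
#' @param min_reads Minimum read count (default 10).
#' @param min_fc Minimum fold change (default 2).
#' @param max_q Maximum adjusted p-value (default 0.01).
#' @param factor_name Optional factor label stored on the result.
#' @return Tibble of passing regions (order preserved) with attributes
#'   `factor_name` and `filter_params`.
#' @export
filter_binding_sites <- function(scored, min_reads = 10, min_fc = 2,
                                 max_q = 0.01, factor_name = NULL) {
  keep <- scored$read_count >= min_reads &
    scored$fold_change >= min_fc &
    scored$q_value <= max_q
  out <- scored[keep, , drop = FALSE]
  attr(out, "factor_name") <- factor_name
  attr(out, "filter_params") <- list(min_reads = min_reads, min_fc = min_fc,
                                     max_q = max_q)
  out
}

#' Full consensus binding-site detection for one factor
#'
#' Convenience driver chaining the per-factor stages: binarize each caller's
#' peaks, sum occupancy, call consensus regions (support >= `min_support`,
#' length >= `min_length`), fit the background model on bins that intersect
#' neither the candidates nor any single caller's peaks (potential binding
#' regions contaminate background estimates), score against the control,
#' and filter.
#'
#' @param caller_peaks List of >= 2 interval tibbles, one per peak caller.
#' @param sample_reads,control_reads Extended-read interval tibbles.
#' @param genome Genome index tibble.
#' @param min_support,min_length See [call_consensus_regions()].
#' @param bin_size Background bin size in bp.
#' @param min_reads,min_fc,max_q See [filter_binding_sites()].
#' @param factor_name Optional factor label.
#' @return List with `sites` (filtered binding-site tibble), `candidates`
#'   (all scored candidates) and `background` (the fitted model).
#' @export
consensus_binding_sites <- function(caller_peaks, sample_reads, control_reads,
                                    genome, min_support = 2, min_length = 150,
                                    bin_size = 1000, min_reads = 10,
                                    min_fc = 2, max_q = 0.01,
                                    factor_name = NULL) {
  if (length(caller_peaks) < 2L) {
    abort("consensus requires peaks from at least 2 callers")
  }
  tracks <- lapply(caller_peaks, binarize_occupancy, genome = genome)
  summed <- sum_binary_tracks(tracks)
  candidates <- call_consensus_regions(summed, min_support, min_length)
  sample_cov <- coverage_from_intervals(sample_reads, genome)
  control_cov <- coverage_from_intervals(control_reads, genome)
  # background bins must avoid *potential* binding regions, not only the
  # consensus candidates: a site reported by a single caller still carries
  # enrichment that would contaminate the mean/dispersion estimates
  potential <- bind_rows(c(caller_peaks, list(candidates)))
  bg <- fit_background_model(sample_cov, control_cov, exclude = potential,
                             bin_size = bin_size)
  scored <- score_regions(candidates, sample_reads, control_reads, bg)
  sites <- filter_binding_sites(scored, min_reads, min_fc, max_q, factor_name)
  list(sites = sites, candidates = scored, background = bg)
}
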