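# Per-base coverage and occupancy tracks.
#
# A coverage_track is a named list (one numeric vector per chromosome, 1-bp
# resolution, chromosome order taken from the genome index) with attributes
# `library_size` (number of intervals that built it) and `read_length` (their
# mean width, used to convert bin coverage sums back to read-equivalents).
# Dense vectors are deliberate: target genomes are desk-scale and per-base
# oracles stay exact.

new_coverage_track <- function(values, genome, library_size = NA_integer_,
                               read_length = NA_real_) {
  structure(values,
            library_size = library_size,
            read_length = read_length,
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), %s bp, library size %s\n",
              length(x), format(sum(lengths(x)), big.mark = ","),
              attr(x, "library_size")))
  invisible(x)
}

check_same_genome <- function(a, b) {
  if (!identical(names(a), names(b)) || !identical(lengths(a), lengths(b))) {
    abort("tracks are defined on different genomes")
  }
}

#' Extend reads in the 3' direction
#'
#' Each uniquely mapped read is replaced by a fixed-length interval anchored
#' at its 5' end: plus-strand (and unstranded) reads become
#' `[start, start + length)`, minus-strand reads `[end - length, end)`.
#' Results are clipped to chromosome bounds. Reads flagged non-unique (an
#' optional logical `unique` column) are dropped with a message.
#'
#' @param reads Interval tibble with optional `strand` and `unique` columns.
#' @param genome Genome index tibble.
#' @param length Extension length in bp (default 200).
#' @return Interval tibble of extended reads.
#' @export
extend_reads <- function(reads, genome, length = 200) {
  validate_genome(genome)
  validate_intervals(reads, genome, what = "read")
  if ("unique" %in% names(reads)) {
    n_drop <- sum(!reads$unique)
    if (n_drop > 0) {
      message(sprintf("dropping %d non-uniquely mapped read(s)", n_drop))
      reads <- reads[reads$unique, , drop = FALSE]
    }
  }
  strand <- if ("strand" %in% names(reads)) reads$strand else rep(".", nrow(reads))
  minus <- strand == "-"
  start <- ifelse(minus, reads$end - length, reads$start)
  end <- ifelse(minus, reads$end, reads$start + length)
  sizes <- chrom_sizes_lookup(genome)
  out <- reads
  out$start <- as.integer(pmax(0, start))
  out$end <- as.integer(pmin(sizes[reads$chrom], end))
  out
}

#' Build a per-base coverage track from intervals
#'
#' Value at each base equals the number of intervals covering it.
#'
#' @param intervals Interval tibble.
#' @param genome Genome index tibble.
#' @return A `coverage_track` carrying `library_size` (interval count) and
#'   `read_length` (mean interval width) attributes.
#' @export
coverage_from_intervals <- function(intervals, genome) {
  validate_genome(genome)
  validate_intervals(intervals, genome, what = "interval")
  sizes <- chrom_sizes_lookup(genome)
  values <- lapply(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]
    L <- genome$size[i]
    sel <- intervals$chrom == chrom
    if (!any(sel)) return(numeric(L))
    d <- tabulate(intervals$start[sel] + 1L, nbins = L + 1L) -
      tabulate(intervals$end[sel] + 1L, nbins = L + 1L)
    cumsum(d)[seq_len(L)]
  })
  names(values) <- genome$chrom
  new_coverage_track(values, genome,
                     library_size = nrow(intervals),
                     read_length = if (nrow(intervals)) {
                       mean(intervals$end - intervals$start)
                     } else NA_real_)
}

#' Binary occupancy track from peaks
#'
#' Assigns 1 to every base inside any peak and 0 elsewhere. The union is
#' idempotent: overlapping peaks never produce values above 1.
#'
#' @param peaks Interval tibble of predicted binding regions.
#' @param genome Genome index tibble.
#' @return A `binary_track` (coverage_track of 0/1 values).
#' @export
binarize_occupancy <- function(peaks, genome) {
  cov <- coverage_from_intervals(peaks, genome)
  values <- lapply(cov, function(v) as.numeric(v > 0))
  structure(new_coverage_track(values, genome, library_size = nrow(peaks)),
            class = c("binary_track", "coverage_track"))
}

#' Sum binary occupancy tracks across peak callers
#'
#' @param tracks List of `binary_track`s on the same genome.
#' @return A `coverage_track` whose value at each base is the number of
#'   callers whose peaks cover it.
#' @export
sum_binary_tracks <- function(tracks) {
  if (length(tracks) == 0L) abort("no tracks supplied")
  for (t in tracks[-1]) check_same_genome(tracks[[1]], t)
  values <- tracks[[1]]
  for (t in tracks[-1]) {
    for (chrom in names(values)) values[[chrom]] <- values[[chrom]] + t[[chrom]]
  }
  structure(unclass(values), class = "coverage_track",
            library_size = NA_integer_, read_length = NA_real_)
}

#' Background-equalized control subtraction
#'
#' Scales the control track so sample and control share the same background
#' level (scale factor from the fitted background model) and subtracts it
#' from the sample, clamping at zero by default.
#'
#' @param sample,control `coverage_track`s on the same genome.
#' @param bg A fitted `nb_background` (provides the scale factor), or `NULL`
#'   together with an explicit `scale`.
#' @param scale Control-to-sample scale; defaults to `bg$scale`.
#' @param clamp Clamp negative values at zero (default `TRUE`).
#' @return A `coverage_track` of subtracted signal.
#' @export
subtract_control <- function(sample, control, bg = NULL,
                             scale = if (!is.null(bg)) bg$scale else 1,
                             clamp = TRUE) {
  check_same_genome(sample, control)
  values <- lapply(names(sample), function(chrom) {
    d <- sample[[chrom]] - scale * control[[chrom]]
    if (clamp) pmax(0, d) else d
  })
  names(values) <- names(sample)
  structure(values, class = "coverage_track",
            library_size = attr(sample, "library_size"),
            read_length = attr(sample, "read_length"))
}

# IRanges-backed overlap counting: for each query interval, the number of
# subject intervals overlapping it by >= 1 bp.
count_overlapping <- function(query, subject) {
  counts <- integer(nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(counts)
  for (chrom in unique(query$chrom)) {
    qi <- which(query$chrom == chrom)
    si <- which(subject$chrom == chrom)
    if (length(si) == 0L) next
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    counts[qi] <- IRanges::countOverlaps(qr, sr)
  }
  counts
}

# For each query interval, TRUE iff it overlaps any subject interval.
overlaps_any <- function(query, subject) {
  count_overlapping(query, subject) > 0L
}
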