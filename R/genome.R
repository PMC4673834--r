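# Genome model and interval I/O.
#
# Coordinate convention throughout the package: 0-based, half-open [start, end),
# i.e. BED native. Interval tables are tibbles with at least the columns
# `chrom`, `start`, `end`; `name`, `score`, `strand` are optional and defaulted
# on read.

#' Read a chromosome sizes file
#'
#' Parses the standard two-column `chrom.sizes` format (chromosome name,
#' length in bp, whitespace-separated) into a genome index. Chromosome order
#' in the file is preserved and used for all downstream outputs.
#'
#' @param path Path to a two-column text file.
#' @return A tibble with columns `chrom` (character) and `size` (integer bp),
#'   one row per chromosome, in file order.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1\t10000", "chr2\t5000"), tf)
#' read_chrom_sizes(tf)
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  chrom <- character(length(keep))
  size <- integer(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) != 2L) {
      abort(sprintf("chrom.sizes line %d: expected 2 fields, found %d",
                    ln, length(fields)))
    }
    len <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(len) || len <= 0 || len != floor(len)) {
      abort(sprintf("chrom.sizes line %d: invalid length '%s'", ln, fields[2]))
    }
    chrom[i] <- fields[1]
    size[i] <- as.integer(len)
  }
  if (anyDuplicated(chrom)) {
    abort(sprintf("duplicate chromosome name: %s",
                  chrom[duplicated(chrom)][1]))
  }
  tibble(chrom = chrom, size = size)
}

#' Construct a genome index from vectors
#'
#' @param chrom Chromosome names (unique).
#' @param size Chromosome lengths in bp (positive integers).
#' @return A genome index tibble (`chrom`, `size`).
#' @export
genome_index <- function(chrom, size) {
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  if (any(size <= 0)) abort("chromosome lengths must be positive")
  tibble(chrom = as.character(chrom), size = as.integer(size))
}

validate_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("chrom", "size") %in% names(genome))) {
    abort("`genome` must be a tibble with columns `chrom` and `size`")
  }
  if (nrow(genome) == 0L) abort("genome index is empty")
  invisible(genome)
}

chrom_sizes_lookup <- function(genome) {
  setNames(as.numeric(genome$size), genome$chrom)
}

validate_intervals <- function(x, genome = NULL, what = "interval") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("%s table must have columns `chrom`, `start`, `end`", what))
  }
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad)) {
    abort(sprintf("%s %d: invalid coordinates [%s, %s)", what, bad[1],
                  x$start[bad[1]], x$end[bad[1]]))
  }
  if (!is.null(genome)) {
    sizes <- chrom_sizes_lookup(genome)
    unknown <- which(!(x$chrom %in% names(sizes)))
    if (length(unknown)) {
      abort(sprintf("%s %d: chromosome '%s' not in genome index",
                    what, unknown[1], x$chrom[unknown[1]]))
    }
    over <- which(x$end > sizes[x$chrom])
    if (length(over)) {
      abort(sprintf("%s %d: end %s exceeds length of %s",
                    what, over[1], x$end[over[1]], x$chrom[over[1]]))
    }
  }
  invisible(x)
}

#' Read a BED3--BED6 file into an interval tibble
#'
#' Missing columns are defaulted: `name` to `"."`, `score` to `0`, `strand`
#' to `"."`. Coordinates are validated against `genome` when supplied.
#'
#' @param path Path to a BED file (3 to 6 columns, whitespace-separated).
#' @param genome Optional genome index tibble for coordinate validation.
#' @param keep_extra Keep columns beyond the sixth (as `extra1`, `extra2`, ...)?
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` in file order.
#' @export
read_bed <- function(path, genome = NULL, keep_extra = FALSE) {
  df <- tryCatch(
    read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
               colClasses = "character", comment.char = "#", quote = ""),
    error = function(e) NULL
  )
  if (is.null(df)) {
    # empty file
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character()))
  }
  nc <- ncol(df)
  if (nc < 3L) abort(sprintf("BED file '%s': fewer than 3 columns", path))
  out <- tibble(
    chrom = df[[1]],
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    name = if (nc >= 4) df[[4]] else ".",
    score = if (nc >= 5) suppressWarnings(as.numeric(df[[5]])) else 0,
    strand = if (nc >= 6) df[[6]] else "."
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    abort(sprintf("BED file '%s': non-numeric coordinates", path))
  }
  bad_strand <- !(out$strand %in% c("+", "-", "."))
  if (any(bad_strand)) {
    abort(sprintf("BED file '%s' line %d: invalid strand '%s'",
                  path, which(bad_strand)[1], out$strand[which(bad_strand)[1]]))
  }
  validate_intervals(out, genome, what = sprintf("BED '%s' record", basename(path)))
  if (keep_extra && nc > 6L) {
    for (j in 7:nc) out[[paste0("extra", j - 6L)]] <- df[[j]]
  }
  out
}

#' Write an interval tibble as BED
#'
#' Writes BED6 (`chrom`, `start`, `end`, `name`, `score`, `strand`, defaults
#' filled in) followed by any additional columns present (BED6+). Output is
#' deterministic byte-for-byte.
#'
#' @param x Interval tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  n <- nrow(x)
  out <- data.frame(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(x)) x$name else rep(".", n),
    score = if ("score" %in% names(x)) x$score else rep(0, n),
    strand = if ("strand" %in% names(x)) x$strand else rep(".", n),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(x), c("chrom", "start", "end", "name", "score", "strand"))
  for (col in extra) out[[col]] <- x[[col]]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Emits maximal constant-value runs; zero-valued runs are omitted.
#'
#' @param track A `coverage_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    r <- rle(as.numeric(track[[chrom]]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                         format(r$values[keep], scientific = FALSE, trim = TRUE)),
                 con)
    }
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Bases not covered by any record are zero.
#'
#' @param path Path to a bedGraph file.
#' @param genome Genome index tibble defining track dimensions.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, genome) {
  validate_genome(genome)
  values <- lapply(chrom_sizes_lookup(genome), function(L) numeric(L))
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    df <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
    validate_intervals(
      tibble(chrom = df[[1]], start = df[[2]], end = df[[3]]),
      genome, what = "bedGraph record")
    for (i in seq_len(nrow(df))) {
      values[[df[[1]][i]]][(df[[2]][i] + 1L):df[[3]][i]] <- df[[4]][i]
    }
  }
  new_coverage_track(values, genome)
}
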