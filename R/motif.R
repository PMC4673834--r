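# Composite-motif scanning with a variable-length spacer.
#
# Patterns are bipartite IUPAC strings joined by an unconstrained spacer of
# bounded length, e.g. the E-box/GATA signature CTG-N(6-8)-WGATAR bound by
# the LDB1 transcription-factor complex. Matching is case-insensitive; an N
# in the subject sequence (masked/unknown base) matches nothing except a
# pattern N, so masked runs cannot create spurious composite hits.

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", V = "B", D = "H", H = "D", N = "N")

check_iupac <- function(s, what = "pattern") {
  chars <- strsplit(toupper(s), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_BITS))
  if (length(bad)) {
    abort(sprintf("invalid IUPAC code '%s' in %s '%s'", bad[1], what, s))
  }
  chars
}

revcomp_iupac <- function(s) {
  chars <- check_iupac(s)
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Define a composite motif pattern
#'
#' @param left,right IUPAC strings for the two fixed parts (non-empty).
#' @param spacer_min,spacer_max Bounds (bp) on the unconstrained spacer.
#' @return An object of class `motif_pattern`.
#' @export
#' @examples
#' motif_pattern("CTG", 6, 8, "WGATAR") # composite E-box/GATA signature
motif_pattern <- function(left, spacer_min, spacer_max, right) {
  if (nchar(left) == 0 || nchar(right) == 0) {
    abort("pattern parts must be non-empty")
  }
  if (spacer_min > spacer_max || spacer_min < 0) {
    abort("spacer bounds must satisfy 0 <= min <= max")
  }
  check_iupac(left)
  check_iupac(right)
  structure(list(left = toupper(left), spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max),
                 right = toupper(right)),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %sN(%d-%d)%s\n", x$left, x$spacer_min,
              x$spacer_max, x$right))
  invisible(x)
}

#' Parse a composite pattern from text notation
#'
#' Accepts `"CTGN(6-8)WGATAR"` or `"CTGN{6,8}WGATAR"`.
#'
#' @param text Pattern string.
#' @return A `motif_pattern`.
#' @export
parse_motif_pattern <- function(text) {
  m <- regmatches(text, regexec(
    "^([A-Za-z]+)N[({](\\d+)[-,](\\d+)[)}]([A-Za-z]+)$", text))[[1]]
  if (length(m) != 5L) {
    abort(sprintf("cannot parse composite pattern '%s'", text))
  }
  motif_pattern(m[2], as.integer(m[3]), as.integer(m[4]), m[5])
}

#' The bundled default: the composite E-box/GATA motif CTGN(6-8)WGATAR
#' @return A `motif_pattern`.
#' @export
composite_ebox_gata <- function() motif_pattern("CTG", 6, 8, "WGATAR")

# subject encoding: ACGT -> single bits; any other character (N, masked
# unknowns) -> 0 so it matches only pattern N.
encode_subject <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- IUPAC_BITS[chars]
  codes[is.na(codes) | !(chars %in% c("A", "C", "G", "T"))] <- 0L
  unname(codes)
}

# positions where every fixed pattern base is compatible, for one oriented
# pattern (left, spacer length, right); returns 1-based offsets
match_offsets <- function(s_codes, left_chars, spacer, right_chars) {
  nl <- length(left_chars)
  nr <- length(right_chars)
  total <- nl + spacer + nr
  n <- length(s_codes)
  if (n < total) return(integer(0))
  npos <- n - total + 1L
  ok <- rep(TRUE, npos)
  pos <- c(seq_len(nl), nl + spacer + seq_len(nr))
  chars <- c(left_chars, right_chars)
  for (j in seq_along(pos)) {
    if (chars[j] == "N") next  # pattern N matches any subject base
    mask <- IUPAC_BITS[[chars[j]]]
    sub <- s_codes[pos[j]:(pos[j] + npos - 1L)]
    ok <- ok & bitwAnd(mask, sub) > 0L
    if (!any(ok)) return(integer(0))
  }
  which(ok)
}

#' Scan one sequence for a composite motif
#'
#' Reports every (offset, spacer length, strand) combination whose fixed
#' bases satisfy the pattern. Minus-strand hits are found by scanning the
#' forward sequence with the reverse complement of the pattern and are
#' reported in forward coordinates.
#'
#' @param seq A character string (DNA; case-insensitive).
#' @param pattern A `motif_pattern`.
#' @param both_strands Scan the minus strand too (default `TRUE`)?
#' @param site_id Optional id recorded on each hit.
#' @return Tibble of hits: `site_id`, `offset` (0-based), `length`, `spacer`,
#'   `strand`.
#' @export
scan_sequence <- function(seq, pattern, both_strands = TRUE, site_id = NA) {
  if (!inherits(pattern, "motif_pattern")) {
    abort("`pattern` must be a motif_pattern")
  }
  s_codes <- encode_subject(seq)
  left_f <- check_iupac(pattern$left)
  right_f <- check_iupac(pattern$right)
  left_r <- check_iupac(revcomp_iupac(pattern$right))
  right_r <- check_iupac(revcomp_iupac(pattern$left))
  hits <- list()
  for (spacer in pattern$spacer_min:pattern$spacer_max) {
    total <- length(left_f) + spacer + length(right_f)
    off <- match_offsets(s_codes, left_f, spacer, right_f)
    if (length(off)) {
      hits[[length(hits) + 1L]] <- tibble(
        site_id = site_id, offset = off - 1L, length = total,
        spacer = spacer, strand = "+")
    }
    if (both_strands) {
      off <- match_offsets(s_codes, left_r, spacer, right_r)
      if (length(off)) {
        hits[[length(hits) + 1L]] <- tibble(
          site_id = site_id, offset = off - 1L, length = total,
          spacer = spacer, strand = "-")
      }
    }
  }
  if (!length(hits)) {
    return(tibble(site_id = site_id[0], offset = integer(), length = integer(),
                  spacer = integer(), strand = character()))
  }
  arrange(bind_rows(hits), .data$offset, .data$spacer, .data$strand)
}

#' Fetch fixed-width sequences centered on binding sites
#'
#' Retrieves `width` bases centered on each site center
#' (`[center - width/2, center + width/2)`) from a soft-masked FASTA (or a
#' named character vector of chromosome sequences). Windows extending past
#' chromosome ends are N-padded by default. Lowercase (soft-masked) and N
#' bases count as masked.
#'
#' @param sites Tibble with `chrom` and `center` columns (or `start`/`end`,
#'   from which centers are derived).
#' @param fasta Path to a FASTA file, or a named character vector.
#' @param width Sequence width in bp (default 200).
#' @param pad N-pad out-of-range windows (default `TRUE`; otherwise error).
#' @return Tibble with `site_id`, `seq`, `masked` (masked-base count).
#' @export
fetch_site_sequences <- function(sites, fasta, width = 200, pad = TRUE) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    x <- Biostrings::readBStringSet(fasta)
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    fasta
  } else {
    abort("`fasta` must be a FASTA path or a named character vector")
  }
  centers <- if ("center" %in% names(sites)) sites$center else
    interval_centers(sites)
  ids <- if ("site_id" %in% names(sites)) sites$site_id
  else if ("name" %in% names(sites)) sites$name
  else sprintf("site_%d", seq_len(nrow(sites)))
  half <- width %/% 2L
  out_seq <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    if (!chrom %in% names(seqs)) {
      abort(sprintf("chromosome '%s' missing from FASTA", chrom))
    }
    L <- nchar(seqs[[chrom]])
    lo <- centers[i] - half        # 0-based
    hi <- lo + width
    if ((lo < 0 || hi > L) && !pad) {
      abort(sprintf("site %s window [%d, %d) outside chromosome", ids[i], lo, hi))
    }
    s <- substr(seqs[[chrom]], max(lo, 0) + 1L, min(hi, L))
    out_seq[i] <- paste0(strrep("N", max(0, -lo)), s,
                         strrep("N", max(0, hi - L)))
  }
  tibble(site_id = ids, seq = out_seq,
         masked = vapply(out_seq, count_masked, integer(1), USE.NAMES = FALSE))
}

count_masked <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  sum(chars %in% c("a", "c", "g", "t", "n", "N"))
}

#' Drop heavily repeat-masked site sequences
#'
#' Removes sites whose masked-base count reaches `max_masked` (inclusive
#' bound: a site with exactly `max_masked` masked bases is removed).
#'
#' @param seqs Site-sequence tibble from [fetch_site_sequences()].
#' @param max_masked Masked-bp threshold (default 150).
#' @return Filtered tibble.
#' @export
filter_repeat_masked <- function(seqs, max_masked = 150) {
  seqs[seqs$masked < max_masked, , drop = FALSE]
}

#' Draw a random subset of sites
#'
#' Uniform sampling without replacement; deterministic per seed. Used to draw
#' representative site sets per co-binding class before motif analysis.
#'
#' @param sites Tibble of sites.
#' @param n Subset size (must not exceed `nrow(sites)`).
#' @param seed Integer seed.
#' @return Tibble of `n` rows.
#' @export
sample_sites <- function(sites, n, seed = 1) {
  if (n > nrow(sites)) {
    abort(sprintf("cannot sample %d from %d sites", n, nrow(sites)))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  sites[sample.int(nrow(sites), n), , drop = FALSE]
}

#' Scan a set of site sequences
#'
#' @param seqs Site-sequence tibble (`site_id`, `seq`).
#' @param pattern A `motif_pattern`.
#' @param both_strands Scan both strands (default `TRUE`)?
#' @return Tibble of all hits across sites.
#' @export
scan_sites <- function(seqs, pattern, both_strands = TRUE) {
  bind_rows(lapply(seq_len(nrow(seqs)), function(i) {
    scan_sequence(seqs$seq[i], pattern, both_strands,
                  site_id = seqs$site_id[i])
  }))
}

#' Proportion of sites containing a motif
#'
#' A site counts once however many hits it contains; the instance count is
#' reported alongside.
#'
#' @param seqs Site-sequence tibble (already repeat-filtered).
#' @param pattern A `motif_pattern`.
#' @param both_strands Scan both strands (default `TRUE`)?
#' @param min_sites Report `NA` fraction when fewer than `min_sites` sites
#'   carry the motif (support threshold; default 0 = always report).
#' @return One-row tibble: `n_total`, `n_with_motif`, `fraction`, `n_hits`.
#' @export
motif_site_proportion <- function(seqs, pattern, both_strands = TRUE,
                                  min_sites = 0) {
  if (nrow(seqs) == 0L) abort("no site sequences supplied")
  hits <- scan_sites(seqs, pattern, both_strands)
  n_with <- length(unique(hits$site_id))
  tibble(n_total = nrow(seqs), n_with_motif = n_with,
         fraction = if (n_with >= min_sites) n_with / nrow(seqs) else NA_real_,
         n_hits = nrow(hits))
}
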