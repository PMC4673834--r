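# Independent brute-force oracles used to validate the optimized
# implementations. These deliberately share no code with the package paths
# they check.

# per-base recomputation of the consensus rule: mark every base with summed
# caller occupancy >= min_support, then walk the flag vector collecting runs
# and keep those of sufficient length
oracle_consensus <- function(summed_track, min_support = 2, min_length = 150) {
  out <- list()
  for (chrom in names(summed_track)) {
    flag <- summed_track[[chrom]] >= min_support
    runs <- list()
    i <- 1L
    L <- length(flag)
    while (i <= L) {
      if (flag[i]) {
        j <- i
        while (j < L && flag[j + 1L]) j <- j + 1L
        if (j - i + 1L >= min_length) {
          runs[[length(runs) + 1L]] <- c(i - 1L, j)  # 0-based half-open
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    for (r in runs) {
      out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = r[1],
                                            end = r[2])
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  do.call(rbind, out)
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

revcomp_string <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- rev(strsplit(toupper(seq), "")[[1]])
  paste(comp[chars], collapse = "")
}

# enumerate every offset x spacer x strand and check base-by-base IUPAC
# compatibility; subject N matches only pattern N (IUPAC_SETS$N includes "N")
oracle_scan <- function(seq, left = "CTG", smin = 6, smax = 8,
                        right = "WGATAR", both_strands = TRUE) {
  scan_one_strand <- function(chars, n) {
    hits <- list()
    for (spacer in smin:smax) {
      pat <- c(strsplit(left, "")[[1]], rep(NA_character_, spacer),
               strsplit(right, "")[[1]])
      total <- length(pat)
      if (n < total) next
      for (o in seq_len(n - total + 1L)) {
        ok <- TRUE
        for (j in seq_along(pat)) {
          pc <- pat[j]
          if (is.na(pc)) next
          if (!(chars[o + j - 1L] %in% IUPAC_SETS[[pc]])) { ok <- FALSE; break }
        }
        if (ok) hits[[length(hits) + 1L]] <- c(o - 1L, total, spacer)
      }
    }
    hits
  }
  n <- nchar(seq)
  fw <- scan_one_strand(strsplit(toupper(seq), "")[[1]], n)
  res <- lapply(fw, function(h) data.frame(offset = h[1], length = h[2],
                                           spacer = h[3], strand = "+"))
  if (both_strands) {
    # scan the reverse complement of the subject; map back to forward coords
    rv <- scan_one_strand(strsplit(revcomp_string(seq), "")[[1]], n)
    res <- c(res, lapply(rv, function(h) {
      data.frame(offset = n - h[1] - h[2], length = h[2], spacer = h[3],
                 strand = "-")
    }))
  }
  if (!length(res)) {
    return(data.frame(offset = integer(), length = integer(),
                      spacer = integer(), strand = character()))
  }
  out <- do.call(rbind, res)
  out[order(out$offset, out$spacer, out$strand), , drop = FALSE]
}

# naive O(m^2) Benjamini-Hochberg step-up: q_i = min over ranks j with
# p_(j) >= p_i of p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# all-pairs nearest-TSS assignment with explicit tie-breaking
oracle_nearest_gene <- function(sites, genes, max_distance = 1e6) {
  centers <- if ("center" %in% names(sites)) sites$center else
    (sites$start + sites$end) %/% 2
  gene <- rep(NA_character_, nrow(sites))
  distance <- rep(NA_real_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    g <- genes[genes$chrom == sites$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- centers[i] - g$tss
    ord <- order(abs(d), g$tss, g$name)
    best <- ord[1]
    if (abs(d[best]) <= max_distance) {
      gene[i] <- g$name[best]
      distance[i] <- d[best]
    }
  }
  data.frame(gene = gene, distance = distance, stringsAsFactors = FALSE)
}

# exact Poisson survival P(X >= k) by direct summation of the mass function
oracle_poisson_survival <- function(k, lambda) {
  if (k <= 0) return(1)
  upper <- max(k + 50, ceiling(lambda + 40 * sqrt(lambda) + 50))
  sum(dpois(k:upper, lambda))
}

random_genome <- function(n_chrom = 1, len = 10000) {
  genome_index(sprintf("chr%d", seq_len(n_chrom)), rep(len, n_chrom))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
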