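# Ground-truthed synthetic data generator.
#
# Emulates the statistical structure the pipeline assumes: a small genome with
# soft-masked repeat stretches, planted binding sites of two factors with a
# controllable shared fraction, negative-binomial background coverage for the
# enriched samples and the IgG control, three imperfect peak-caller outputs,
# composite motifs embedded at shared/A-class sites, and a gene annotation.
# Every artifact is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 1,500 sites with class fractions (shared, A-only, B-only) =
#' (0.6, 0.2, 0.2), 30 expected reads per bound site per factor, a
#' negative-binomial background of 1 read/kb with dispersion 0.2, three
#' callers at 90% sensitivity, and composite motifs embedded at 90% of
#' shared and A-only sites.
#'
#' @param seed Master seed; every stage derives its RNG stream from it.
#' @param n_chromosomes,chrom_length Genome shape (bp per chromosome).
#' @param n_sites Number of planted binding sites.
#' @param class_fractions Named fractions `shared`, `a_only`, `b_only`
#'   (must sum to 1).
#' @param enrichment Expected reads per bound site per bound factor.
#' @param background_rate Background reads per kb.
#' @param nb_dispersion Negative-binomial overdispersion of background bin
#'   counts (0 = Poisson).
#' @param motif_prob Named per-class probabilities of embedding a composite
#'   motif at a site.
#' @param repeat_fraction Fraction of the genome soft-masked (lowercase).
#' @param caller_sensitivity Per-caller probability of reporting a true site.
#' @param caller_fp_rate Spurious peaks per Mb per caller.
#' @param caller_jitter_sd SD (bp) of peak boundary jitter.
#' @param caller_halfwidth Half-width (bp) of reported peaks.
#' @param n_genes Number of annotated genes.
#' @param read_length Emitted read-interval length in bp.
#' @param site_read_sd SD (bp) of site-read placement around the center.
#' @param min_spacing Minimum spacing between planted site centers (bp).
#' @param with_sequence Generate genome sequence (needed for motif stages)?
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       chrom_length = 2e6,
                       n_sites = 1500,
                       class_fractions = c(shared = 0.6, a_only = 0.2,
                                           b_only = 0.2),
                       enrichment = 30,
                       background_rate = 1,
                       nb_dispersion = 0.2,
                       motif_prob = c(shared = 0.9, a_only = 0.9, b_only = 0),
                       repeat_fraction = 0.1,
                       caller_sensitivity = 0.9,
                       caller_fp_rate = 2,
                       caller_jitter_sd = 30,
                       caller_halfwidth = 300,
                       n_genes = 60,
                       read_length = 200,
                       site_read_sd = 60,
                       min_spacing = 2000,
                       with_sequence = FALSE) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  stopifnot(
    cfg$n_chromosomes >= 1, cfg$chrom_length > 0, cfg$n_sites >= 0,
    cfg$enrichment >= 0, cfg$background_rate >= 0, cfg$nb_dispersion >= 0,
    cfg$repeat_fraction >= 0, cfg$repeat_fraction <= 1,
    cfg$caller_sensitivity >= 0, cfg$caller_sensitivity <= 1,
    cfg$caller_fp_rate >= 0, cfg$n_genes >= 0, cfg$read_length > 0
  )
  if (abs(sum(cfg$class_fractions) - 1) > 1e-8 ||
      any(cfg$class_fractions < 0)) {
    abort("`class_fractions` must be non-negative and sum to 1")
  }
  if (!all(c("shared", "a_only", "b_only") %in% names(cfg$class_fractions))) {
    abort("`class_fractions` must be named shared/a_only/b_only")
  }
  if (any(cfg$motif_prob < 0 | cfg$motif_prob > 1)) {
    abort("`motif_prob` entries must lie in [0, 1]")
  }
  cfg
}

# each stage runs under its own deterministic stream derived from the master
# seed; the caller's RNG state is untouched
with_stage_seed <- function(config, offset, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed((config$seed * 101 + offset) %% 2147483647L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  force(expr)
}

#' Simulate a genome (index and optionally soft-masked sequence)
#'
#' Uniform-random A/C/G/T sequence with contiguous lowercase (soft-masked)
#' stretches covering approximately `repeat_fraction` of each chromosome.
#'
#' @param config A `sim_config`.
#' @return List with `genome` (index tibble) and `sequences` (named character
#'   vector, or `NULL` when `with_sequence` is `FALSE`).
#' @export
simulate_genome <- function(config) {
  genome <- genome_index(sprintf("chr%d", seq_len(config$n_chromosomes)),
                         rep(config$chrom_length, config$n_chromosomes))
  sequences <- NULL
  if (config$with_sequence) {
    sequences <- with_stage_seed(config, 0, {
      out <- lapply(genome$size, function(L) {
        chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        if (config$repeat_fraction > 0) {
          masked <- logical(L)
          target <- round(config$repeat_fraction * L)
          while (sum(masked) < target) {
            len <- min(50L + ceiling(rexp(1, 1 / 450)), L)
            pos <- sample.int(L - len + 1L, 1L)
            masked[pos:(pos + len - 1L)] <- TRUE
          }
          chars[masked] <- tolower(chars[masked])
        }
        paste(chars, collapse = "")
      })
      setNames(unlist(out), genome$chrom)
    })
  }
  list(genome = genome, sequences = sequences)
}

#' Plant the binding landscape
#'
#' Site centers are uniform with a minimum spacing; classes are drawn from
#' the configured fractions; a concrete instance of the composite
#' CTG-N(6-8)-WGATAR motif is written into the sequence (uppercase) at
#' shared/A-class sites with the configured per-class probability.
#'
#' @param config A `sim_config`.
#' @param genome Genome index tibble.
#' @param sequences Optional named character vector of chromosome sequences;
#'   when supplied it is returned with motifs embedded.
#' @return List with `truth` (tibble: `site_id`, `chrom`, `center`, `class`,
#'   `enrich_a`, `enrich_b`, `motif`, `motif_spacer`) and `sequences`.
#' @export
simulate_binding_landscape <- function(config, genome, sequences = NULL) {
  n <- config$n_sites
  if (n == 0L) {
    return(list(truth = tibble(
      site_id = character(), chrom = character(), center = integer(),
      class = character(), enrich_a = numeric(), enrich_b = numeric(),
      motif = logical(), motif_spacer = integer()), sequences = sequences))
  }
  margin <- 1500
  gap <- config$min_spacing
  alloc <- diff(c(0, round(cumsum(genome$size / sum(genome$size)) * n)))

  res <- with_stage_seed(config, 1, {
    centers <- list()
    for (i in seq_len(nrow(genome))) {
      n_c <- alloc[i]
      if (n_c == 0L) { centers[[i]] <- integer(0); next }
      slack <- genome$size[i] - 2 * margin - (n_c - 1) * gap
      if (slack <= 0) abort("genome too small for requested sites and spacing")
      centers[[i]] <- as.integer(round(
        sort(runif(n_c, 0, slack)) + margin + gap * (seq_len(n_c) - 1)))
    }
    truth <- tibble(
      site_id = sprintf("truth_%d", seq_len(n)),
      chrom = rep(genome$chrom, lengths(centers)),
      center = unlist(centers),
      class = sample(names(config$class_fractions), n, replace = TRUE,
                     prob = config$class_fractions)
    )
    truth$enrich_a <- ifelse(truth$class != "b_only", config$enrichment, 0)
    truth$enrich_b <- ifelse(truth$class != "a_only", config$enrichment, 0)
    truth$motif <- runif(n) < config$motif_prob[truth$class]
    truth$motif_spacer <- ifelse(truth$motif,
                                 sample(6:8, n, replace = TRUE), NA_integer_)
    if (!is.null(sequences)) {
      for (i in which(truth$motif)) {
        spacer <- paste(sample(c("A", "C", "G", "T"), truth$motif_spacer[i],
                               replace = TRUE), collapse = "")
        inst <- paste0("CTG", spacer, sample(c("A", "T"), 1), "GATA",
                       sample(c("A", "G"), 1))
        start0 <- truth$center[i] - nchar(inst) %/% 2L  # 0-based
        chrom <- truth$chrom[i]
        substr(sequences[[chrom]], start0 + 1L, start0 + nchar(inst)) <- inst
      }
    }
    list(truth = truth, sequences = sequences)
  })
  res
}

#' Simulate extended-read intervals for one track
#'
#' Background reads: per-kb counts drawn from the negative binomial (Poisson
#' when dispersion is 0) with uniform positions inside each kb; site reads:
#' Poisson(`enrichment`) per site bound by the factor, placed
#' Normal(center, `site_read_sd`) truncated to the chromosome. The IgG track
#' receives background only. All reads are emitted directly as
#' `read_length`-bp intervals (alignment and 3' extension are upstream of
#' this generator's scope).
#'
#' @param truth Truth tibble from [simulate_binding_landscape()].
#' @param config A `sim_config`.
#' @param genome Genome index tibble.
#' @param factor `"A"`, `"B"` or `"IgG"`.
#' @return Extended-read interval tibble.
#' @export
simulate_coverage <- function(truth, config, genome,
                              factor = c("A", "B", "IgG")) {
  factor <- match.arg(factor)
  offset <- c(A = 2, B = 3, IgG = 4)[[factor]]
  rl <- config$read_length
  half <- rl %/% 2L
  with_stage_seed(config, offset, {
    pieces <- lapply(seq_len(nrow(genome)), function(ci) {
      chrom <- genome$chrom[ci]
      L <- genome$size[ci]
      n_kb <- L %/% 1000L
      counts <- if (config$nb_dispersion > 0) {
        rnbinom(n_kb, mu = config$background_rate,
                size = 1 / config$nb_dispersion)
      } else {
        rpois(n_kb, config$background_rate)
      }
      bg_pos <- runif(sum(counts),
                      min = rep((seq_len(n_kb) - 1) * 1000, counts),
                      max = rep(seq_len(n_kb) * 1000, counts))
      starts <- floor(bg_pos)

      if (factor != "IgG") {
        mu <- if (factor == "A") "enrich_a" else "enrich_b"
        st <- truth[truth$chrom == chrom & truth[[mu]] > 0, , drop = FALSE]
        if (nrow(st)) {
          n_i <- rpois(nrow(st), st[[mu]])
          ctr <- rnorm(sum(n_i), mean = rep(st$center, n_i),
                       sd = config$site_read_sd)
          ctr <- pmin(pmax(ctr, 0), L)
          starts <- c(starts, floor(ctr) - half)
        }
      }
      if (!length(starts)) return(NULL)
      tibble(chrom = chrom,
             start = as.integer(pmax(0, starts)),
             end = as.integer(pmin(L, starts + rl)))
    })
    out <- bind_rows(pieces)
    if (nrow(out) == 0L) {
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    name = character(), score = numeric(),
                    strand = character()))
    }
    out$name <- sprintf("%s_read_%d", factor, seq_len(nrow(out)))
    out$score <- 0
    out$strand <- "."
    out
  })
}

#' Simulate imperfect peak-caller outputs
#'
#' Each caller independently reports each true bound site with probability
#' `caller_sensitivity` as `center +/- caller_halfwidth` with Normal boundary
#' jitter, and adds Poisson(`caller_fp_rate` x genome Mb) spurious peaks at
#' random positions. Deterministic per (seed, caller index).
#'
#' @param truth Truth tibble.
#' @param config A `sim_config`.
#' @param genome Genome index tibble.
#' @param factor `"A"` or `"B"`.
#' @param n_callers Number of callers (default 3).
#' @return List of `n_callers` peak interval tibbles.
#' @export
simulate_caller_outputs <- function(truth, config, genome,
                                    factor = c("A", "B"), n_callers = 3) {
  factor <- match.arg(factor)
  base <- if (factor == "A") 10 else 20
  mu <- if (factor == "A") "enrich_a" else "enrich_b"
  bound <- truth[truth[[mu]] > 0, , drop = FALSE]
  sizes <- chrom_sizes_lookup(genome)
  genome_mb <- sum(genome$size) / 1e6
  hw <- config$caller_halfwidth

  lapply(seq_len(n_callers), function(caller) {
    with_stage_seed(config, base + caller, {
      det <- runif(nrow(bound)) < config$caller_sensitivity
      d <- bound[det, , drop = FALSE]
      s <- d$center - hw + rnorm(nrow(d), 0, config$caller_jitter_sd)
      e <- d$center + hw + rnorm(nrow(d), 0, config$caller_jitter_sd)
      # keep a sane minimum width under extreme jitter
      e <- pmax(e, s + 50)
      peaks <- tibble(chrom = d$chrom, start = s, end = e)
      n_fp <- rpois(1, config$caller_fp_rate * genome_mb)
      if (n_fp > 0) {
        fp_chrom <- sample(genome$chrom, n_fp, replace = TRUE,
                           prob = genome$size)
        fp_center <- runif(n_fp, hw, sizes[fp_chrom] - hw)
        peaks <- bind_rows(peaks, tibble(chrom = fp_chrom,
                                         start = fp_center - hw,
                                         end = fp_center + hw))
      }
      peaks$start <- as.integer(pmax(0, floor(peaks$start)))
      peaks$end <- as.integer(pmin(sizes[peaks$chrom], ceiling(peaks$end)))
      peaks$name <- sprintf("%s_caller%d_peak%d", factor, caller,
                            seq_len(nrow(peaks)))
      peaks$score <- 0
      peaks$strand <- "."
      arrange(peaks, .data$chrom, .data$start)
    })
  })
}

#' Simulate a gene annotation
#'
#' Non-overlapping genes of uniform random length (2--10 kb) with random
#' strand, uniformly placed.
#'
#' @param config A `sim_config`.
#' @param genome Genome index tibble.
#' @return Gene interval tibble (BED6 columns) with a `tss` column.
#' @export
simulate_gene_annotation <- function(config, genome) {
  n <- config$n_genes
  if (n == 0L) {
    return(as_gene_models(tibble(chrom = character(), start = integer(),
                                 end = integer(), name = character(),
                                 score = numeric(), strand = character())))
  }
  if (n * 10000 > sum(genome$size)) abort("genome too small for requested genes")
  alloc <- round(genome$size / sum(genome$size) * n)
  alloc[length(alloc)] <- n - sum(alloc[-length(alloc)])
  with_stage_seed(config, 5, {
    pieces <- lapply(seq_len(nrow(genome)), function(ci) {
      n_c <- alloc[ci]
      if (n_c <= 0) return(NULL)
      L <- genome$size[ci]
      gap <- 11000
      slack <- L - n_c * gap
      if (slack <= 0) abort("genome too small for requested genes")
      starts <- as.integer(floor(sort(runif(n_c, 0, slack)) +
                                   gap * (seq_len(n_c) - 1)))
      len <- as.integer(floor(runif(n_c, 2000, 10000)))
      tibble(chrom = genome$chrom[ci], start = starts, end = starts + len,
             strand = sample(c("+", "-"), n_c, replace = TRUE))
    })
    genes <- bind_rows(pieces)
    genes$name <- sprintf("gene_%d", seq_len(nrow(genes)))
    genes$score <- 0
    as_gene_models(genes[, c("chrom", "start", "end", "name", "score",
                             "strand")])
  })
}

#' Generate a complete synthetic dataset
#'
#' @param config A `sim_config`.
#' @return List of class `sim_dataset`: `config`, `genome`, `sequences`,
#'   `truth`, `reads` (tibbles `A`, `B`, `IgG`), `callers` (lists `A`, `B`),
#'   `genes`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  g <- simulate_genome(config)
  land <- simulate_binding_landscape(config, g$genome, g$sequences)
  structure(list(
    config = config,
    genome = g$genome,
    sequences = land$sequences,
    truth = land$truth,
    reads = list(
      A = simulate_coverage(land$truth, config, g$genome, "A"),
      B = simulate_coverage(land$truth, config, g$genome, "B"),
      IgG = simulate_coverage(land$truth, config, g$genome, "IgG")
    ),
    callers = list(
      A = simulate_caller_outputs(land$truth, config, g$genome, "A"),
      B = simulate_caller_outputs(land$truth, config, g$genome, "B")
    ),
    genes = simulate_gene_annotation(config, g$genome)
  ), class = "sim_dataset")
}

#' Write a synthetic dataset to a directory
#'
#' Emits chrom.sizes, FASTA (when sequence was generated), per-factor and IgG
#' read BEDs, caller BEDs, gene BED6, the truth table (TSV) and a config echo.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(sim$genome, file.path(dir, "genome.chrom.sizes"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(sim$sequences)) {
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(sim$sequences),
      file.path(dir, "genome.fa"), width = 70)
  }
  for (f in names(sim$reads)) {
    write_bed(sim$reads[[f]], file.path(dir, sprintf("reads_%s.bed", f)))
  }
  for (f in names(sim$callers)) {
    for (i in seq_along(sim$callers[[f]])) {
      write_bed(sim$callers[[f]][[i]],
                file.path(dir, sprintf("caller_%s_%d.bed", f, i)))
    }
  }
  write_bed(sim$genes[, c("chrom", "start", "end", "name", "score", "strand")],
            file.path(dir, "genes.bed"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$class_fractions <- paste(sprintf("%s=%g", names(cfg$class_fractions),
                                       cfg$class_fractions), collapse = ",")
  cfg$motif_prob <- paste(sprintf("%s=%g", names(cfg$motif_prob),
                                  cfg$motif_prob), collapse = ",")
  writeLines(sprintf("%s = %s", names(cfg), unlist(lapply(cfg, format))),
             file.path(dir, "sim_config.txt"))
  invisible(dir)
}

#' Read a truth table written by [write_sim_dataset()]
#'
#' @param path Path to `truth.tsv`.
#' @return Truth tibble (lossless round trip).
#' @export
read_truth <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  as_tibble(df) %>%
    mutate(site_id = as.character(.data$site_id),
           center = as.integer(.data$center),
           motif = as.logical(.data$motif),
           motif_spacer = as.integer(.data$motif_spacer))
}
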