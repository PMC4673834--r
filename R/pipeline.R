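# End-to-end pipeline: simulate (or load) -> coverage -> consensus per factor
# -> co-binding classification -> motif proportions per class -> nearest-TSS
# annotation, with a resolved-config echo and a checksummed run manifest.

#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: read extension 200 bp;
#' consensus support >= 2 and length >= 150 bp; site filters read count >= 10,
#' fold change >= 2, q <= 0.01; pairing distance 250 bp; profile window
#' +/- 500 bp in 25-bp sub-windows; K-means K = 3; composite motif
#' CTGN(6-8)WGATAR in 200-bp sequences with < 150 masked bp; nearest gene
#' within 1 Mb; proximal < 5 kb.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # input mode: simulate = TRUE generates data; otherwise file paths below
    simulate = TRUE,
    chrom_sizes = "", fasta = "",
    reads_a = "", reads_b = "", reads_igg = "",
    callers_a = "", callers_b = "",   # comma-separated BED paths
    genes = "",
    reads_extended = TRUE,
    # simulation block (used when simulate = TRUE)
    seed = 1, n_chromosomes = 2, chrom_length = 500000, n_sites = 200,
    frac_shared = 0.6, frac_a_only = 0.2, frac_b_only = 0.2,
    enrichment = 30, background_rate = 1, nb_dispersion = 0.2,
    repeat_fraction = 0.1, caller_sensitivity = 0.9, caller_fp_rate = 2,
    caller_jitter_sd = 30, n_genes = 30, with_sequence = TRUE,
    # stage parameters
    extension = 200, min_support = 2, min_length = 150, bin_size = 1000,
    min_reads = 10, min_fc = 2, max_q = 0.01,
    pairing_distance = 250, half_window = 500, subwindow = 25,
    k = 3, n_init = 10, zscore_mode = "row",
    motif = "CTGN(6-8)WGATAR", motif_width = 200, max_masked = 150,
    max_gene_distance = 1e6, proximal_distance = 5000
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown pipeline parameter: %s", unknown[1]))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key = value pipeline config file
#'
#' Unset keys take the defaults of [pipeline_config()]; values are coerced to
#' the default's type. Lines starting with `#` are comments.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  defaults <- pipeline_config()
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  over <- list()
  for (i in seq_along(lines)) {
    kv <- regmatches(lines[i], regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.*)$",
                                       lines[i]))[[1]]
    if (length(kv) != 3L) abort(sprintf("config line not key = value: '%s'",
                                        lines[i]))
    key <- kv[2]; val <- trimws(kv[3])
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown pipeline parameter '%s'", key))
    }
    proto <- defaults[[key]]
    over[[key]] <- if (is.logical(proto)) as.logical(val)
    else if (is.numeric(proto)) as.numeric(val)
    else val
  }
  do.call(pipeline_config, over)
}

#' Write a resolved pipeline config
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, scientific = FALSE),
                            character(1))),
             path)
  invisible(path)
}

validate_pipeline_config <- function(config) {
  num_pos <- c("extension", "min_support", "min_length", "bin_size",
               "min_reads", "half_window", "subwindow", "k", "n_init",
               "motif_width", "max_masked", "max_gene_distance",
               "proximal_distance")
  for (p in num_pos) {
    if (!is.numeric(config[[p]]) || config[[p]] <= 0) {
      abort(sprintf("pipeline parameter '%s' must be positive (got %s)",
                    p, format(config[[p]])))
    }
  }
  if (config$min_fc < 0 || config$max_q < 0 || config$max_q > 1) {
    abort("invalid filter thresholds")
  }
  if (config$pairing_distance < 0) abort("'pairing_distance' must be >= 0")
  if (config$half_window %% config$subwindow != 0) {
    abort("'half_window' must be divisible by 'subwindow'")
  }
  fr <- c(config$frac_shared, config$frac_a_only, config$frac_b_only)
  if (config$simulate && (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)) {
    abort("class fractions must be non-negative and sum to 1")
  }
  parse_motif_pattern(config$motif)
  invisible(config)
}

sim_config_from_pipeline <- function(config) {
  sim_config(
    seed = config$seed, n_chromosomes = config$n_chromosomes,
    chrom_length = config$chrom_length, n_sites = config$n_sites,
    class_fractions = c(shared = config$frac_shared,
                        a_only = config$frac_a_only,
                        b_only = config$frac_b_only),
    enrichment = config$enrichment, background_rate = config$background_rate,
    nb_dispersion = config$nb_dispersion,
    repeat_fraction = config$repeat_fraction,
    caller_sensitivity = config$caller_sensitivity,
    caller_fp_rate = config$caller_fp_rate,
    caller_jitter_sd = config$caller_jitter_sd,
    n_genes = config$n_genes, read_length = config$extension,
    with_sequence = config$with_sequence
  )
}

load_pipeline_inputs <- function(config, out_dir) {
  if (isTRUE(config$simulate)) {
    sim <- simulate_dataset(sim_config_from_pipeline(config))
    sim_dir <- file.path(out_dir, "simulated_inputs")
    write_sim_dataset(sim, sim_dir)
    list(genome = sim$genome,
         sequences = sim$sequences,
         fasta = if (!is.null(sim$sequences)) file.path(sim_dir, "genome.fa"),
         reads = sim$reads, callers = sim$callers, genes = sim$genes,
         truth = sim$truth, sim_dir = sim_dir)
  } else {
    genome <- read_chrom_sizes(config$chrom_sizes)
    split_paths <- function(s) trimws(strsplit(s, ",")[[1]])
    read_reads <- function(path) {
      reads <- read_bed(path, genome)
      if (!config$reads_extended) {
        reads <- extend_reads(reads, genome, config$extension)
      }
      reads
    }
    list(
      genome = genome,
      sequences = NULL,
      fasta = if (nzchar(config$fasta)) config$fasta,
      reads = list(A = read_reads(config$reads_a),
                   B = read_reads(config$reads_b),
                   IgG = read_reads(config$reads_igg)),
      callers = list(
        A = lapply(split_paths(config$callers_a), read_bed, genome = genome),
        B = lapply(split_paths(config$callers_b), read_bed, genome = genome)),
      genes = if (nzchar(config$genes)) read_gene_bed(config$genes, genome),
      truth = NULL, sim_dir = NULL
    )
  }
}

write_sites_bed <- function(sites, path) {
  out <- tibble(
    chrom = sites$chrom, start = sites$start, end = sites$end,
    name = sites$name,
    score = round(-10 * log10(pmax(sites$q_value, 1e-300)), 2),
    strand = ".",
    read_count = sites$read_count, control_count = sites$control_count,
    fold_change = signif(sites$fold_change, 6),
    p = signif(sites$p_value, 6), q = signif(sites$q_value, 6)
  )
  write_bed(out, path)
}

#' Run the full pipeline
#'
#' Executes all stages in order (simulate or load inputs, consensus binding
#' sites per factor, co-binding classification, per-class motif proportions,
#' nearest-TSS annotation), writes every stage output plus a resolved config
#' and a checksummed manifest into `out_dir`, and logs record counts along
#' the candidate -> scored -> passing funnel.
#'
#' @param config A `pipeline_config` (or path to a config file).
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the main in-memory results (`sites_a`,
#'   `sites_b`, `cobinding`, `motif_summary`, `annotation`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(
    tool = "cobindseq",
    version = as.character(utils::packageVersion("cobindseq")),
    seed = config$seed,
    stages = list()
  )
  outputs <- character(0)
  add_stage <- function(name, counts, files) {
    manifest$stages[[name]] <<- list(
      counts = counts,
      outputs = lapply(setNames(files, basename(files)),
                       function(f) unname(tools::md5sum(f)))
    )
    outputs <<- c(outputs, files)
  }

  cfg_path <- file.path(out_dir, "resolved_config.txt")
  write_pipeline_config(config, cfg_path)

  say("stage inputs: %s", if (config$simulate) "simulating dataset" else
    "loading user inputs")
  inputs <- load_pipeline_inputs(config, out_dir)
  add_stage("inputs",
            list(n_reads_a = nrow(inputs$reads$A),
                 n_reads_b = nrow(inputs$reads$B),
                 n_reads_igg = nrow(inputs$reads$IgG),
                 n_genes = if (is.null(inputs$genes)) 0L else
                   nrow(inputs$genes)),
            cfg_path)

  # consensus binding sites per factor
  res <- list()
  for (f in c("A", "B")) {
    say("stage consensus (%s)", f)
    r <- consensus_binding_sites(
      inputs$callers[[f]], inputs$reads[[f]], inputs$reads$IgG,
      inputs$genome, min_support = config$min_support,
      min_length = config$min_length, bin_size = config$bin_size,
      min_reads = config$min_reads, min_fc = config$min_fc,
      max_q = config$max_q, factor_name = f)
    res[[f]] <- r
    sites_path <- file.path(out_dir, sprintf("sites_%s.bed", f))
    cand_path <- file.path(out_dir, sprintf("candidates_%s.bed", f))
    write_sites_bed(r$sites, sites_path)
    write_sites_bed(r$candidates, cand_path)
    say("  %s: %d candidates -> %d passing sites", f,
        nrow(r$candidates), nrow(r$sites))
    add_stage(paste0("consensus_", f),
              list(n_candidates = nrow(r$candidates),
                   n_sites = nrow(r$sites)),
              c(sites_path, cand_path))
  }

  # co-binding classification
  say("stage cobinding")
  cov <- lapply(inputs$reads, coverage_from_intervals, genome = inputs$genome)
  sub_a <- subtract_control(cov$A, cov$IgG, res$A$background)
  sub_b <- subtract_control(cov$B, cov$IgG, res$B$background)
  cb <- classify_cobinding(
    res$A$sites, res$B$sites, sub_a, sub_b,
    pairing_distance = config$pairing_distance,
    half_window = config$half_window, subwindow = config$subwindow,
    k = config$k, seed = config$seed, n_init = config$n_init,
    zscore_mode = config$zscore_mode)
  combined_path <- file.path(out_dir, "combined_sites.tsv")
  write.table(cb$sites, combined_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  z_path <- file.path(out_dir, "zscore_matrix.tsv")
  write.table(round(unclass(cb$z), 6), z_path, sep = "\t", quote = FALSE,
              col.names = NA)
  say("  %d combined sites; cluster labels: %s", nrow(cb$sites),
      paste(cb$clusters$labels, collapse = "/"))
  add_stage("cobinding",
            list(n_combined = nrow(cb$sites),
                 n_paired = sum(cb$sites$source == "paired")),
            c(combined_path, z_path))

  # motif proportions per co-binding class
  motif_summary <- NULL
  if (!is.null(inputs$fasta) || !is.null(inputs$sequences)) {
    say("stage motif")
    pattern <- parse_motif_pattern(config$motif)
    fasta <- if (!is.null(inputs$sequences)) inputs$sequences else inputs$fasta
    cb$sites$site_id <- sprintf("combined_%d", seq_len(nrow(cb$sites)))
    seqs <- fetch_site_sequences(cb$sites, fasta, width = config$motif_width)
    seqs$label <- cb$sites$label
    kept <- filter_repeat_masked(seqs, config$max_masked)
    motif_summary <- bind_rows(lapply(split(kept, kept$label), function(s) {
      prop <- motif_site_proportion(s, pattern)
      tibble(label = s$label[1], prop)
    }))
    motif_path <- file.path(out_dir, "motif_summary.tsv")
    write.table(motif_summary, motif_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    add_stage("motif",
              list(n_sites_scanned = nrow(kept),
                   n_sites_masked_out = nrow(seqs) - nrow(kept)),
              motif_path)
  }

  # nearest-TSS annotation of combined sites
  annotation <- NULL
  if (!is.null(inputs$genes) && nrow(inputs$genes) > 0) {
    say("stage annotate")
    annotation <- assign_nearest_gene(
      cb$sites, inputs$genes, max_distance = config$max_gene_distance,
      proximal_distance = config$proximal_distance)
    ann_path <- file.path(out_dir, "gene_assignment.tsv")
    write.table(annotation, ann_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    summ <- tss_distance_summary(annotation)
    summ_path <- file.path(out_dir, "tss_summary.tsv")
    write.table(summ, summ_path, sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("annotate",
              list(n_assigned = sum(!is.na(annotation$gene)),
                   n_proximal = summ$n_proximal, n_distal = summ$n_distal),
              c(ann_path, summ_path))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: %d output files, manifest at %s", length(outputs), manifest_path)
  invisible(list(config = config, inputs = inputs,
                 sites_a = res$A$sites, sites_b = res$B$sites,
                 background = list(A = res$A$background, B = res$B$background),
                 cobinding = cb, motif_summary = motif_summary,
                 annotation = annotation, manifest = manifest))
}
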