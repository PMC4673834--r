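# Nearest-TSS gene assignment and proximal/distal classification.
#
# Sites are assigned to the single nearest gene by |site center - TSS| within
# a maximum distance (default 1 Mb); sites closer than 5 kb to their TSS are
# proximal, assigned sites at >= 5 kb are distal, the rest unassigned.

#' Read a BED6 gene annotation
#'
#' Derives each gene's TSS from its strand (start for `+`, `end - 1` for
#' `-`; strand `"."` is rejected) and returns genes sorted by chromosome
#' and TSS.
#'
#' @param path Path to a BED6 file.
#' @param genome Optional genome index tibble for validation.
#' @return Tibble of gene models: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `tss`.
#' @export
read_gene_bed <- function(path, genome = NULL) {
  genes <- read_bed(path, genome)
  as_gene_models(genes)
}

#' Derive TSS positions for a gene interval table
#'
#' @param genes Interval tibble with a `+`/`-` `strand` column.
#' @return `genes` with a `tss` column, sorted by (`chrom`, `tss`).
#' @export
as_gene_models <- function(genes) {
  if (!all(genes$strand %in% c("+", "-"))) {
    bad <- which(!(genes$strand %in% c("+", "-")))[1]
    abort(sprintf("gene %d: strand '%s' leaves the TSS undefined",
                  bad, genes$strand[bad]))
  }
  genes$tss <- as.integer(ifelse(genes$strand == "+", genes$start,
                                 genes$end - 1L))
  arrange(genes, .data$chrom, .data$tss)
}

#' Assign each site to its single nearest TSS within a distance cap
#'
#' Distance is signed (`site center - TSS`); the gene minimizing |distance|
#' on the same chromosome wins if within `max_distance`, with ties broken by
#' the smaller TSS coordinate and then lexicographic gene id. Sites with no
#' gene in range are `unassigned`.
#'
#' @param sites Tibble with `chrom` and `center` (or `start`/`end`) columns.
#' @param genes Gene-model tibble from [read_gene_bed()] / [as_gene_models()].
#' @param max_distance Assignment cap in bp (default 1e6).
#' @param proximal_distance Proximal threshold in bp: |distance| strictly
#'   below it is `proximal` (default 5000).
#' @return Tibble: `site_id`, `chrom`, `center`, `gene`, `distance`, `class`.
#' @export
assign_nearest_gene <- function(sites, genes, max_distance = 1e6,
                                proximal_distance = 5000) {
  centers <- if ("center" %in% names(sites)) sites$center else
    interval_centers(sites)
  ids <- if ("site_id" %in% names(sites)) sites$site_id
  else if ("name" %in% names(sites)) sites$name
  else sprintf("site_%d", seq_len(nrow(sites)))

  gene <- rep(NA_character_, nrow(sites))
  distance <- rep(NA_real_, nrow(sites))

  for (chrom in unique(sites$chrom)) {
    si <- which(sites$chrom == chrom)
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0L) next
    # one candidate per distinct TSS; the first gene id at that TSS wins ties
    g <- g[order(g$tss, g$name), , drop = FALSE]
    first <- !duplicated(g$tss)
    tss <- g$tss[first]
    gid <- g$name[first]
    idx <- findInterval(centers[si], tss)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(tss))
    d_left <- abs(centers[si] - tss[left])
    d_right <- abs(centers[si] - tss[right])
    no_left <- idx < 1L
    d_left[no_left] <- Inf
    # equidistant candidates resolve to the smaller TSS, i.e. the left one
    use_left <- d_left <= d_right
    pick <- ifelse(use_left, left, right)
    d <- centers[si] - tss[pick]
    ok <- abs(d) <= max_distance
    gene[si[ok]] <- gid[pick[ok]]
    distance[si[ok]] <- d[ok]
  }

  tibble(
    site_id = ids, chrom = sites$chrom, center = as.integer(centers),
    gene = gene, distance = distance,
    class = ifelse(is.na(gene), "unassigned",
                   ifelse(abs(distance) < proximal_distance,
                          "proximal", "distal"))
  )
}

#' Summarize TSS-distance classes
#'
#' @param assignments Tibble from [assign_nearest_gene()].
#' @return One-row tibble with counts and fractions of proximal, distal and
#'   unassigned sites (fractions sum to 1).
#' @export
tss_distance_summary <- function(assignments) {
  if (nrow(assignments) == 0L) abort("no assignments supplied")
  n <- nrow(assignments)
  n_prox <- sum(assignments$class == "proximal")
  n_dist <- sum(assignments$class == "distal")
  n_un <- n - n_prox - n_dist
  tibble(n = n, n_proximal = n_prox, n_distal = n_dist, n_unassigned = n_un,
         proximal = n_prox / n, distal = n_dist / n, unassigned = n_un / n)
}

#' Gene lists per TSS-distance class
#'
#' @param assignments Tibble from [assign_nearest_gene()].
#' @return Named list of unique gene ids for `proximal` and `distal` sites.
#' @export
gene_lists_by_class <- function(assignments) {
  lapply(split(assignments$gene, assignments$class), function(g) {
    sort(unique(g[!is.na(g)]))
  })
}
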