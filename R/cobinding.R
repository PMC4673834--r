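# Two-factor co-binding classification.
#
# Binding-site sets of two factors are merged (sites whose centers lie within
# a pairing distance become one combined site), control-subtracted coverage in
# +/- half_window around each combined center is averaged in fixed sub-windows
# for both factor tracks, each row x track segment is z-scored, and the z-score
# matrix is partitioned by K-means (K = 3) into factor-A-only, factor-B-only
# and shared classes.

interval_centers <- function(x) as.integer((x$start + x$end) %/% 2)

#' Merge two factors' binding sites into combined sites
#'
#' Sites of factor A and factor B whose centers lie within `pairing_distance`
#' of each other are emitted once as `paired` (center = midpoint of the two
#' centers); unpaired sites are emitted as `A_only` / `B_only`. Multi-overlaps
#' are resolved by greedy nearest-center matching, so each original site
#' appears in exactly one combined site.
#'
#' @param sites_a,sites_b Binding-site interval tibbles for factor A and B.
#' @param pairing_distance Maximum center-to-center distance for pairing
#'   (default 250 bp).
#' @return Tibble with columns `chrom`, `center`, `source` (one of `A_only`,
#'   `B_only`, `paired`), `site_a`, `site_b` (originating site names,
#'   `NA` where absent).
#' @export
merge_factor_sites <- function(sites_a, sites_b, pairing_distance = 250) {
  name_of <- function(x, prefix) {
    if ("name" %in% names(x) && !anyDuplicated(x$name)) x$name
    else sprintf("%s_%d", prefix, seq_len(nrow(x)))
  }
  a <- tibble(chrom = sites_a$chrom, center = interval_centers(sites_a),
              id = name_of(sites_a, "A"))
  b <- tibble(chrom = sites_b$chrom, center = interval_centers(sites_b),
              id = name_of(sites_b, "B"))

  paired_a <- rep(NA_integer_, nrow(a))
  paired_b <- rep(NA_integer_, nrow(b))
  for (chrom in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == chrom)
    bi <- which(b$chrom == chrom)
    # candidate pairs within pairing distance, greedily matched nearest-first
    cand <- do.call(rbind, lapply(ai, function(i) {
      d <- abs(b$center[bi] - a$center[i])
      hit <- which(d <= pairing_distance)
      if (!length(hit)) return(NULL)
      cbind(i, bi[hit], d[hit])
    }))
    if (is.null(cand)) next
    cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (is.na(paired_a[i]) && is.na(paired_b[j])) {
        paired_a[i] <- j
        paired_b[j] <- i
      }
    }
  }

  ip <- which(!is.na(paired_a))
  combined <- bind_rows(
    if (length(ip)) tibble(
      chrom = a$chrom[ip],
      center = as.integer((a$center[ip] + b$center[paired_a[ip]]) %/% 2),
      source = "paired", site_a = a$id[ip], site_b = b$id[paired_a[ip]]),
    tibble(chrom = a$chrom[is.na(paired_a)],
           center = a$center[is.na(paired_a)],
           source = "A_only", site_a = a$id[is.na(paired_a)],
           site_b = NA_character_),
    tibble(chrom = b$chrom[is.na(paired_b)],
           center = b$center[is.na(paired_b)],
           source = "B_only", site_a = NA_character_,
           site_b = b$id[is.na(paired_b)])
  )
  arrange(combined, .data$chrom, .data$center)
}

#' Build the two-track co-binding profile matrix
#'
#' For each combined site, averages subtracted coverage of both factor tracks
#' in consecutive sub-windows across `center - half_window` to
#' `center + half_window`. Windows reaching past chromosome ends are
#' zero-padded.
#'
#' @param sites Combined-site tibble (columns `chrom`, `center`).
#' @param track_a,track_b Control-subtracted `coverage_track`s.
#' @param half_window Half window span in bp (default 500).
#' @param subwindow Sub-window width in bp (default 25); must divide
#'   `half_window`.
#' @return A numeric matrix of class `profile_matrix`, one row per site,
#'   `2 * (2 * half_window / subwindow)` columns named
#'   `trackA_w01 ... trackB_w40` (defaults).
#' @export
profile_matrix <- function(sites, track_a, track_b, half_window = 500,
                           subwindow = 25) {
  if (half_window %% subwindow != 0) {
    abort("`half_window` must be divisible by `subwindow`")
  }
  check_same_genome(track_a, track_b)
  nw <- as.integer(2 * half_window / subwindow)
  span <- 2L * as.integer(half_window)

  window_means <- function(track, chrom, center) {
    v <- track[[chrom]]
    lo <- center - half_window      # 0-based start of window
    idx <- (lo + 1L):(lo + span)    # 1-based positions, may exceed bounds
    vals <- numeric(span)
    ok <- idx >= 1L & idx <= length(v)
    vals[ok] <- v[idx[ok]]
    .colMeans(vals, subwindow, nw)
  }

  m <- matrix(0, nrow = nrow(sites), ncol = 2L * nw)
  for (i in seq_len(nrow(sites))) {
    m[i, seq_len(nw)] <- window_means(track_a, sites$chrom[i], sites$center[i])
    m[i, nw + seq_len(nw)] <- window_means(track_b, sites$chrom[i],
                                           sites$center[i])
  }
  colnames(m) <- c(sprintf("trackA_w%02d", seq_len(nw)),
                   sprintf("trackB_w%02d", seq_len(nw)))
  rownames(m) <- if ("site_id" %in% names(sites)) sites$site_id else
    sprintf("site_%d", seq_len(nrow(sites)))
  structure(m, n_subwindows = nw, class = c("profile_matrix", "matrix", "array"))
}

#' Z-score a profile matrix
#'
#' Default (`mode = "row"`): each site's whole two-track row is standardized
#' with the population SD, so clustering reflects profile shape and the
#' relative amplitude of the two tracks within a site, but not absolute ChIP
#' efficiency differences between sites. `mode = "segment"` standardizes each
#' row x factor-track segment independently (pure per-track shape; note this
#' also equalizes a bound and an unbound track's amplitudes, which makes
#' sparse background noise in the unbound track look like signal).
#' `mode = "column"` standardizes each sub-window column across sites.
#' Zero-variance rows/segments/columns become all zeros.
#'
#' @param m A `profile_matrix`.
#' @param mode `"row"` (default), `"segment"` or `"column"`.
#' @return A matrix of class `z_matrix`, same shape and dimnames.
#' @export
zscore_rows <- function(m, mode = c("row", "segment", "column")) {
  mode <- match.arg(mode)
  if (any(!is.finite(m))) abort("profile matrix contains non-finite values")
  nw <- attr(m, "n_subwindows")
  if (is.null(nw)) nw <- ncol(m) %/% 2L
  z <- unclass(m)
  if (mode %in% c("row", "segment")) {
    col_sets <- if (mode == "row") list(seq_len(ncol(z)))
    else list(seq_len(nw), nw + seq_len(nw))
    for (cols in col_sets) {
      x <- z[, cols, drop = FALSE]
      mu <- rowMeans(x)
      sd_pop <- sqrt(pmax(0, rowMeans(x^2) - mu^2))
      zs <- (x - mu) / ifelse(sd_pop > 0, sd_pop, 1)
      zs[sd_pop == 0, ] <- 0
      z[, cols] <- zs
    }
  } else {
    for (j in seq_len(ncol(z))) {
      mu <- mean(z[, j])
      sd_pop <- sqrt(max(0, mean(z[, j]^2) - mu^2))
      z[, j] <- if (sd_pop > 0) (z[, j] - mu) / sd_pop else 0
    }
  }
  structure(z, n_subwindows = nw, zscore_mode = mode,
            class = c("z_matrix", "matrix", "array"))
}

# k-means++ seeding: first center uniform, subsequent centers drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, nrow = k, ncol = ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = p)
    centers[j + 1L, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j + 1L, ])^2))
  }
  centers
}

#' K-means clustering of co-binding z-score profiles
#'
#' Lloyd's algorithm with k-means++ initialization; the best of `n_init`
#' restarts by total within-cluster sum of squares is kept. Deterministic
#' given `seed`.
#'
#' @param z A `z_matrix` (or any numeric matrix, rows = sites).
#' @param k Number of clusters (default 3).
#' @param seed Integer seed for the restarts.
#' @param n_init Number of random restarts (default 10).
#' @return An object of class `cobind_clusters`: `cluster` (integer vector),
#'   `centers`, `tot_withinss`, `sizes`, `k`, `seed`, `n_init`.
#' @export
kmeans_cluster <- function(z, k = 3, seed = 1, n_init = 10) {
  x <- unclass(z)
  if (nrow(x) < k) abort(sprintf("need at least k = %d rows, have %d", k,
                                 nrow(x)))
  best <- NULL
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (i in seq_len(n_init)) {
    centers <- kmeanspp_centers(x, k)
    fit <- tryCatch(
      suppressWarnings(kmeans(x, centers = centers, iter.max = 100,
                              algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) abort("k-means failed on all restarts")
  structure(
    list(cluster = as.integer(best$cluster), centers = best$centers,
         tot_withinss = best$tot.withinss,
         sizes = as.integer(best$size), k = as.integer(k),
         seed = seed, n_init = n_init, labels = NULL, ambiguous = FALSE),
    class = "cobind_clusters"
  )
}

#' @export
print.cobind_clusters <- function(x, ...) {
  cat(sprintf("<cobind_clusters> k = %d, n = %d, total within-SS %.1f\n",
              x$k, length(x$cluster), x$tot_withinss))
  if (!is.null(x$labels)) {
    cat("labels:", paste(sprintf("%d=%s", seq_along(x$labels), x$labels),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign semantic labels to the three co-binding clusters
#'
#' Computes each cluster's mean raw (un-z-scored) profile signal per factor
#' track; the cluster with the largest A-to-B log-ratio is `A_only`, the
#' smallest `B_only`, and the remaining cluster `shared`. An ambiguity flag is
#' set when the ranking is degenerate.
#'
#' @param clusters A `cobind_clusters` with `k = 3`.
#' @param profile The raw `profile_matrix` the z-matrix was derived from.
#' @return `clusters` with `labels` (per-cluster), `site_label` (per-site)
#'   and `cluster_signal` (per-cluster mean signal per track) filled in.
#' @export
label_clusters <- function(clusters, profile) {
  if (clusters$k != 3L) abort("semantic labeling requires k = 3")
  nw <- attr(profile, "n_subwindows")
  if (is.null(nw)) nw <- ncol(profile) %/% 2L
  m <- unclass(profile)
  mean_a <- vapply(1:3, function(g) {
    mean(m[clusters$cluster == g, seq_len(nw), drop = FALSE])
  }, numeric(1))
  mean_b <- vapply(1:3, function(g) {
    mean(m[clusters$cluster == g, nw + seq_len(nw), drop = FALSE])
  }, numeric(1))
  eps <- 1e-3
  ratio <- log2((mean_a + eps) / (mean_b + eps))
  labels <- rep("shared", 3L)
  labels[which.max(ratio)] <- "A_only"
  labels[which.min(ratio)] <- "B_only"
  ambiguous <- which.max(ratio) == which.min(ratio) ||
    anyDuplicated(signif(ratio, 12)) > 0
  if (ambiguous) {
    # fall back to a strict ranking so labels stay a bijection
    ord <- order(ratio, decreasing = TRUE)
    labels <- character(3L)
    labels[ord] <- c("A_only", "shared", "B_only")
  }
  clusters$labels <- labels
  clusters$site_label <- labels[clusters$cluster]
  clusters$cluster_signal <- tibble(cluster = 1:3, mean_a = mean_a,
                                    mean_b = mean_b, label = labels)
  clusters$ambiguous <- ambiguous
  clusters
}

#' Classify co-binding patterns for two factors
#'
#' End-to-end wrapper: merge the two binding-site sets, build the subtracted
#' two-track profile matrix around combined centers, z-score per row and
#' track, run K-means (K = 3) and label clusters.
#'
#' @param sites_a,sites_b Binding-site tibbles for factor A and B.
#' @param track_a,track_b Control-subtracted `coverage_track`s.
#' @param pairing_distance,half_window,subwindow,k,seed,n_init,zscore_mode
#'   Stage parameters; see the underlying functions.
#' @return List with `sites` (combined tibble plus `cluster` and `label`
#'   columns), `profile`, `z` and `clusters`.
#' @export
classify_cobinding <- function(sites_a, sites_b, track_a, track_b,
                               pairing_distance = 250, half_window = 500,
                               subwindow = 25, k = 3, seed = 1, n_init = 10,
                               zscore_mode = "row") {
  combined <- merge_factor_sites(sites_a, sites_b, pairing_distance)
  prof <- profile_matrix(combined, track_a, track_b, half_window, subwindow)
  z <- zscore_rows(prof, mode = zscore_mode)
  cl <- kmeans_cluster(z, k = k, seed = seed, n_init = n_init)
  if (k == 3) cl <- label_clusters(cl, prof)
  combined$cluster <- cl$cluster
  combined$label <- if (!is.null(cl$site_label)) cl$site_label else
    as.character(cl$cluster)
  list(sites = combined, profile = prof, z = z, clusters = cl)
}
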