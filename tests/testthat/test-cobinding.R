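# Site merging, profile construction, z-scoring and K-means classification.

test_that("site merging pairs centers within the pairing distance", {
  mk <- function(centers) tibble::tibble(
    chrom = "chr1", start = as.integer(centers - 100),
    end = as.integer(centers + 100))
  # 200 bp apart -> paired at the midpoint
  m <- merge_factor_sites(mk(1000), mk(1200))
  expect_equal(m$source, "paired")
  expect_equal(m$center, 1100)
  # 300 bp apart -> kept separate
  m2 <- merge_factor_sites(mk(1000), mk(1300))
  expect_setequal(m2$source, c("A_only", "B_only"))
  # empty B set
  m3 <- merge_factor_sites(mk(c(1000, 5000)), mk(numeric(0)))
  expect_equal(m3$source, rep("A_only", 2))
})

test_that("site merging conserves sites and resolves multi-overlaps greedily", {
  set.seed(13)
  for (i in 1:10) {
    na <- sample(5:40, 1); nb <- sample(5:40, 1)
    mk <- function(n) {
      c0 <- sort(sample.int(50000, n))
      tibble::tibble(chrom = "chr1", start = as.integer(c0 - 50),
                     end = as.integer(c0 + 50))
    }
    m <- merge_factor_sites(mk(na), mk(nb))
    n_paired <- sum(m$source == "paired")
    expect_equal(sum(m$source == "A_only") + sum(m$source == "B_only") +
                   2 * n_paired, na + nb)
    # each original site appears exactly once
    expect_false(anyDuplicated(stats::na.omit(m$site_a)) > 0)
    expect_false(anyDuplicated(stats::na.omit(m$site_b)) > 0)
  }
})

test_that("control subtraction scales, clamps and handles zero control", {
  g <- genome_index("chr1", 1000)
  iv <- function(s, e) tibble::tibble(chrom = "chr1", start = s, end = e)
  sample_cov <- coverage_from_intervals(iv(0L, 500L), g)
  control_cov <- coverage_from_intervals(iv(c(0L, 0L), c(500L, 500L)), g)
  # sample = 0.5 x control everywhere -> exact cancellation
  out <- subtract_control(sample_cov, control_cov, scale = 0.5)
  expect_true(all(out$chr1 == 0))
  # zero control -> identity
  zero <- coverage_from_intervals(iv(integer(0), integer(0)), g)
  expect_equal(subtract_control(sample_cov, zero, scale = 1)$chr1,
               sample_cov$chr1)
  # clamp contract
  out2 <- subtract_control(sample_cov, control_cov, scale = 2)
  expect_true(all(out2$chr1 >= 0))
  out3 <- subtract_control(sample_cov, control_cov, scale = 2, clamp = FALSE)
  expect_true(any(out3$chr1 < 0))
})

test_that("profile matrix averages sub-windows and zero-pads boundaries", {
  g <- genome_index("chr1", 10000)
  flat <- lapply(chrom_sizes <- c(chr1 = 10000), function(L) rep(4, L))
  flat_track <- structure(flat, class = "coverage_track")
  sites <- tibble::tibble(chrom = "chr1", center = 5000L)
  m <- profile_matrix(sites, flat_track, flat_track)
  expect_equal(dim(m), c(1, 80))
  expect_true(all(m == 4))
  expect_equal(colnames(m)[1], "trackA_w01")
  expect_equal(colnames(m)[80], "trackB_w40")

  # site 100 bp from the start: left out-of-range sub-windows are zero
  edge <- profile_matrix(tibble::tibble(chrom = "chr1", center = 100L),
                         flat_track, flat_track)
  expect_true(all(edge[1, 1:16] == 0))   # first 400 bp out of range
  expect_true(all(edge[1, 17:40] == 4))
})

test_that("segment z-scoring standardizes each track segment independently", {
  m <- matrix(0, 2, 6)
  m[1, ] <- c(1, 2, 3, 7, 7, 7)   # track B segment constant
  m[2, ] <- c(5, 5, 5, 1, 3, 5)
  attr(m, "n_subwindows") <- 3L
  class(m) <- c("profile_matrix", "matrix", "array")
  z <- zscore_rows(m, mode = "segment")
  expect_equal(z[1, 1:3], c(-1.224745, 0, 1.224745),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(z[1, 4:6]), c(0, 0, 0))    # zero-variance rule
  # standardization identity on segments with variance
  expect_equal(mean(z[2, 4:6]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z[2, 4:6]^2)), 1, tolerance = 1e-9)
  expect_error(zscore_rows(m * NA), "non-finite")
})

test_that("default row z-scoring standardizes each whole site row", {
  set.seed(6)
  m <- matrix(rexp(240), 12, 20)
  attr(m, "n_subwindows") <- 10L
  z <- zscore_rows(m)
  expect_equal(rowMeans(z), rep(0, 12), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sqrt(rowMeans(z^2)), rep(1, 12), tolerance = 1e-9,
               ignore_attr = TRUE)
  # relative amplitude of the two tracks within a site is preserved
  m2 <- rbind(c(rep(10, 10), rep(0.1, 10)))
  attr(m2, "n_subwindows") <- 10L
  z2 <- zscore_rows(m2)
  expect_true(all(z2[1, 1:10] > 0) && all(z2[1, 11:20] < 0))
  const <- matrix(3, 2, 20)
  attr(const, "n_subwindows") <- 10L
  expect_true(all(zscore_rows(const) == 0))
})

test_that("column z-scoring standardizes across sites", {
  set.seed(2)
  m <- matrix(runif(200), 10, 20)
  attr(m, "n_subwindows") <- 10L
  z <- zscore_rows(m, mode = "column")
  expect_equal(colMeans(z), rep(0, 20), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sqrt(colMeans(z^2)), rep(1, 20), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("k-means recovers well-separated planted classes exactly", {
  skip_if_not_installed("mclust")
  set.seed(31)
  centers <- rbind(c(rep(3, 10), rep(0, 10)),
                   c(rep(0, 10), rep(3, 10)),
                   c(rep(3, 10), rep(3, 10)))
  truth <- sample(1:3, 300, replace = TRUE)
  z <- centers[truth, ] + matrix(rnorm(300 * 20, sd = 0.3), 300)
  cl <- kmeans_cluster(z, k = 3, seed = 4)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1.0)

  one <- kmeans_cluster(z, k = 1, seed = 4)
  expect_equal(unique(one$cluster), 1L)
  expect_error(kmeans_cluster(z[1:2, ], k = 3), "at least k")
})

test_that("k-means is deterministic given the seed", {
  set.seed(99)
  z <- matrix(rnorm(600), 100, 6)
  a <- kmeans_cluster(z, k = 3, seed = 7)
  b <- kmeans_cluster(z, k = 3, seed = 7)
  expect_identical(a$cluster, b$cluster)
  expect_equal(a$tot_withinss, b$tot_withinss)
})

test_that("cluster labeling maps centroid track means to semantic classes", {
  # construct raw profiles: cluster signal on A only / B only / both
  set.seed(17)
  n <- 90
  truth <- rep(1:3, each = 30)
  m <- matrix(0.01, n, 20)
  m[truth == 1, 1:10] <- 5    # A_only
  m[truth == 2, 11:20] <- 5   # B_only
  m[truth == 3, ] <- 5        # shared
  attr(m, "n_subwindows") <- 10L
  cl <- list(cluster = truth, k = 3L)
  class(cl) <- "cobind_clusters"
  lab <- label_clusters(cl, m)
  expect_equal(lab$labels, c("A_only", "B_only", "shared"))
  expect_false(lab$ambiguous)

  # swapping the tracks swaps the A/B labels
  m_swap <- m[, c(11:20, 1:10)]
  attr(m_swap, "n_subwindows") <- 10L
  lab_swap <- label_clusters(cl, m_swap)
  expect_equal(lab_swap$labels, c("B_only", "A_only", "shared"))
})

test_that("classification is symmetric under factor exchange", {
  cfg <- sim_config(seed = 5, n_sites = 200, chrom_length = 500000,
                    n_chromosomes = 1, n_genes = 20)
  sim <- simulate_dataset(cfg)
  cov <- lapply(sim$reads, coverage_from_intervals, genome = sim$genome)
  sub_a <- subtract_control(cov$A, cov$IgG, scale = 1)
  sub_b <- subtract_control(cov$B, cov$IgG, scale = 1)
  sites <- tibble::tibble(chrom = sim$truth$chrom, center = sim$truth$center)
  prof_ab <- profile_matrix(sites, sub_a, sub_b)
  prof_ba <- profile_matrix(sites, sub_b, sub_a)
  cl_ab <- label_clusters(kmeans_cluster(zscore_rows(prof_ab), seed = 3),
                          prof_ab)
  cl_ba <- label_clusters(kmeans_cluster(zscore_rows(prof_ba), seed = 3),
                          prof_ba)
  swap <- c(A_only = "B_only", B_only = "A_only", shared = "shared")
  expect_equal(unname(swap[cl_ab$site_label]), cl_ba$site_label)
})

test_that("tidiers and autoplot expose clustering results", {
  set.seed(8)
  z <- matrix(rnorm(300), 50, 6)
  attr(z, "n_subwindows") <- 3L
  class(z) <- c("z_matrix", "matrix", "array")
  cl <- kmeans_cluster(z, k = 3, seed = 2)
  td <- generics::tidy(cl)
  expect_equal(nrow(td), 50)
  gl <- generics::glance(cl)
  expect_equal(gl$k, 3)
  p <- ggplot2::autoplot(z, clusters = cl)
  expect_s3_class(p, "ggplot")
})
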