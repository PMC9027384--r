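two_blob <- function(n_per = 5, sd = 0.05, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(1 + rnorm(n_per * 3, sd = sd), n_per),
             matrix(-1 + rnorm(n_per * 3, sd = sd), n_per))
  rownames(x) <- sprintf("p%02d", seq_len(2 * n_per))
  x
}

test_that("cop_kmeans recovers the exhaustive minimum-SSE bipartition", {
  for (seed in 1:4) {
    x <- two_blob(seed = seed)
    oracle <- best_bipartition(x)
    a <- cop_kmeans(x, 2, seed = seed)
    expect_true(same_partition(a, oracle$labels))
  }
  # k = 1 puts everything together
  x <- two_blob()
  expect_true(all(cop_kmeans(x, 1) == 1L))
  expect_error(cop_kmeans(x, nrow(x) + 1L), "exceeds")
})

test_that("must-link constraints are always honoured", {
  # a link joining the two blobs forces co-clustering
  x <- two_blob()
  cs <- constraint_set(must_links = rbind(c("p01", "p06")))
  for (seed in 1:5) {
    a <- cop_kmeans(x, 2, cs, seed = seed)
    expect_equal(a[["p01"]], a[["p06"]])
  }
  # random data, random chains, 100 seeded runs, zero violations
  set.seed(99)
  for (run in 1:100) {
    n <- sample(20:40, 1)
    x <- matrix(rnorm(n * 4), n)
    rownames(x) <- sprintf("g%02d", seq_len(n))
    picks <- sample(rownames(x), 6)
    cs <- constraint_set(must_links = cbind(picks[-6], picks[-1]))
    a <- cop_kmeans(x, sample(2:5, 1), cs, seed = run)
    expect_length(unique(a[picks]), 1L)
  }
})

test_that("silhouette matches hand values and the brute-force definition", {
  # 1-D toy from the definition: a(0)=0.1, b(0)=10.05
  x1 <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(silhouette_mean(x1, lab, is_dist = FALSE),
               ((10.05 - 0.1) / 10.05 + (9.95 - 0.1) / 9.95) / 2,
               tolerance = 1e-12)
  expect_equal(silhouette_mean(x1, lab, is_dist = FALSE), 0.99, tolerance = 1e-3)
  # duplicated points, a(i) = 0 convention -> 1
  xdup <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(silhouette_mean(xdup, lab, is_dist = FALSE), 1.0)
  # singleton cluster scores 0
  x3 <- matrix(c(0, 0.1, 9), ncol = 1)
  s3 <- silhouette_mean(x3, c(1, 1, 2), is_dist = FALSE)
  expect_equal(s3, sil_brute(x3, c(1, 1, 2)), tolerance = 1e-12)
  expect_error(silhouette_mean(x1, rep(1, 4), is_dist = FALSE), "single cluster")
  # brute-force agreement on random instances, n up to 300
  set.seed(42)
  for (n in c(40, 120, 300)) {
    x <- matrix(rnorm(n * 3), n)
    lab <- sample(1:4, n, replace = TRUE)
    expect_equal(silhouette_mean(x, lab, is_dist = FALSE), sil_brute(x, lab),
                 tolerance = 1e-12)
  }
  # random labels on structureless data stay near zero
  set.seed(7)
  x <- matrix(rnorm(200 * 3), 200)
  expect_lt(abs(silhouette_mean(x, sample(1:4, 200, TRUE), is_dist = FALSE)), 0.1)
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(13)
  x <- matrix(rnorm(150 * 4), 150)
  lab <- sample(1:5, 150, TRUE)
  ref <- mean(cluster::silhouette(lab, dist(x))[, "sil_width"])
  expect_equal(silhouette_mean(x, lab, is_dist = FALSE), ref, tolerance = 1e-12)
})

test_that("select_k prefers the true blob count and is deterministic", {
  x <- two_blob(n_per = 15, sd = 0.1, seed = 2)
  cfg <- pipeline_config(k_min = 2, k_max = 6, repeats_per_k = 3, seed = 5)
  r1 <- select_k(x, config = cfg)
  expect_equal(r1$k, 2L)
  expect_true(all(r1$silhouette_by_k$mean >= -1 & r1$silhouette_by_k$mean <= 1))
  expect_gt(r1$silhouette_by_k$mean[1], max(r1$silhouette_by_k$mean[-1]))
  r2 <- select_k(x, config = cfg)
  expect_identical(r1$assignments, r2$assignments)
  expect_identical(r1$silhouette_by_k, r2$silhouette_by_k)
})

test_that("zero-noise planted data is a fixed point (ARI = 1 at true k)", {
  skip_if_not_installed("mclust")
  io <- small_inputs(noise_sd = 0, leak = 0)
  deg <- filter_degs(io$x, 1.5)
  expect_setequal(deg$gene_ids, names(io$truth$cluster_of)[io$truth$cluster_of > 0])
  sc <- scale_profiles(io$x, deg)
  sig <- build_signatures(io$net$interactions, rownames(io$x))
  cs <- derive_mustlinks(sig, deg)
  a <- cop_kmeans(sc, io$truth$k_planted, cs, seed = 1)
  tr <- io$truth$cluster_of[names(a)]
  expect_equal(mclust::adjustedRandIndex(a, tr), 1)
})
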