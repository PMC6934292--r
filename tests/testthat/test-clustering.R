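test_that("preprocessing standardizes and winsorizes as documented", {
  withr::with_seed(4, {
    mat <- cbind(M1 = rnorm(2000), M2 = rexp(2000))
  })
  model <- fit_preprocess(mat)
  std <- apply_preprocess(model, mat)
  expect_equal(unname(colMeans(std)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(std, 2, sd)), c(1, 1), tolerance = 1e-10)
  # a 99th-percentile value is clipped to the 97.5th-percentile bound
  v99 <- quantile(mat[, "M2"], 0.99, names = FALSE)
  b975 <- model$upper[model$marker == "M2"]
  row <- cbind(M1 = 0, M2 = v99)
  got <- apply_preprocess(model, row)
  expect_equal(got[, "M2"] * model$sd[2] + model$mean[2], b975,
               ignore_attr = TRUE)
})

test_that("constant markers are flagged and excluded from the matrix", {
  mat <- cbind(M1 = rnorm(100), FLAT = rep(2, 100))
  expect_warning(model <- fit_preprocess(mat), "FLAT")
  std <- apply_preprocess(model, mat)
  expect_equal(colnames(std), "M1")
})

test_that("exclusion variant drops out-of-bound cells instead", {
  withr::with_seed(5, mat <- cbind(M1 = rnorm(1000)))
  model <- fit_preprocess(mat, method = "exclude")
  std <- apply_preprocess(model, mat)
  expect_equal(nrow(std), sum(mat[, 1] >= model$lower & mat[, 1] <= model$upper))
  expect_true(length(attr(std, "kept_rows")) == nrow(std))
})

test_that("silhouette peaks at the true K for separated blobs", {
  blobs <- make_blobs(150, rbind(c(0, 0), c(6, 6)), sd = 0.4)
  scan <- kmeans_scan(blobs$data, k_range = 2:6, seed = 1)
  m <- tidy(scan)
  expect_equal(m$k[which.max(m$silhouette)], 2)
  # SSE non-increasing in K
  expect_true(all(diff(m$sse) <= 1e-8))
  # determinism under the seed
  scan2 <- kmeans_scan(blobs$data, k_range = 2:6, seed = 1)
  expect_identical(scan$models[["3"]]$cluster, scan2$models[["3"]]$cluster)
  expect_error(kmeans_scan(blobs$data[1:4, ], k_range = 2:6), "exceeds")
})

test_that("consensus is binary for perfectly separated blobs", {
  blobs <- make_blobs(60, rbind(c(0, 0), c(8, 0), c(0, 8)), sd = 0.3)
  cons <- consensus_cluster(blobs$data, k_range = 3, n_iterations = 40,
                            n_starts = 5, seed = 2)
  cm <- cons$results[["3"]]$consensus
  expect_true(isSymmetric(unname(cm)))
  expect_true(all(diag(cm)[!is.na(diag(cm))] == 1))
  vals <- cm[upper.tri(cm)]
  vals <- vals[!is.na(vals)]
  expect_true(all(vals %in% c(0, 1)))
  # within-blob pairs 1, between-blob pairs 0
  same <- outer(blobs$labels, blobs$labels, "==")[upper.tri(cm)]
  expect_true(all(cm[upper.tri(cm)][same] %in% c(1, NA)))
  expect_true(all(cm[upper.tri(cm)][!same] %in% c(0, NA)))
  expect_error(
    consensus_cluster(blobs$data, 3, resample_fraction = 1.2),
    "resample_fraction"
  )
})

test_that("consensus results are stable across seeds on separated data", {
  blobs <- make_blobs(150, rbind(c(0, 0), c(8, 0), c(0, 8)), sd = 0.3)
  pac <- vapply(c(11, 22), function(s) {
    cons <- consensus_cluster(blobs$data, k_range = 3, subsample_cells = 300,
                              n_iterations = 50, n_starts = 5, seed = s)
    consensus_summary(cons)$pac
  }, numeric(1))
  expect_equal(pac[1], pac[2], tolerance = 0.05)
  expect_lt(max(pac), 0.05)
})

test_that("all criteria agree on a clean K=4 mixture", {
  blobs <- make_blobs(100, rbind(c(0, 0), c(7, 0), c(0, 7), c(7, 7)),
                      sd = 0.35)
  scan <- kmeans_scan(blobs$data, k_range = 2:6, seed = 3)
  cons <- consensus_cluster(blobs$data, k_range = 2:6, n_iterations = 40,
                            n_starts = 5, seed = 3)
  choice <- choose_k(scan, cons)
  expect_equal(choice$chosen_k, 4)
  expect_equal(tidy(scan)$k[which.max(tidy(scan)$silhouette)], 4)
  expect_length(choice$flags, 0)
})

test_that("single-blob data is flagged unreliable", {
  blob <- make_blobs(250, rbind(c(0, 0)), sd = 1)
  scan <- kmeans_scan(blob$data, k_range = 2:5, seed = 4)
  choice <- choose_k(scan)
  expect_true(any(grepl("unreliable", choice$flags)))
})

test_that("cluster profiles recover planted mean shifts and conserve mass", {
  blobs <- make_blobs(200, rbind(c(-2, 0), c(2, 0)), sd = 0.3, seed = 6)
  colnames(blobs$data) <- c("M1", "M2")
  scan <- kmeans_scan(blobs$data, k_range = 2, seed = 5)
  prof <- cluster_profiles(scan$models[["2"]], blobs$data)
  expect_equal(sum(prof$pct_cells) / 2, 100)  # two markers per cluster row set
  # size-weighted deviations sum to zero per marker
  sums <- prof |>
    dplyr::group_by(marker) |>
    dplyr::summarise(s = sum(deviation * pct_cells / 100))
  expect_equal(sums$s, c(0, 0), tolerance = 1e-10)
  # planted shift on M1 is +/- 2 around the population mean
  m1 <- prof[prof$marker == "M1", ]
  expect_equal(sort(unname(m1$deviation)), c(-2, 2), tolerance = 0.1)
  # K = 1: all deviations zero, 100% of cells
  prof1 <- cluster_profiles(rep(1L, nrow(blobs$data)), blobs$data)
  expect_equal(unname(prof1$deviation), c(0, 0))
  expect_equal(unique(prof1$pct_cells), 100)
})

test_that("sample compositions are proper per-sample fractions", {
  assign <- c(1L, 1L, 2L, 2L, 2L, 3L)
  samples <- c("s1", "s1", "s1", "s2", "s2", "s2")
  comp <- sample_composition(assign, samples)
  sums <- tapply(comp$fraction, comp$sample_id, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  # a sample entirely in one cluster is an indicator vector
  one <- sample_composition(rep(2L, 4), rep("s", 4))
  expect_equal(one$fraction, 1)
  expect_equal(one$cluster, 2L)
})

test_that("planted phenotypes are recovered end to end", {
  skip_if_not_installed("mclust")
  # 7 phenotypes, >= 2 SD separation, through the full preprocessing path
  cfg <- synthetic_config(
    cells_per_sample = 2100,
    groups = list("g" = list(n_phenotypes = 7, scatter_prob = 1),
                  "h" = list(n_phenotypes = 7, scatter_prob = 1))
  )
  tbl <- simulate_sample(cfg, "g", "s1", seed = 31)
  lg <- suppressMessages(log2_transform(tbl))
  pp <- fit_preprocess(lg)
  mat <- apply_preprocess(pp, lg)
  scan <- kmeans_scan(mat, k_range = 7, seed = 7)
  ari <- mclust::adjustedRandIndex(scan$models[["7"]]$cluster, tbl$phenotype)
  expect_gt(ari, 0.8)
})

test_that("preprocessing and clustering are invariant to cell order", {
  blobs <- make_blobs(100, rbind(c(0, 0), c(6, 6)), sd = 0.4, seed = 8)
  colnames(blobs$data) <- c("M1", "M2")
  perm <- withr::with_seed(9, sample(nrow(blobs$data)))
  m1 <- fit_preprocess(blobs$data)
  m2 <- fit_preprocess(blobs$data[perm, ])
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  s1 <- apply_preprocess(m1, blobs$data)
  s2 <- apply_preprocess(m2, blobs$data[perm, ])
  expect_equal(s2, s1[perm, ], ignore_attr = TRUE)
})
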