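two_groups <- function(a, b) {
  tibble::tibble(value = c(a, b),
                 group = rep(c("A", "B"), c(length(a), length(b))))
}

test_that("pooled t-test matches the textbook computation", {
  df <- two_groups(c(1, 2, 3), c(4, 5, 6))
  got <- compare_means(df, value, group)
  # closed form: means 2 and 5, pooled var 1, se = sqrt(1*(1/3+1/3))
  t_expect <- (2 - 5) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(got$statistic, t_expect)
  expect_equal(got$p_value, 2 * pt(t_expect, df = 4))
  expect_false(got$adjusted)
  # identical groups: statistic 0, p 1
  same <- compare_means(two_groups(c(1, 2, 3), c(1, 2, 3)), value, group)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # swapping labels negates t, p unchanged
  rev <- compare_means(two_groups(c(4, 5, 6), c(1, 2, 3)), value, group)
  expect_equal(rev$statistic, -got$statistic)
  expect_equal(rev$p_value, got$p_value)
})

test_that("degenerate t-test inputs error as specified", {
  expect_error(compare_means(two_groups(1, c(2, 3)), value, group),
               "at least 2")
  expect_error(compare_means(two_groups(c(1, 1), c(2, 2)), value, group),
               "zero pooled variance")
  zero_var_same <- compare_means(two_groups(c(2, 2), c(2, 2)), value, group)
  expect_equal(zero_var_same$p_value, 1)
})

test_that("Mann-Whitney p is exact for the fully separated 4 vs 4 case", {
  df <- two_groups(c(1, 2, 3, 4), c(5, 6, 7, 8))
  got <- compare_ranks(df, value, group)
  # enumeration oracle: 2 of the C(8,4)=70 orderings are this extreme
  expect_equal(got$p_value, 2 / 70)
  expect_equal(got$statistic, 0)
})

test_that("U statistic is invariant under monotone transforms", {
  withr::with_seed(10, df <- two_groups(rnorm(8), rnorm(8) + 1))
  a <- compare_ranks(df, value, group)
  df2 <- dplyr::mutate(df, value = exp(value))
  b <- compare_ranks(df2, value, group)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  single <- compare_ranks(two_groups(3, 3), value, group)
  expect_equal(single$p_value, 1)
})

test_that("replicate correlation reproduces the limiting cases", {
  expect_equal(replicate_correlation(1:10, 2 * (1:10) + 3), 1)
  expect_equal(replicate_correlation(1:10, -(1:10)), -1)
  withr::with_seed(11, {
    r <- replicate_correlation(rnorm(1000), rnorm(1000))
  })
  expect_lt(abs(r), 0.1)
  expect_error(replicate_correlation(1:2, 1:2), "length")
  expect_error(replicate_correlation(rep(1, 5), 1:5), "variance")
})

test_that("range-thirds discretization follows the stated bin rule", {
  df <- tibble::tibble(subject_id = paste0("s", 1:4),
                       f = c(0, 3, 6.5, 9))
  got <- discretize_features(df, rule = "range")
  expect_equal(as.character(got$f), c("low", "medium", "high", "high"))
  # min -> low, max -> high by contract
  expect_equal(as.character(got$f[df$f == min(df$f)]), "low")
  expect_equal(as.character(got$f[df$f == max(df$f)]), "high")
})

test_that("tertile and range rules differ on skewed data and are labelled", {
  df <- tibble::tibble(subject_id = paste0("s", 1:20),
                       f = c(rep(0.1, 13), rep(0.2, 5), 5, 10))
  r1 <- discretize_features(df, rule = "range")
  r2 <- discretize_features(df, rule = "tertile")
  expect_false(identical(table(r1$f), table(r2$f)))
  expect_equal(attr(r1, "rules")$rule, "range")
  expect_equal(attr(r2, "rules")$rule, "tertile")
  cst <- tibble::tibble(subject_id = c("a", "b"), f = c(1, 1))
  expect_warning(got <- discretize_features(cst), "constant")
  expect_equal(as.character(got$f), c("medium", "medium"))
})

test_that("hierarchical integration reproduces closed-form distances", {
  disc <- tibble::tibble(
    subject_id = c("s1", "s2", "s3"),
    f1 = factor(c("low", "low", "high"), c("low", "medium", "high"),
                ordered = TRUE),
    f2 = factor(c("low", "low", "high"), c("low", "medium", "high"),
                ordered = TRUE)
  )
  got <- integrate_and_cluster(disc)
  # identical subjects merge first at height 0
  expect_equal(got$hclust$height[1], 0)
  first <- got$hclust$merge[1, ]
  expect_setequal(first, c(-1, -2))
  # all-low vs all-high over f features: distance 2 * sqrt(f)
  d <- dist(got$ordinal)
  expect_equal(as.matrix(d)["s1", "s3"], 2 * sqrt(2))
  expect_error(integrate_and_cluster(disc[1, ]), "at least 2")
})

test_that("duplicated subjects pair with their originals at height zero", {
  withr::with_seed(12, {
    df <- tibble::tibble(
      subject_id = paste0("s", 1:5),
      f1 = runif(5), f2 = runif(5), f3 = runif(5)
    )
  })
  disc <- discretize_features(df)
  dup <- dplyr::mutate(disc, subject_id = paste0(subject_id, "_dup"))
  both <- dplyr::bind_rows(disc, dup)
  got <- integrate_and_cluster(both)
  d <- as.matrix(dist(got$ordinal))
  expect_equal(unname(diag(d[disc$subject_id, dup$subject_id])), rep(0, 5))
  expect_gte(sum(got$hclust$height == 0), 5)
})

test_that("rank test has power on the planted cohort contrast", {
  cfg <- synthetic_config(
    n_subjects_per_group = 10,
    cells_per_sample = 300,
    rng_seed = 77
  )
  co <- simulate_cohort(cfg)
  cells <- suppressMessages(filter_quality(co$cells))
  hm <- hallmark_sets(default_marker_panel())[[1]]
  model <- fit_quantization(cells, hm$markers)
  per_subject <- co$subjects
  per_subject$mol <- vapply(per_subject$sample_id, function(s) {
    st <- encode_states(cells[cells$sample_id == s, ], model, hm)
    molecular_heterogeneity(st)
  }, numeric(1))
  got <- compare_ranks(per_subject, mol, group, alternative = "less")
  expect_lt(got$p_value, 0.05)
})
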