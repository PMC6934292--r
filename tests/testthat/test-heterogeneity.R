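two_cell_table <- function(distance) {
  tibble::tibble(
    cell_id = c("a", "b"), sample_id = "s1",
    x = c(0, distance), y = 0, area = pi, quality_score = 1, M1 = c(1, 2)
  )
}

test_that("neighbor rule is strict at 1.3 times the summed radii", {
  # radius 1 cells: contact iff distance < 2.6
  g <- build_neighbor_graph(two_cell_table(2.5))
  expect_equal(nrow(g$edges), 1)
  g2 <- build_neighbor_graph(two_cell_table(2.7))
  expect_equal(nrow(g2$edges), 0)
  g3 <- build_neighbor_graph(two_cell_table(2.6))  # boundary: not neighbors
  expect_equal(nrow(g3$edges), 0)
})

test_that("single-cell tables give one node and no edges", {
  g <- build_neighbor_graph(two_cell_table(1)[1, ])
  expect_equal(length(g$cell_id), 1)
  expect_equal(nrow(g$edges), 0)
  expect_equal(g$degree, 0L)
})

test_that("grid-indexed graph equals the brute-force oracle", {
  withr::with_seed(13, {
    n <- 300
    cells <- tibble::tibble(
      cell_id = paste0("c", 1:n), sample_id = "s1",
      x = runif(n, 0, 120), y = runif(n, 0, 120),
      area = pi * runif(n, 0.5, 3)^2, quality_score = 1, M1 = runif(n)
    )
  })
  g <- build_neighbor_graph(cells)
  oracle <- brute_force_edges(cells)
  canon <- function(e) e[order(e$from, e$to), ]
  expect_equal(canon(as.data.frame(g$edges)), canon(as.data.frame(oracle)),
               ignore_attr = TRUE)
  # symmetry is implicit in the from<to edge list; degrees count both ends
  expect_equal(sum(g$degree), 2 * nrow(g$edges))
  expect_true(all(g$edges$from < g$edges$to))
  expect_equal(g$radius, sqrt(cells$area / pi))
})

test_that("molecular heterogeneity matches closed forms", {
  expect_equal(molecular_heterogeneity(rep(5L, 100), n_states = 27), 0)
  expect_equal(molecular_heterogeneity(0:26, n_states = 27), 1)
  expect_equal(molecular_heterogeneity(rep(0:1, 50), n_states = 27),
               log(2) / log(27))
  expect_error(molecular_heterogeneity(integer(0), n_states = 27), "no cells")
})

test_that("spatial states count same-state neighbors only", {
  chain <- tibble::tibble(
    cell_id = c("a", "b", "c"), sample_id = "s1",
    x = c(0, 2, 4), y = 0, area = pi, quality_score = 1, M1 = 1
  )
  g <- build_neighbor_graph(chain)  # consecutive pairs only (4 > 2.6)
  expect_equal(nrow(g$edges), 2)
  expect_equal(spatial_states(g, c(7L, 7L, 7L)), c(1L, 2L, 1L))
  expect_equal(spatial_states(g, c(7L, 8L, 7L)), c(0L, 0L, 0L))
  # isolated cells all have spatial state zero
  iso <- build_neighbor_graph(dplyr::mutate(chain, x = c(0, 10, 20)))
  expect_equal(spatial_states(iso, c(7L, 7L, 7L)), c(0L, 0L, 0L))
})

test_that("spatial heterogeneity matches closed forms", {
  expect_equal(spatial_heterogeneity(rep(2L, 10), z_max = 2), 0)
  expect_equal(spatial_heterogeneity(0:4, z_max = 4), 1)
  expect_equal(
    spatial_heterogeneity(c(1L, 2L, 1L), z_max = 2),
    -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3)) / log(3)
  )
  # all isolated: one possible state, zero heterogeneity by convention
  expect_equal(spatial_heterogeneity(c(0L, 0L), z_max = 0), 0)
  expect_error(spatial_heterogeneity(c(0L, 3L), z_max = 2), "exceeds")
})

test_that("the report covers every sample-hallmark pair deterministically", {
  cfg <- small_config()
  co <- simulate_cohort(cfg)
  cells <- suppressMessages(filter_quality(co$cells))
  hms <- hallmark_sets(default_marker_panel())
  rep <- heterogeneity_report(cells, hms)
  expect_equal(nrow(rep), 4 * 2)
  expect_true(all(rep$molecular_heterogeneity >= 0 &
                    rep$molecular_heterogeneity <= 1))
  expect_true(all(rep$spatial_heterogeneity >= 0 &
                    rep$spatial_heterogeneity <= 1))
  expect_true(all(vapply(rep$pm, function(p) abs(sum(p) - 1) < 1e-12,
                         logical(1))))
  expect_true(all(vapply(rep$ps, function(p) abs(sum(p) - 1) < 1e-12,
                         logical(1))))
  # permuting cell order leaves the report unchanged
  withr::with_seed(2, perm <- sample(nrow(cells)))
  rep2 <- heterogeneity_report(cells[perm, ], hms)
  ord <- order(rep$sample_id, rep$hallmark)
  ord2 <- order(rep2$sample_id, rep2$hallmark)
  expect_equal(tidy(rep)[ord, ], tidy(rep2)[ord2, ], ignore_attr = TRUE)
})

test_that("label shuffling breaks spatial but not molecular structure", {
  cfg <- synthetic_config(
    cells_per_sample = 800,
    groups = list("g" = list(n_phenotypes = 3, scatter_prob = 0.05),
                  "h" = list(n_phenotypes = 3, scatter_prob = 0.05))
  )
  tbl <- simulate_sample(cfg, "g", "s1", seed = 17)
  model <- fit_quantization(tbl, cell_markers(tbl))
  hm <- hallmark_sets(default_marker_panel())[[1]]
  st <- encode_states(tbl, model, hm)
  g <- build_neighbor_graph(tbl)
  withr::with_seed(3, shuffled <- sample(st$state_code))
  same_orig <- mean(spatial_states(g, st$state_code))
  same_shuf <- mean(spatial_states(g, shuffled))
  expect_gt(same_orig, same_shuf)
  expect_equal(
    molecular_heterogeneity(st$state_code, n_states = 27),
    molecular_heterogeneity(shuffled, n_states = 27)
  )
})

test_that("replicate cores can be mean-pooled per subject", {
  rep <- tibble::tibble(
    sample_id = c("s1a", "s1b", "s2a"),
    hallmark = "h",
    molecular_heterogeneity = c(0.2, 0.4, 0.6),
    spatial_heterogeneity = c(0.1, 0.3, 0.5)
  )
  pooled <- pool_subject_metrics(
    rep, c(s1a = "s1", s1b = "s1", s2a = "s2")
  )
  expect_equal(pooled$molecular_heterogeneity[pooled$subject_id == "s1"], 0.3)
  expect_equal(pooled$n_cores, c(2, 1))
})
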