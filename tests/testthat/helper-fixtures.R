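# Small fixtures shared across test files; everything is built in code.

# Minimal hand-written cell table: geometry and intensities chosen so that
# expected values can be derived by hand.
toy_cells <- function() {
  tibble::tibble(
    cell_id = paste0("c", 1:3),
    sample_id = "s1",
    x = c(0, 2.5, 5.0),
    y = 0,
    area = pi,              # radius 1 for every cell
    quality_score = c(0.90, 0.95, 0.99),
    M1 = c(1, 5, 9),
    M2 = c(2, 4, 8)
  )
}

# Small cohort config used where full defaults would be slow.
small_config <- function(...) {
  synthetic_config(
    n_subjects_per_group = 2,
    cells_per_sample = 250,
    ...
  )
}

# Well-separated Gaussian blobs for clustering tests.
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    mats <- lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_per * ncol(centers), mean = centers[i, ], sd = sd),
             nrow = n_per, byrow = TRUE)
    })
    list(data = do.call(rbind, mats),
         labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# Brute-force O(n^2) neighbor oracle: strict inequality on
# dist < factor * (r_i + r_j).
brute_force_edges <- function(cells, contact_factor = 1.3) {
  r <- sqrt(cells$area / pi)
  n <- nrow(cells)
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      if (d < contact_factor * (r[i] + r[j])) {
        from <- c(from, i)
        to <- c(to, j)
      }
    }
  }
  tibble::tibble(from = from, to = to)
}

write_temp_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "cells.csv")
  readr::write_csv(df, path)
  path
}
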