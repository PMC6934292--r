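#' Default synthetic marker panel
#'
#' A small two-hallmark panel used by the synthetic cohort generator:
#' the three-marker proliferative-signaling set (EGFR, Ki67, Nestin) and
#' the four-marker angiogenesis set (SMA, VEGFR2, CD31, S100A4).
#'
#' @return A marker panel tibble (`marker`, `hallmark`, `compartment`).
#' @export
default_marker_panel <- function() {
  tibble::tibble(
    marker = c("EGFR", "Ki67", "Nestin", "SMA", "VEGFR2", "CD31", "S100A4"),
    hallmark = c(rep("proliferative_signaling", 3),
                 rep("inducing_angiogenesis", 4)),
    compartment = c("membrane", "nucleus", "cytoplasm", "cytoplasm",
                    "membrane", "membrane", "cytoplasm")
  )
}

#' Deterministic per-phenotype marker means
#'
#' Assigns each latent phenotype a per-marker mean on the log2 intensity
#' scale via an explicit ordinal design: each phenotype carries a
#' low/medium/high anchor level per marker and the mean is
#' `base + separation * (level - 1)`.  The first three phenotypes are the
#' pan-low, pan-high and pan-medium populations; each further phenotype
#' starts from pan-medium and deviates on two markers (one up, one down,
#' markers cycling with the phenotype index), so all profiles are
#' distinct and, in a mixed cohort, every marker's pooled intensity mass
#' stays close to a third per level -- which keeps cohort-fitted tertile
#' thresholds in the gaps between expression modes rather than splitting
#' a mode by noise.
#'
#' @param markers Character vector of marker names.
#' @param n_phenotypes Number of phenotypes (rows).
#' @param base Baseline (medium) log2 mean intensity.
#' @param separation Log2 mean shift per ordinal level step; with
#'   `separation` at least twice `marker_log_sd`, phenotypes are planted
#'   at least 2 SD apart on their differing markers.
#' @return Numeric matrix `n_phenotypes x length(markers)` of log2 means,
#'   with dimnames.
#' @export
phenotype_means <- function(markers, n_phenotypes, base = 6, separation = 2) {
  stopifnot(n_phenotypes >= 1)
  nm <- length(markers)
  lv <- matrix(1L, n_phenotypes, nm,
               dimnames = list(paste0("P", seq_len(n_phenotypes)), markers))
  if (n_phenotypes >= 1) lv[1, ] <- 0L
  if (n_phenotypes >= 2) lv[2, ] <- 2L
  # P3 stays pan-medium; P4+ deviate on two cycling markers
  for (p in seq_len(n_phenotypes)[-(1:3)]) {
    up <- (2L * (p - 4L)) %% nm + 1L
    down <- (2L * (p - 4L) + 1L) %% nm + 1L
    lv[p, up] <- 2L
    lv[p, down] <- 0L
  }
  base + separation * (lv - 1)
}

#' Configuration for the synthetic spatial cohort generator
#'
#' Defines a two-group study: each subject contributes one field of
#' spatially scattered cells whose marker intensities are driven by a
#' latent cell phenotype.  Spatial aggregation of like-phenotype cells is
#' produced by seeded nearest-phenotype assignment: `n_spatial_seeds`
#' random seed points each carry a phenotype, and a cell adopts its nearest
#' seed's phenotype with probability `1 - scatter_prob`, otherwise a
#' uniformly random phenotype of its group.  `scatter_prob = 0` gives
#' maximal aggregation, `scatter_prob = 1` complete spatial randomness.
#'
#' Group `g` uses phenotypes `1..n_phenotypes[g]` (rows of
#' `phenotype_marker_means`), so groups can share cell types.  Intensities
#' are log-normal: normal on the log2 scale around the phenotype's
#' per-marker mean with SD `marker_log_sd`.
#'
#' @param n_subjects_per_group Subjects per group (>= 1).
#' @param cells_per_sample Cells per subject field (>= 1).
#' @param field_width,field_height Field extent (length units).
#' @param groups Named list, one element per group label, each a list with
#'   `n_phenotypes` and `scatter_prob`.
#' @param phenotype_marker_means Matrix of per-phenotype, per-marker log2
#'   means covering every phenotype any group uses; defaults to
#'   [phenotype_means()] over [default_marker_panel()] markers.
#' @param marker_log_sd Within-phenotype SD on the log2 scale (> 0).
#' @param cell_radius_mean,cell_radius_sd Cell radius distribution
#'   (truncated normal, r > 0), in field length units.
#' @param n_spatial_seeds Number of phenotype seed points per field.
#' @param quality_score_range Interval in \[0, 1\] for uniform quality
#'   scores.
#' @param rng_seed Master seed; per-subject seeds are derived from it.
#' @return A validated list of class `synth_config`.
#' @export
synthetic_config <- function(n_subjects_per_group = 10,
                             cells_per_sample = 1000,
                             field_width = 600,
                             field_height = 600,
                             groups = list(
                               "mt-like" = list(n_phenotypes = 2,
                                                scatter_prob = 0.05),
                               "wt-like" = list(n_phenotypes = 6,
                                                scatter_prob = 0.95)
                             ),
                             phenotype_marker_means = NULL,
                             marker_log_sd = 0.5,
                             cell_radius_mean = 5,
                             cell_radius_sd = 1,
                             n_spatial_seeds = 25,
                             quality_score_range = c(0.7, 1),
                             rng_seed = 1L) {
  max_phen <- max(vapply(groups, function(g) g$n_phenotypes, numeric(1)))
  if (is.null(phenotype_marker_means)) {
    phenotype_marker_means <-
      phenotype_means(default_marker_panel()$marker, max_phen)
  }
  cfg <- list(
    n_subjects_per_group = n_subjects_per_group,
    cells_per_sample = cells_per_sample,
    field_width = field_width, field_height = field_height,
    groups = groups,
    phenotype_marker_means = phenotype_marker_means,
    marker_log_sd = marker_log_sd,
    cell_radius_mean = cell_radius_mean,
    cell_radius_sd = cell_radius_sd,
    n_spatial_seeds = n_spatial_seeds,
    quality_score_range = quality_score_range,
    rng_seed = as.integer(rng_seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$n_subjects_per_group, cfg$cells_per_sample,
              cfg$n_spatial_seeds,
              vapply(cfg$groups, function(g) g$n_phenotypes, numeric(1)))
  if (any(counts < 1)) abort("all counts must be >= 1")
  if (cfg$marker_log_sd <= 0) abort("marker_log_sd must be > 0")
  sp <- vapply(cfg$groups, function(g) g$scatter_prob, numeric(1))
  if (any(sp < 0 | sp > 1)) abort("scatter_prob must be in [0, 1]")
  q <- cfg$quality_score_range
  if (length(q) != 2 || q[1] > q[2] || q[1] < 0 || q[2] > 1) {
    abort("quality_score_range must be an interval within [0, 1]")
  }
  max_phen <- max(vapply(cfg$groups, function(g) g$n_phenotypes, numeric(1)))
  if (nrow(cfg$phenotype_marker_means) < max_phen) {
    abort("phenotype_marker_means must cover every phenotype in use")
  }
  if (any(is.na(cfg$phenotype_marker_means))) {
    abort("phenotype_marker_means must cover every marker for every phenotype")
  }
  invisible(cfg)
}

#' Read a synthetic configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [synthetic_config()]; `phenotype_marker_means` may be given as a list
#'   of per-phenotype named mean lists.
#' @return A `synth_config` object.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$phenotype_marker_means)) {
    rows <- raw$phenotype_marker_means
    mk <- names(rows[[1]])
    raw$phenotype_marker_means <- do.call(
      rbind, lapply(rows, function(r) unlist(r)[mk])
    )
    colnames(raw$phenotype_marker_means) <- mk
  }
  do.call(synthetic_config, raw)
}

# truncated normal on (0, Inf) by rejection; vectorized
rtrunc_norm_pos <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Simulate one subject's cell field
#'
#' Generates `cells_per_sample` cells: centroids uniform in the field,
#' areas `pi * r^2` with truncated-normal radii, latent phenotypes by the
#' seeded nearest-phenotype rule, log-normal marker intensities, and
#' uniform quality scores.  The latent phenotype is recorded in the
#' `phenotype` column as ground-truth metadata; no analysis function in
#' this package reads it.
#'
#' @param config A [synthetic_config()].
#' @param group Group label (must exist in `config$groups`).
#' @param sample_id Sample identifier for the output table.
#' @param seed Integer seed; the output is deterministic given
#'   `(config, group, sample_id, seed)`.
#' @return A cell table tibble.
#' @export
simulate_sample <- function(config, group, sample_id, seed) {
  stopifnot(inherits(config, "synth_config"))
  if (!group %in% names(config$groups)) {
    abort(paste0("unknown group label: ", group))
  }
  g <- config$groups[[group]]
  phen_pool <- seq_len(g$n_phenotypes)
  means <- config$phenotype_marker_means
  markers <- colnames(means)
  n <- config$cells_per_sample

  with_seed(seed, {
    x <- runif(n, 0, config$field_width)
    y <- runif(n, 0, config$field_height)
    r <- rtrunc_norm_pos(n, config$cell_radius_mean, config$cell_radius_sd)
    seeds_x <- runif(config$n_spatial_seeds, 0, config$field_width)
    seeds_y <- runif(config$n_spatial_seeds, 0, config$field_height)
    seed_phen <- sample(phen_pool, config$n_spatial_seeds, replace = TRUE)
    # nearest seed per cell
    d2 <- outer(x, seeds_x, "-")^2 + outer(y, seeds_y, "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    phen <- seed_phen[nearest]
    scatter <- runif(n) < g$scatter_prob
    phen[scatter] <- sample(phen_pool, sum(scatter), replace = TRUE)
    intens <- matrix(
      2^(rnorm(n * length(markers),
               mean = means[phen, , drop = FALSE],
               sd = config$marker_log_sd)),
      nrow = n, dimnames = list(NULL, markers)
    )
    q <- runif(n, config$quality_score_range[1], config$quality_score_range[2])
    dplyr::bind_cols(
      tibble::tibble(
        cell_id = paste0(sample_id, "_c", seq_len(n)),
        sample_id = sample_id,
        x = x, y = y,
        area = pi * r^2,
        quality_score = q,
        phenotype = phen
      ),
      tibble::as_tibble(intens)
    )
  })
}

#' Simulate a two-group cohort
#'
#' One cell table per subject, `n_subjects_per_group` per group.  Subject
#' seeds are derived deterministically from `config$rng_seed` (consecutive
#' offsets), so the whole cohort is reproducible from the one master seed.
#'
#' @param config A [synthetic_config()].
#' @return A list with `cells` (all subjects' cell tables bound into one
#'   tibble) and `subjects` (metadata tibble: `sample_id`, `group`,
#'   `n_phenotypes`, `scatter_prob`, `seed`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  grid <- tidyr::expand_grid(
    group = names(config$groups),
    subject = seq_len(config$n_subjects_per_group)
  )
  grid$sample_id <- paste0(gsub("[^A-Za-z0-9]", "", grid$group),
                           "_s", grid$subject)
  grid$seed <- config$rng_seed + seq_len(nrow(grid))
  cells <- purrr::pmap(grid, function(group, subject, sample_id, seed) {
    simulate_sample(config, group, sample_id, seed)
  })
  subjects <- tibble::tibble(
    sample_id = grid$sample_id,
    group = grid$group,
    n_phenotypes = vapply(config$groups[grid$group],
                          function(g) g$n_phenotypes, numeric(1)),
    scatter_prob = vapply(config$groups[grid$group],
                          function(g) g$scatter_prob, numeric(1)),
    seed = grid$seed
  )
  list(cells = dplyr::bind_rows(cells), subjects = subjects)
}
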