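#' Fit marker preprocessing for clustering
#'
#' On log2-transformed intensities, computes per-marker trim bounds at the
#' 2.5th and 97.5th percentiles and the post-trim mean and standard
#' deviation used for z-standardization.  Trimming is winsorization by
#' default: values outside the bounds are clipped to them, so no cell is
#' lost to downstream spatial or composition analyses; `method =
#' "exclude"` instead drops cells with any out-of-bounds marker.
#'
#' @param cells A cell table with log2-transformed intensities (see
#'   [log2_transform()]), or a numeric matrix cells x markers.
#' @param markers Marker columns to use; defaults to all.
#' @param trim_quantiles Lower/upper trim probabilities.
#' @param method `"winsorize"` (default) or `"exclude"`.
#' @return A tibble of class `preprocess_model` with columns `marker`,
#'   `lower`, `upper`, `mean`, `sd`, `degenerate`; attribute `"method"`.
#'   Zero-variance markers are flagged degenerate and excluded by
#'   [apply_preprocess()].
#' @export
fit_preprocess <- function(cells, markers = NULL,
                           trim_quantiles = c(0.025, 0.975),
                           method = c("winsorize", "exclude")) {
  method <- match.arg(method)
  mat <- as_marker_matrix(cells, markers)
  stopifnot(length(trim_quantiles) == 2,
            trim_quantiles[1] < trim_quantiles[2])
  rows <- purrr::map(colnames(mat), function(mk) {
    v <- mat[, mk]
    b <- quantile(v, trim_quantiles, names = FALSE, type = 7)
    w <- pmin(pmax(v, b[1]), b[2])
    tibble::tibble(marker = mk, lower = b[1], upper = b[2],
                   mean = mean(w), sd = sd(w))
  })
  out <- dplyr::bind_rows(rows)
  out$degenerate <- out$sd == 0 | !is.finite(out$sd)
  if (any(out$degenerate)) {
    warn(paste0("zero-variance marker(s) excluded from clustering: ",
                paste(out$marker[out$degenerate], collapse = ", ")))
  }
  attr(out, "method") <- method
  class(out) <- c("preprocess_model", class(out))
  out
}

#' Apply a fitted preprocessing model
#'
#' Winsorizes (or excludes) and z-standardizes each retained marker with
#' the statistics frozen in the model.
#'
#' @param model A `preprocess_model` from [fit_preprocess()].
#' @param cells Cell table or matrix with the model's markers.
#' @return Numeric matrix cells x retained markers in standardized space.
#'   Under `method = "exclude"` the `"kept_rows"` attribute maps rows back
#'   to the input.
#' @export
apply_preprocess <- function(model, cells) {
  keep <- model[!model$degenerate, ]
  mat <- as_marker_matrix(cells, keep$marker)
  n0 <- nrow(mat)
  if (identical(attr(model, "method"), "exclude")) {
    inb <- rep(TRUE, n0)
    for (i in seq_len(nrow(keep))) {
      v <- mat[, keep$marker[i]]
      inb <- inb & v >= keep$lower[i] & v <= keep$upper[i]
    }
    mat <- mat[inb, , drop = FALSE]
    kept <- which(inb)
  } else {
    kept <- seq_len(n0)
    for (i in seq_len(nrow(keep))) {
      mat[, i] <- pmin(pmax(mat[, i], keep$lower[i]), keep$upper[i])
    }
  }
  out <- sweep(sweep(mat, 2, keep$mean, "-"), 2, keep$sd, "/")
  attr(out, "kept_rows") <- kept
  out
}

as_marker_matrix <- function(cells, markers = NULL) {
  if (is.matrix(cells)) {
    if (!is.null(markers)) cells <- cells[, markers, drop = FALSE]
    return(cells)
  }
  markers <- markers %||% cell_markers(cells)
  as.matrix(cells[markers])
}

#' K-means scan over a range of cluster counts
#'
#' Fits best-of-`n_starts` K-means (squared-Euclidean objective,
#' `stats::kmeans`) for each K and records the model-selection metrics:
#' mean silhouette width, the Calinski-Harabasz criterion
#' `(B/(K-1)) / (W/(n-K))`, and the within-cluster sum of squares (SSE).
#' Deterministic given `seed`.
#'
#' @param data Standardized cells x markers matrix (see
#'   [apply_preprocess()]).
#' @param k_range Cluster counts to scan (default 2 to 15).
#' @param n_starts Random starts per K (default 10).
#' @param seed Integer seed.
#' @param silhouette_max_n Silhouette needs all pairwise distances; above
#'   this many cells a fixed-seed subsample of this size is scored instead.
#' @return An object of class `kmeans_scan`: list with `models` (named
#'   list of `kmeans` fits), `metrics` tibble (`k`, `sse`, `silhouette`,
#'   `calinski`), `n_starts`, `seed`.
#' @export
kmeans_scan <- function(data, k_range = 2:15, n_starts = 10, seed = 1,
                        silhouette_max_n = 5000) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (max(k_range) > n) abort("K exceeds the number of cells")
  sil_idx <- seq_len(n)
  with_seed(seed, {
    if (n > silhouette_max_n) sil_idx <- sort(sample.int(n, silhouette_max_n))
    d_sil <- dist(data[sil_idx, , drop = FALSE])
    models <- list()
    metrics <- purrr::map(k_range, function(k) {
      km <- kmeans_safe(data, k, n_starts)
      models[[as.character(k)]] <<- km
      sil <- mean(cluster::silhouette(km$cluster[sil_idx], d_sil)[, 3])
      ch <- (km$betweenss / (k - 1)) / (km$tot.withinss / (n - k))
      tibble::tibble(k = k, sse = km$tot.withinss, silhouette = sil,
                     calinski = ch)
    })
    structure(
      list(models = models, metrics = dplyr::bind_rows(metrics),
           n_starts = n_starts, seed = seed),
      class = "kmeans_scan"
    )
  })
}

# kmeans with retry on the rare empty-cluster / QuickTRANSfer failure
kmeans_safe <- function(data, k, n_starts) {
  for (attempt in 1:5) {
    km <- tryCatch(
      suppressWarnings(
        kmeans(data, centers = k, nstart = n_starts, iter.max = 100)
      ),
      error = function(e) NULL
    )
    if (!is.null(km) && all(km$size > 0)) return(km)
  }
  abort(paste0("kmeans failed to produce ", k, " nonempty clusters"))
}

#' @export
print.kmeans_scan <- function(x, ...) {
  cat("<kmeans_scan> K =", paste(range(x$metrics$k), collapse = ".."),
      "| best silhouette at K =",
      x$metrics$k[which.max(x$metrics$silhouette)], "\n")
  print(x$metrics)
  invisible(x)
}

#' Consensus clustering over cell subsamples
#'
#' Repeatedly clusters random subsets of the cells and summarizes, for
#' every cell pair, how often the two cells land in the same cluster among
#' the iterations where both were sampled.  A sharp consensus matrix
#' (entries near 0 or 1) indicates a stable cluster number.  When the data
#' has more than `subsample_cells` rows a fixed random subset of that size
#' is used for the whole procedure.
#'
#' @param data Standardized cells x markers matrix.
#' @param k_range Cluster counts to evaluate.
#' @param subsample_cells Cap on cells entering the consensus (default
#'   5000).
#' @param n_iterations Resampling iterations per K (default 1000).
#' @param resample_fraction Fraction of cells drawn (without replacement)
#'   per iteration, in (0, 1\]; default 0.8.
#' @param n_starts K-means starts within each iteration.
#' @param seed Integer seed.
#' @return An object of class `consensus_result`: per K a list with the
#'   consensus matrix (`NA` for pairs never co-sampled), the ECDF of
#'   off-diagonal consensus values, and the area under that CDF; plus the
#'   sampling settings.
#' @export
consensus_cluster <- function(data, k_range, subsample_cells = 5000,
                              n_iterations = 1000, resample_fraction = 0.8,
                              n_starts = 1, seed = 1) {
  data <- as.matrix(data)
  if (resample_fraction <= 0 || resample_fraction > 1) {
    abort("resample_fraction must be in (0, 1]")
  }
  with_seed(seed, {
    n_all <- nrow(data)
    idx <- if (n_all > subsample_cells) {
      sort(sample.int(n_all, subsample_cells))
    } else {
      seq_len(n_all)
    }
    dat <- data[idx, , drop = FALSE]
    n <- nrow(dat)
    m <- max(1L, floor(resample_fraction * n))
    per_k <- purrr::map(k_range, function(k) {
      together <- matrix(0, n, n)
      sampled <- matrix(0, n, n)
      for (it in seq_len(n_iterations)) {
        s <- sample.int(n, m)
        km <- kmeans_safe(dat[s, , drop = FALSE], k, n_starts)
        z <- matrix(0, m, k)
        z[cbind(seq_len(m), km$cluster)] <- 1
        together[s, s] <- together[s, s] + tcrossprod(z)
        sampled[s, s] <- sampled[s, s] + 1
      }
      cons <- together / sampled  # NaN where never co-sampled
      cons[sampled == 0] <- NA
      vals <- cons[upper.tri(cons)]
      vals <- vals[!is.na(vals)]
      cdf <- ecdf(vals)
      grid <- seq(0, 1, length.out = 101)
      list(k = k, consensus = cons, cdf = cdf,
           auc = mean(cdf(grid)),
           n_cells = n)
    })
    structure(
      list(results = setNames(per_k, as.character(k_range)),
           k_range = k_range, subsample_cells = subsample_cells,
           n_iterations = n_iterations,
           resample_fraction = resample_fraction, seed = seed),
      class = "consensus_result"
    )
  })
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>", x$n_iterations, "iterations at",
      x$resample_fraction * 100, "% resampling,",
      x$results[[1]]$n_cells, "cells\n")
  print(consensus_summary(x))
  invisible(x)
}

#' Per-K consensus summary
#'
#' @param consensus A [consensus_cluster()] result.
#' @return Tibble with per-K CDF area (`auc`), the gain over the previous
#'   K (`delta_auc`), and the proportion of ambiguous pairs (consensus in
#'   (0.1, 0.9), the PAC score; lower is sharper).
#' @export
consensus_summary <- function(consensus) {
  tib <- purrr::map(consensus$results, function(r) {
    vals <- r$consensus[upper.tri(r$consensus)]
    vals <- vals[!is.na(vals)]
    tibble::tibble(
      k = r$k, auc = r$auc,
      pac = mean(vals > 0.1 & vals < 0.9)
    )
  })
  out <- dplyr::bind_rows(tib)
  out$delta_auc <- c(NA, diff(out$auc)) / dplyr::lag(out$auc)
  out
}

#' Choose the number of clusters from the scan metrics
#'
#' Emits a per-criterion ranking (silhouette, Calinski, SSE elbow,
#' consensus CDF) and a recommended K by an explicit rule: the smallest K
#' at which the relative gain in consensus CDF area drops below
#' `flat_gain` (the CDF has flattened), tie-broken by silhouette; without
#' consensus results, the silhouette maximum.  The recommendation is
#' flagged unreliable when no criterion shows a distinct optimum (maximum
#' silhouette below 0.25), and a disagreement flag is raised when the
#' silhouette optimum differs from the recommendation.
#'
#' @param scan A [kmeans_scan()] result.
#' @param consensus Optional [consensus_cluster()] result.
#' @param flat_gain Relative CDF-area gain below which the consensus curve
#'   counts as flat.
#' @return List of class `k_choice`: `chosen_k`, `report` (per-K metric
#'   tibble), `flags` (character vector).
#' @export
choose_k <- function(scan, consensus = NULL, flat_gain = 0.1) {
  report <- scan$metrics
  flags <- character(0)
  if (!is.null(consensus)) {
    cs <- consensus_summary(consensus)
    report <- dplyr::left_join(report, cs, by = "k")
    flat <- which(report$delta_auc < flat_gain)
    chosen <- if (length(flat) > 0) {
      report$k[flat[1] - 1]  # last K before the gain flattens
    } else {
      report$k[which.max(report$silhouette)]
    }
  } else {
    chosen <- report$k[which.max(report$silhouette)]
  }
  sil_best <- report$k[which.max(report$silhouette)]
  if (sil_best != chosen) {
    flags <- c(flags, paste0("criteria disagree: silhouette prefers K=",
                             sil_best, ", consensus rule K=", chosen))
  }
  # no distinct optimum: uniformly weak or flat silhouette profile
  if (max(report$silhouette) < 0.25 ||
      diff(range(report$silhouette)) < 0.1) {
    flags <- c(flags, "unreliable: no criterion shows a distinct optimum")
  }
  structure(list(chosen_k = chosen, report = report, flags = flags),
            class = "k_choice")
}

#' @export
print.k_choice <- function(x, ...) {
  cat("<k_choice> recommended K =", x$chosen_k, "\n")
  if (length(x$flags)) cat(paste0("  ! ", x$flags, collapse = "\n"), "\n")
  print(x$report)
  invisible(x)
}

#' Per-cluster marker profiles (lollipop values)
#'
#' For each cluster, each marker's mean deviation from the population mean
#' in the analysis (standardized) space, plus the cluster's share of all
#' cells.  Size-weighted deviations sum to zero per marker.
#'
#' @param model A `kmeans` fit (one element of `kmeans_scan()$models`) or
#'   an integer assignment vector.
#' @param data The matrix the model was fitted on.
#' @return Tibble of class `cluster_profiles`: `cluster`, `marker`,
#'   `deviation`, `pct_cells`.
#' @export
cluster_profiles <- function(model, data) {
  assign <- if (inherits(model, "kmeans")) model$cluster else model
  data <- as.matrix(data)
  stopifnot(length(assign) == nrow(data))
  pop_mean <- colMeans(data)
  ks <- sort(unique(assign))
  out <- purrr::map(ks, function(k) {
    sel <- assign == k
    tibble::tibble(
      cluster = k,
      marker = colnames(data),
      deviation = colMeans(data[sel, , drop = FALSE]) - pop_mean,
      pct_cells = 100 * mean(sel)
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("cluster_profiles", class(out))
  out
}

#' Per-sample cluster composition
#'
#' Fraction of each sample's cells assigned to each cluster; fractions sum
#' to one per sample.
#'
#' @param model A `kmeans` fit or assignment vector.
#' @param sample_ids Sample identifier per cell (same order as the
#'   clustering matrix rows), or a cell table whose rows match.
#' @return Tibble of class `sample_composition`: `sample_id`, `cluster`,
#'   `fraction` (all clusters present for every sample, zeros included).
#' @export
sample_composition <- function(model, sample_ids) {
  assign <- if (inherits(model, "kmeans")) model$cluster else model
  if (is.data.frame(sample_ids)) sample_ids <- sample_ids$sample_id
  stopifnot(length(assign) == length(sample_ids))
  out <- tibble::tibble(sample_id = sample_ids, cluster = assign) |>
    dplyr::count(.data$sample_id, .data$cluster) |>
    tidyr::complete(.data$sample_id, cluster = sort(unique(assign)),
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "cluster", "fraction")
  class(out) <- c("sample_composition", class(out))
  out
}
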