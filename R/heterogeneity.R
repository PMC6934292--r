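#' Build the cell-contact neighbor graph of one sample
#'
#' Two cells are neighbors when the Euclidean distance between their
#' centroids is strictly less than `contact_factor` times the sum of their
#' circle-equivalent radii (`sqrt(area/pi)`).  The graph is undirected,
#' has no self-edges, and is built within one sample only.
#'
#' A uniform-grid spatial index keeps the search near-linear for large
#' fields; the edge set is identical to the all-pairs computation because
#' the bucket width bounds the largest possible contact distance.
#'
#' @param cells A cell table containing exactly one sample.
#' @param contact_factor Multiple of the summed radii that still counts as
#'   contact; 1.3 by default.
#' @return An object of class `neighbor_graph`: list with `cell_id`,
#'   `edges` (tibble `from`/`to` of cell indices, `from < to`), `degree`
#'   (per-cell neighbor count, input order), `radius`, and
#'   `contact_factor`.
#' @export
build_neighbor_graph <- function(cells, contact_factor = 1.3) {
  if (length(unique(cells$sample_id)) > 1) {
    abort("build_neighbor_graph() takes one sample at a time")
  }
  stopifnot(all(cells$area > 0), contact_factor > 0)
  n <- nrow(cells)
  r <- cell_radius(cells$area)
  x <- cells$x
  y <- cells$y

  edges_from <- integer(0)
  edges_to <- integer(0)
  if (n > 1) {
    cw <- 2 * contact_factor * max(r)  # max possible contact distance
    gx <- floor((x - min(x)) / cw)
    gy <- floor((y - min(y)) / cw)
    key <- paste(gx, gy)
    buckets <- split(seq_len(n), key)
    bucket_of <- function(a, b) buckets[[paste(a, b)]]
    acc_from <- integer(0)
    acc_to <- integer(0)
    for (b in buckets) {
      bx <- gx[b[1]]
      by <- gy[b[1]]
      cand <- unlist(lapply(-1:1, function(dx) {
        unlist(lapply(-1:1, function(dy) bucket_of(bx + dx, by + dy)))
      }), use.names = FALSE)
      for (i in b) {
        j <- cand[cand > i]
        if (length(j) == 0) next
        d2 <- (x[j] - x[i])^2 + (y[j] - y[i])^2
        hit <- j[d2 < (contact_factor * (r[i] + r[j]))^2]
        if (length(hit) > 0) {
          acc_from <- c(acc_from, rep.int(i, length(hit)))
          acc_to <- c(acc_to, hit)
        }
      }
    }
    edges_from <- acc_from
    edges_to <- acc_to
  }
  degree <- tabulate(c(edges_from, edges_to), nbins = n)
  structure(
    list(
      cell_id = cells$cell_id,
      edges = tibble::tibble(from = edges_from, to = edges_to),
      degree = degree,
      radius = r,
      contact_factor = contact_factor
    ),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph> ", length(x$cell_id), " cells, ",
      nrow(x$edges), " contacts (factor ", x$contact_factor,
      "), max degree ", max(c(0L, x$degree)), "\n", sep = "")
  invisible(x)
}

# shared entropy core: normalized Shannon entropy of a frequency vector,
# 0*ln 0 := 0, normalized by ln(n_possible)
normalized_entropy <- function(freq, n_possible) {
  if (n_possible <= 1) return(0)
  p <- freq[freq > 0]
  -sum(p * log(p)) / log(n_possible)
}

#' Molecular heterogeneity of a sample
#'
#' Normalized Shannon entropy of the molecular-state frequency
#' distribution: `-sum_i Pm_i ln(Pm_i) / ln(Nm)`, where `Pm_i` is the
#' fraction of cells in state `i` and `Nm` the number of possible states
#' of the hallmark set.  Ranges from 0 (all cells in one state) to 1
#' (cells uniform over all `Nm` states).
#'
#' @param states A `state_assignment` from [encode_states()], or an integer
#'   vector of state codes (then `n_states` is required).
#' @param n_states State-space size `Nm`; taken from the assignment when
#'   omitted.
#' @return Scalar in \[0, 1\].
#' @export
molecular_heterogeneity <- function(states, n_states = NULL) {
  if (inherits(states, "state_assignment")) {
    n_states <- n_states %||% attr(states, "n_states")
    states <- states$state_code
  }
  if (length(states) == 0) abort("no cells: cannot compute heterogeneity")
  if (is.null(n_states) || n_states < 3) {
    abort("n_states must be given and >= 3")
  }
  freq <- as.vector(table(states)) / length(states)
  normalized_entropy(freq, n_states)
}

#' Per-cell spatial states
#'
#' A cell's spatial state is the number of its graph neighbors that share
#' its exact molecular state code.  Zero (no same-state neighbors, or no
#' neighbors at all) is a valid spatial state and is retained.
#'
#' @param graph A [build_neighbor_graph()] result.
#' @param states A `state_assignment`, or a vector of state codes ordered
#'   as the graph's cells.
#' @return Integer vector of same-state neighbor counts, one per cell in
#'   graph order.
#' @export
spatial_states <- function(graph, states) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (inherits(states, "state_assignment")) {
    idx <- match(graph$cell_id, states$cell_id)
    if (anyNA(idx)) abort("graph and state assignment cover different cells")
    codes <- states$state_code[idx]
  } else {
    codes <- states
    if (length(codes) != length(graph$cell_id)) {
      abort("graph and state vector cover different cells")
    }
  }
  same <- codes[graph$edges$from] == codes[graph$edges$to]
  counts <- tabulate(c(graph$edges$from[same], graph$edges$to[same]),
                     nbins = length(codes))
  as.integer(counts)
}

#' Spatial heterogeneity of a sample
#'
#' Normalized Shannon entropy of the spatial-state frequency distribution:
#' `-sum_k Ps_k ln(Ps_k) / ln(Z_max + 1)` for `k = 0..Z_max`, where `Ps_k`
#' is the fraction of cells with spatial state `k` and `Z_max` is the
#' maximum neighbor count observed in the sample.  When `Z_max = 0` (every
#' cell isolated) only one spatial state is possible and the metric is 0
#' by convention.
#'
#' @param counts Integer vector of per-cell spatial states from
#'   [spatial_states()].
#' @param z_max Maximum neighbor count in the sample (the graph's maximum
#'   degree, not the maximum same-state count).
#' @return Scalar in \[0, 1\].
#' @export
spatial_heterogeneity <- function(counts, z_max) {
  if (length(counts) == 0) abort("no cells: cannot compute heterogeneity")
  if (any(counts > z_max)) abort("spatial state exceeds z_max")
  if (z_max == 0) return(0)
  freq <- tabulate(counts + 1L, nbins = z_max + 1L) / length(counts)
  normalized_entropy(freq, z_max + 1)
}

#' Per-sample, per-hallmark heterogeneity report
#'
#' Runs the full heterogeneity computation for every sample and hallmark:
#' encode molecular states with a shared quantization model, build the
#' sample's contact graph once, and compute both normalized-entropy
#' metrics.  Deterministic and invariant to cell order.
#'
#' @param cells A quality-filtered cell table (one or more samples).
#' @param hallmarks A list of [hallmark_set()]s (e.g. from
#'   [hallmark_sets()]).
#' @param model Optional `quantization_model`; fitted on the pooled cohort
#'   when omitted.
#' @param contact_factor Contact multiple for the neighbor graph.
#' @return A tibble of class `heterogeneity_report`: one row per
#'   sample x hallmark with `sample_id`, `hallmark`, `n_cells`, `n_states`
#'   (`Nm`), `z_max`, `molecular_heterogeneity`, `spatial_heterogeneity`,
#'   and list-columns `pm` / `ps` holding the state frequency
#'   distributions.
#' @export
heterogeneity_report <- function(cells, hallmarks, model = NULL,
                                 contact_factor = 1.3) {
  if (inherits(hallmarks, "hallmark_set")) hallmarks <- list(hallmarks)
  need <- unique(unlist(lapply(hallmarks, function(h) h$markers)))
  if (is.null(model)) {
    model <- fit_quantization(cells, markers = need, scope = "cohort")
  }
  samples <- unique(cells$sample_id)
  rows <- purrr::map(samples, function(s) {
    sub <- cells[cells$sample_id == s, ]
    graph <- build_neighbor_graph(sub, contact_factor = contact_factor)
    z_max <- max(c(0L, graph$degree))
    purrr::map(hallmarks, function(h) {
      st <- encode_states(sub, model, h)
      ss <- spatial_states(graph, st)
      pm <- table(factor(st$state_code, levels = 0:(attr(st, "n_states") - 1)))
      pm <- as.vector(pm) / nrow(st)
      ps <- tabulate(ss + 1L, nbins = z_max + 1L) / length(ss)
      tibble::tibble(
        sample_id = s,
        hallmark = h$name,
        n_cells = nrow(sub),
        n_states = attr(st, "n_states"),
        z_max = z_max,
        molecular_heterogeneity = molecular_heterogeneity(st),
        spatial_heterogeneity = spatial_heterogeneity(ss, z_max),
        pm = list(pm),
        ps = list(ps)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("heterogeneity_report", class(out))
  out
}

#' Pool replicate cores per subject
#'
#' Averages the per-core heterogeneity metrics over cores of one subject
#' (mean pooling); use when several tissue cores per subject were measured
#' and one value per subject is needed for group testing.
#'
#' @param report A [heterogeneity_report()].
#' @param subject_of Named vector mapping `sample_id` to subject identifier.
#' @return A tibble with one row per subject x hallmark.
#' @export
pool_subject_metrics <- function(report, subject_of) {
  report |>
    dplyr::mutate(subject_id = subject_of[.data$sample_id]) |>
    dplyr::group_by(.data$subject_id, .data$hallmark) |>
    dplyr::summarise(
      n_cores = dplyr::n(),
      molecular_heterogeneity = mean(.data$molecular_heterogeneity),
      spatial_heterogeneity = mean(.data$spatial_heterogeneity),
      .groups = "drop"
    )
}
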