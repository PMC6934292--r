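#' Fit per-marker tertile quantization thresholds
#'
#' Computes each marker's 33rd and 67th empirical quantiles (linear
#' interpolation between order statistics, `stats::quantile()` type 7) over
#' the scoped cells.  These thresholds map a continuous intensity to an
#' ordinal low/medium/high level via [assign_levels()].
#'
#' The default scope pools all cells of the cohort, so every sample shares
#' one state definition and heterogeneity values are comparable across
#' samples; `scope = "sample"` fits a separate threshold pair per sample.
#'
#' @param cells A cell table (quality-filtered).
#' @param markers Markers to fit; defaults to all marker columns.
#' @param scope `"cohort"` (pooled, default) or `"sample"`.
#' @return A tibble of class `quantization_model` with columns `marker`,
#'   `q33`, `q67`, `degenerate` (and `sample_id` under per-sample scope);
#'   attribute `"scope"` records the fit scope.  A constant marker yields
#'   `q33 == q67` and is flagged degenerate (every cell then gets level 0).
#' @export
fit_quantization <- function(cells, markers = cell_markers(cells),
                             scope = c("cohort", "sample")) {
  scope <- match.arg(scope)
  fit_one <- function(df) {
    qs <- vapply(markers, function(m) {
      quantile(df[[m]], c(0.33, 0.67), names = FALSE, type = 7)
    }, numeric(2))
    tibble::tibble(
      marker = markers,
      q33 = unname(qs[1, ]), q67 = unname(qs[2, ]),
      degenerate = unname(qs[1, ] == qs[2, ])
    )
  }
  if (scope == "cohort") {
    if (nrow(cells) < 3) abort("need at least 3 cells to fit quantiles")
    out <- fit_one(cells)
  } else {
    out <- cells |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_modify(function(df, key) {
        if (nrow(df) < 3) abort("need at least 3 cells per sample")
        fit_one(df)
      }) |>
      dplyr::ungroup()
  }
  if (any(out$degenerate)) {
    warn(paste0("degenerate (constant) marker(s): ",
                paste(unique(out$marker[out$degenerate]), collapse = ", ")))
  }
  attr(out, "scope") <- scope
  class(out) <- c("quantization_model", class(out))
  out
}

#' Assign an ordinal level from tertile thresholds
#'
#' Boundary convention (fixed): `value <= q33` is low (0),
#' `q33 < value <= q67` is medium (1), `value > q67` is high (2).
#'
#' @param value Numeric vector of intensities.
#' @param q33,q67 Thresholds with `q33 <= q67` (recycled).
#' @return Integer vector of levels in `{0, 1, 2}`.
#' @export
assign_levels <- function(value, q33, q67) {
  stopifnot(all(q33 <= q67))
  ifelse(value <= q33, 0L, ifelse(value <= q67, 1L, 2L))
}

#' Number of possible molecular states of a hallmark set
#'
#' Three ordinal levels per marker give `3^m` possible states for an
#' `m`-marker set; e.g. 27 for a three-marker set.
#'
#' @param hallmark A [hallmark_set()] or a character vector of markers.
#' @return Integer state-space size `Nm`.
#' @export
state_space_size <- function(hallmark) {
  m <- if (inherits(hallmark, "hallmark_set")) hallmark$markers else hallmark
  as.integer(3^length(m))
}

#' Encode per-cell molecular states over a hallmark set
#'
#' Quantizes each hallmark marker with the fitted thresholds and
#' concatenates the ordinal levels, in the hallmark's fixed marker order,
#' into a base-3 state code: `code = sum_j level_j * 3^(j-1)` with the
#' first marker least significant.  Codes run from 0 (all low) to
#' `Nm - 1 = 3^m - 1` (all high).
#'
#' @param cells A cell table.
#' @param model A `quantization_model` covering the hallmark's markers.
#' @param hallmark A [hallmark_set()].
#' @return A tibble of class `state_assignment`: `sample_id`, `cell_id`,
#'   one `level_<marker>` column per marker, and `state_code`.  Attributes:
#'   `"hallmark"`, `"n_states"`.
#' @export
encode_states <- function(cells, model, hallmark) {
  stopifnot(inherits(hallmark, "hallmark_set"))
  missing <- setdiff(hallmark$markers, model$marker)
  if (length(missing) > 0) {
    abort(paste0("marker(s) missing from quantization model: ",
                 paste(missing, collapse = ", ")))
  }
  missing_tbl <- setdiff(hallmark$markers, names(cells))
  if (length(missing_tbl) > 0) {
    abort(paste0("hallmark marker(s) absent from cell table: ",
                 paste(missing_tbl, collapse = ", ")))
  }
  per_sample <- identical(attr(model, "scope"), "sample")
  out <- tibble::tibble(sample_id = cells$sample_id, cell_id = cells$cell_id)
  code <- integer(nrow(cells))
  for (j in seq_along(hallmark$markers)) {
    mk <- hallmark$markers[j]
    row <- model[model$marker == mk, ]
    if (per_sample) {
      idx <- match(cells$sample_id, row$sample_id)
      if (anyNA(idx)) abort("sample missing from per-sample model")
      lv <- assign_levels(cells[[mk]], row$q33[idx], row$q67[idx])
    } else {
      lv <- assign_levels(cells[[mk]], row$q33[1], row$q67[1])
    }
    out[[paste0("level_", mk)]] <- lv
    code <- code + lv * 3L^(j - 1L)
  }
  out$state_code <- code
  attr(out, "hallmark") <- hallmark
  attr(out, "n_states") <- state_space_size(hallmark)
  class(out) <- c("state_assignment", class(out))
  out
}

#' Decode a base-3 state code into its level vector
#'
#' Inverse of the encoding used by [encode_states()]: digit `j` (first
#' marker least significant) recovers marker `j`'s level.
#'
#' @param code Integer vector of state codes.
#' @param n_markers Number of markers in the hallmark set.
#' @return Integer matrix `length(code) x n_markers` of levels.
#' @export
decode_state <- function(code, n_markers) {
  stopifnot(all(code >= 0), all(code < 3^n_markers))
  out <- vapply(seq_len(n_markers),
                function(j) code %/% 3^(j - 1) %% 3,
                numeric(length(code)))
  out <- matrix(out, nrow = length(code))
  storage.mode(out) <- "integer"
  out
}

#' Save / load a quantization model
#'
#' Serializes the thresholds to a plain-text YAML file so the exact state
#' definition can be reused across runs.
#'
#' @param model A `quantization_model`.
#' @param path Output / input file path.
#' @return `path` invisibly; `read_quantization()` returns the model.
#' @export
write_quantization <- function(model, path) {
  payload <- list(
    scope = attr(model, "scope"),
    thresholds = purrr::transpose(as.list(tibble::as_tibble(model)))
  )
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' @rdname write_quantization
#' @export
read_quantization <- function(path) {
  payload <- yaml::read_yaml(path)
  out <- dplyr::bind_rows(lapply(payload$thresholds, tibble::as_tibble))
  attr(out, "scope") <- payload$scope
  class(out) <- c("quantization_model", class(out))
  out
}
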