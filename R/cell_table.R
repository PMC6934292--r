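#' Read a per-cell marker table
#'
#' Reads a delimited per-cell table as produced by a segmentation workflow:
#' one row per cell with a cell identifier, sample identifier, centroid
#' coordinates, segmented area, a registration quality score in \[0, 1\],
#' and one nonnegative intensity column per marker.  Rows violating the
#' record invariants (quality score outside \[0, 1\], non-positive area,
#' negative intensity, missing values) are rejected with a per-row report
#' attached as the `"rejected"` attribute, never silently dropped.
#'
#' @param path Path to a delimited text file with a header row.  Comma is
#'   the default delimiter; tab is accepted (`delim = "\t"` or a `.tsv`
#'   extension).
#' @param schema Optional named character vector mapping the standard column
#'   names (`cell_id`, `sample_id`, `x`, `y`, `area`, `quality_score`) to
#'   the column names used in the file, e.g.
#'   `c(cell_id = "Cell.ID", x = "Centroid.X")`.  Unmapped standard names
#'   are looked up verbatim.  All remaining numeric columns are treated as
#'   marker intensities.
#' @param delim Field delimiter; guessed from the file extension when `NULL`.
#' @return A tibble (cell table) with the standard columns followed by one
#'   column per marker.  Attributes: `"rejected"` (tibble of excluded rows
#'   with a `reason` column), `"markers"`.
#' @export
read_cell_table <- function(path, schema = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cell table file not found: ", path))
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)

  mandatory <- c("cell_id", "sample_id", "x", "y", "area", "quality_score")
  lookup <- setNames(mandatory, mandatory)
  if (!is.null(schema)) lookup[names(schema)] <- schema
  missing <- lookup[!lookup %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0(
      "missing mandatory column(s): ",
      paste0(names(missing), " (looked for '", missing, "')", collapse = ", ")
    ))
  }
  # rename file columns to the standard names
  names(raw)[match(lookup, names(raw))] <- names(lookup)

  markers <- setdiff(names(raw), .reserved_cols)
  if (length(markers) < 1) {
    abort("no marker intensity columns found after resolving the schema")
  }
  non_numeric <- markers[!vapply(raw[markers], is.numeric, logical(1))]
  if (length(non_numeric) > 0) {
    abort(paste0("non-numeric intensity column(s): ",
                 paste(non_numeric, collapse = ", ")))
  }

  dup <- duplicated(raw[c("sample_id", "cell_id")])
  if (any(dup)) {
    abort(paste0("duplicate (sample_id, cell_id) pairs, e.g. row ",
                 which(dup)[1]))
  }

  validate_cell_table(raw, markers = markers)
}

#' Validate cell records row by row
#'
#' Applies the per-record invariants (quality score in \[0, 1\], positive
#' area, nonnegative finite intensities) and splits the table into valid
#' records and a rejection report.
#'
#' @param cells A cell table.
#' @param markers Marker columns to validate; defaults to [cell_markers()].
#' @return The valid rows as a tibble, with the rejected rows (plus a
#'   `reason` column) in the `"rejected"` attribute.
#' @export
validate_cell_table <- function(cells, markers = cell_markers(cells)) {
  cells <- tibble::as_tibble(cells)
  intens <- as.matrix(cells[markers])
  reason <- character(nrow(cells))
  bad_q <- is.na(cells$quality_score) | cells$quality_score < 0 |
    cells$quality_score > 1
  bad_a <- is.na(cells$area) | cells$area <= 0
  bad_i <- rowSums(is.na(intens) | intens < 0 | !is.finite(intens)) > 0
  bad_xy <- is.na(cells$x) | is.na(cells$y)
  reason[bad_i] <- "negative or missing intensity"
  reason[bad_a] <- "non-positive area"
  reason[bad_q] <- "quality score outside [0, 1]"
  reason[bad_xy] <- "missing coordinate"
  bad <- reason != ""
  rejected <- dplyr::mutate(cells[bad, ], reason = reason[bad])
  if (nrow(rejected) > 0) {
    inform(paste0(nrow(rejected), " of ", nrow(cells),
                  " cell record(s) rejected; see attr(x, 'rejected')"))
  }
  out <- cells[!bad, ]
  attr(out, "rejected") <- rejected
  attr(out, "markers") <- markers
  out
}

#' Write a cell table
#'
#' Writes the same delimited dialect that [read_cell_table()] reads, at full
#' double precision so that read, write, read round-trips are lossless.
#'
#' @param cells A cell table.
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @param delim Field delimiter; guessed from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::write_delim(cells, path, delim = delim)
  invisible(path)
}

#' Filter cells by registration quality score
#'
#' Retains exactly the cells whose quality score is strictly greater than
#' the threshold.  The default of 0.85 reproduces the common rule of
#' including only cells with a registration quality score above 0.85.
#'
#' @param cells A cell table.
#' @param threshold Quality threshold in \[0, 1\]; strict inequality.
#' @return The retained rows, in input order, with `"n_retained"` and
#'   `"n_removed"` attributes.  Idempotent: filtering twice at the same
#'   threshold is a no-op.
#' @export
filter_quality <- function(cells, threshold = 0.85) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1)
  keep <- cells$quality_score > threshold
  out <- cells[keep, ]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  inform(paste0("quality filter (> ", threshold, "): retained ", sum(keep),
                ", removed ", sum(!keep)))
  out
}

#' Log2-transform marker intensities
#'
#' Replaces each intensity `v` by `log2(v + pseudocount)`; all structural
#' columns are unchanged.  When `pseudocount` is `NULL`, 0 is used if every
#' intensity is positive and 1 otherwise.
#'
#' @param cells A cell table.
#' @param markers Marker columns to transform; defaults to all.
#' @param pseudocount Nonnegative offset; must be positive if any intensity
#'   is zero.
#' @return The transformed cell table, with the pseudocount recorded in the
#'   `"pseudocount"` attribute.
#' @export
log2_transform <- function(cells, markers = cell_markers(cells),
                           pseudocount = NULL) {
  intens <- as.matrix(cells[markers])
  has_zero <- any(intens == 0)
  if (is.null(pseudocount)) {
    pseudocount <- if (has_zero) 1 else 0
    if (has_zero) inform("zero intensities present; using pseudocount 1")
  }
  stopifnot(pseudocount >= 0)
  if (has_zero && pseudocount == 0) {
    abort("zero intensities require a positive pseudocount")
  }
  cells[markers] <- log2(intens + pseudocount)
  attr(cells, "pseudocount") <- pseudocount
  cells
}

#' Read a marker panel
#'
#' A marker panel assigns each marker to one or more cancer hallmarks and
#' records its subcellular compartment.  Expected columns: `marker`,
#' `hallmark` (semicolon-separated when a marker serves several hallmarks),
#' and optionally `compartment` and `display_name`.
#'
#' @param path Delimited text file (comma default, tab for `.tsv`).
#' @return A tibble with one row per marker.
#' @export
read_marker_panel <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  panel <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  if (!all(c("marker", "hallmark") %in% names(panel))) {
    abort("marker panel needs 'marker' and 'hallmark' columns")
  }
  panel
}

#' Construct a hallmark marker set
#'
#' A hallmark set is a small *ordered* list of markers defining a molecular
#' state space.  The marker order fixes the concatenation sequence of the
#' base-3 state code and must be kept constant across an analysis; it is
#' frozen at construction.
#'
#' @param name Hallmark label.
#' @param markers Character vector of marker names, length >= 1, no
#'   duplicates.
#' @return An object of class `hallmark_set`.
#' @export
hallmark_set <- function(name, markers) {
  stopifnot(is.character(name), length(name) == 1)
  markers <- as.character(markers)
  if (length(markers) < 1) abort("a hallmark set needs at least one marker")
  if (anyDuplicated(markers)) abort("duplicate markers in hallmark set")
  structure(list(name = name, markers = markers), class = "hallmark_set")
}

#' @export
print.hallmark_set <- function(x, ...) {
  cat("<hallmark_set> ", x$name, ": ",
      paste(x$markers, collapse = " > "),
      "  (", state_space_size(x), " states)\n", sep = "")
  invisible(x)
}

#' Hallmark sets from a marker panel
#'
#' Expands a marker panel into one [hallmark_set()] per hallmark label,
#' preserving the panel's marker order within each set (the concatenation
#' sequence).
#'
#' @param panel Marker panel tibble from [read_marker_panel()].
#' @return Named list of `hallmark_set` objects.
#' @export
hallmark_sets <- function(panel) {
  long <- tidyr::separate_rows(panel, "hallmark", sep = ";\\s*")
  split_markers <- split(long$marker, long$hallmark)
  # split() orders alphabetically; restore first-appearance hallmark order
  ord <- unique(long$hallmark)
  purrr::imap(split_markers[ord], function(m, nm) hallmark_set(nm, m))
}
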