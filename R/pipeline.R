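#' Assemble a pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the input (a synthetic
#' cohort configuration, or paths to a cell table and subject table),
#' quality threshold, quantization scope, hallmark definitions, clustering
#' settings, and the master seed from which every stage seed is derived.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading real
#'   tables.
#' @param cells_path,subjects_path Delimited input tables (ignored when
#'   `synthetic` is given).  The subject table must have `sample_id` and
#'   `group` columns.
#' @param panel Marker panel tibble; defaults to [default_marker_panel()].
#' @param quality_threshold Quality-score cutoff (strict).
#' @param quantization_scope `"cohort"` or `"sample"`.
#' @param k_range,n_starts K-means scan settings.
#' @param consensus_iterations,consensus_subsample,resample_fraction
#'   Consensus clustering settings (`consensus_iterations = 0` skips the
#'   consensus stage).
#' @param seed Master seed; per-stage seeds are fixed offsets from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       cells_path = NULL, subjects_path = NULL,
                       panel = default_marker_panel(),
                       quality_threshold = 0.85,
                       quantization_scope = "cohort",
                       k_range = 2:8, n_starts = 10,
                       consensus_iterations = 100,
                       consensus_subsample = 5000,
                       resample_fraction = 0.8,
                       seed = 1L) {
  if (is.null(synthetic)) {
    for (p in c(cells_path, subjects_path)) {
      if (is.null(p) || !file.exists(p)) {
        abort(paste0("input file missing: ", p %||% "(not set)"))
      }
    }
  }
  structure(
    list(synthetic = synthetic, cells_path = cells_path,
         subjects_path = subjects_path, panel = panel,
         quality_threshold = quality_threshold,
         quantization_scope = quantization_scope,
         k_range = k_range, n_starts = n_starts,
         consensus_iterations = consensus_iterations,
         consensus_subsample = consensus_subsample,
         resample_fraction = resample_fraction,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching [run_config()] arguments; a
#'   `synthetic:` block is forwarded to [synthetic_config()]
#'   (`synthetic: ~` selects file input via `cells_path`/`subjects_path`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  }
  if (!is.null(raw$k_range)) raw$k_range <- do.call(seq, as.list(raw$k_range))
  do.call(run_config, raw)
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11L, encode = 23L, cluster = 37L, compare = 53L)
  config$seed + unname(offsets[stage])
}

#' Run the full heterogeneity pipeline
#'
#' Executes the stages in order -- simulate/ingest, quality control, state
#' encoding, heterogeneity metrics, phenotype clustering, group
#' comparison, multimodal integration -- writing each stage's tables under
#' `out_dir` and a JSON manifest listing every output with the
#' configuration hash and seed.  A rerun with the same configuration and
#' seed reproduces the tables exactly.
#'
#' @param config A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with every stage's in-memory result plus the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tibble::as_tibble(df), p)
    outputs[[name]] <<- p
    p
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # -- simulate / ingest ------------------------------------------------
  cohort <- run_stage("ingest", {
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$rng_seed <- stage_seed(config, "simulate")
      simulate_cohort(cfg)
    } else {
      list(cells = read_cell_table(config$cells_path),
           subjects = readr::read_csv(config$subjects_path,
                                      show_col_types = FALSE))
    }
  })
  emit(cohort$subjects, "subjects")

  # -- qc ---------------------------------------------------------------
  cells <- run_stage("qc", {
    suppressMessages(filter_quality(cohort$cells, config$quality_threshold))
  })
  emit(dplyr::count(cells, .data$sample_id, name = "n_cells"), "qc_counts")

  hallmarks <- hallmark_sets(config$panel)
  markers <- unique(config$panel$marker)

  # -- encode -----------------------------------------------------------
  model <- run_stage("encode", {
    fit_quantization(cells, markers = markers,
                     scope = config$quantization_scope)
  })
  write_quantization(model, file.path(out_dir, "quantization.yaml"))
  outputs[["quantization"]] <- file.path(out_dir, "quantization.yaml")

  # -- heterogeneity ----------------------------------------------------
  het <- run_stage("heterogeneity", {
    heterogeneity_report(cells, hallmarks, model = model)
  })
  emit(tidy(het), "heterogeneity")

  # -- cluster ----------------------------------------------------------
  cl <- run_stage("cluster", {
    lg <- suppressMessages(log2_transform(cells, markers))
    pp <- fit_preprocess(lg, markers)
    mat <- apply_preprocess(pp, lg)
    scan <- kmeans_scan(mat, k_range = config$k_range,
                        n_starts = config$n_starts,
                        seed = stage_seed(config, "cluster"))
    cons <- NULL
    if (config$consensus_iterations > 0) {
      cons <- consensus_cluster(
        mat, k_range = config$k_range,
        subsample_cells = config$consensus_subsample,
        n_iterations = config$consensus_iterations,
        resample_fraction = config$resample_fraction,
        seed = stage_seed(config, "cluster")
      )
    }
    choice <- choose_k(scan, cons)
    best <- scan$models[[as.character(choice$chosen_k)]]
    list(scan = scan, consensus = cons, choice = choice, model = best,
         profiles = cluster_profiles(best, mat),
         composition = sample_composition(best, cells))
  })
  emit(cl$choice$report, "cluster_selection")
  emit(cl$profiles, "cluster_profiles")
  emit(cl$composition, "sample_composition")

  # -- compare ----------------------------------------------------------
  comp <- run_stage("compare", {
    subj <- cohort$subjects
    het_g <- dplyr::left_join(tidy(het),
                              subj[c("sample_id", "group")],
                              by = "sample_id")
    by_hm <- split(het_g, het_g$hallmark)
    dplyr::bind_rows(purrr::imap(by_hm, function(df, hm) {
      mol <- compare_ranks(df, .data$molecular_heterogeneity, .data$group)
      spa <- compare_ranks(df, .data$spatial_heterogeneity, .data$group)
      mol$feature <- paste0(hm, ":molecular")
      spa$feature <- paste0(hm, ":spatial")
      dplyr::bind_rows(mol, spa)
    }))
  })
  emit(comp, "group_comparisons")

  # -- integrate --------------------------------------------------------
  integ <- run_stage("integrate", {
    het_wide <- tidy(het) |>
      dplyr::select("sample_id", "hallmark", "molecular_heterogeneity",
                    "spatial_heterogeneity") |>
      tidyr::pivot_wider(
        names_from = "hallmark",
        values_from = c("molecular_heterogeneity", "spatial_heterogeneity")
      )
    comp_wide <- cl$composition |>
      dplyr::mutate(cluster = paste0("cluster_", .data$cluster)) |>
      tidyr::pivot_wider(names_from = "cluster", values_from = "fraction")
    feats <- dplyr::left_join(het_wide, comp_wide, by = "sample_id") |>
      dplyr::rename(subject_id = "sample_id")
    disc <- discretize_features(feats, rule = "range")
    list(features = feats, discretized = disc,
         clustering = integrate_and_cluster(disc))
  })
  emit(integ$discretized, "integration_features")
  emit(tidy(integ$clustering), "integration_tree")

  manifest <- list(
    package = "cellhet",
    seed = config$seed,
    config_hash = rlang::hash(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, cells = cells, quantization = model,
                 heterogeneity = het, clustering = cl, comparisons = comp,
                 integration = integ, manifest = manifest))
}
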