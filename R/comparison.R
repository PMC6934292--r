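#' Compare per-subject means between two groups (Student's t)
#'
#' Two-sided unpaired Student's t-test with pooled variance (Welch by
#' `var_equal = FALSE`).  Inputs are per-subject summaries (e.g. a
#' subject's mean marker expression or heterogeneity metric), never
#' per-cell values.  P-values are reported unadjusted; adjust downstream
#' if the context calls for it.
#'
#' @param data Data frame with one row per subject.
#' @param value Column of per-subject values (tidy-eval).
#' @param group Column with exactly two group labels (tidy-eval).
#' @param var_equal Pooled variance (classical Student) when `TRUE`.
#' @return One-row tibble of class `group_comparison`: `feature`,
#'   `group1`, `group2`, `n1`, `n2`, `statistic`, `p_value`, `method`,
#'   `adjusted` (always `FALSE`).
#' @export
compare_means <- function(data, value, group, var_equal = TRUE) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  feature <- rlang::as_label(rlang::enquo(value))
  lv <- unique(g)
  if (length(lv) != 2) abort("compare_means() needs exactly two groups")
  a <- v[g == lv[1]]
  b <- v[g == lv[2]]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 subjects")
  }
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (var_equal && pooled_var == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      abort("zero pooled variance with unequal means")
    }
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
  }
  new_group_comparison(
    feature = feature, group1 = as.character(lv[1]),
    group2 = as.character(lv[2]), n1 = length(a), n2 = length(b),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    method = if (var_equal) "Student t (pooled variance)" else "Welch t"
  )
}

#' Compare per-subject values between two groups (Mann-Whitney)
#'
#' Wilcoxon rank-sum / Mann-Whitney U test on per-subject values.  The
#' p-value is exact for small samples without ties (the `stats::wilcox.test`
#' policy: exact below 50 per group when no ties are present) and uses the
#' normal approximation otherwise.  Unadjusted, as is conventional for
#' per-hallmark heterogeneity contrasts.
#'
#' @inheritParams compare_means
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`
#'   (first group relative to second).
#' @return One-row `group_comparison` tibble; `statistic` is the
#'   Mann-Whitney U of the first group.
#' @export
compare_ranks <- function(data, value, group, alternative = "two.sided") {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  feature <- rlang::as_label(rlang::enquo(value))
  lv <- unique(g)
  if (length(lv) != 2) abort("compare_ranks() needs exactly two groups")
  a <- v[g == lv[1]]
  b <- v[g == lv[2]]
  if (length(a) < 1 || length(b) < 1) abort("empty group")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative))
  # complete ties across both groups: no evidence against the null
  if (is.nan(wt$p.value)) wt$p.value <- 1
  new_group_comparison(
    feature = feature, group1 = as.character(lv[1]),
    group2 = as.character(lv[2]), n1 = length(a), n2 = length(b),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    method = paste0("Mann-Whitney (", alternative, ")")
  )
}

new_group_comparison <- function(...) {
  out <- tibble::tibble(..., adjusted = FALSE)
  class(out) <- c("group_comparison", class(out))
  out
}

#' Slide-to-slide replicate correlation
#'
#' Pearson correlation between paired per-field summaries from replicate
#' slides (e.g. cells per field of view on slide A vs slide B).
#'
#' @param values_a,values_b Paired numeric vectors, equal length >= 3.
#' @return Pearson r (scalar).
#' @export
replicate_correlation <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 3) {
    abort("need paired vectors of equal length >= 3")
  }
  if (sd(values_a) == 0 || sd(values_b) == 0) {
    abort("zero variance: correlation undefined")
  }
  cor(values_a, values_b, method = "pearson")
}

#' Discretize per-subject features into low/medium/high
#'
#' Bins each numeric feature into three ordinal groups for multimodal
#' integration.  `rule = "range"` (default) uses three equal-width bins
#' spanning the observed range with half-open upper boundaries and the
#' maximum assigned to high; `rule = "tertile"` bins at the 33rd/67th
#' quantiles with the [assign_levels()] boundary convention.  Constant
#' features are flagged and assigned medium.
#'
#' @param data Data frame with a subject identifier column and numeric
#'   feature columns.
#' @param rule `"range"` or `"tertile"`.
#' @param id_col Name of the subject identifier column.
#' @return Tibble of class `discretized_features`: id column plus one
#'   ordered factor (`low < medium < high`) per feature.  The binning rule
#'   per feature is recorded in the `"rules"` attribute.
#' @export
discretize_features <- function(data, rule = c("range", "tertile"),
                                id_col = "subject_id") {
  rule <- match.arg(rule)
  feats <- setdiff(names(data), id_col)
  num <- feats[vapply(data[feats], is.numeric, logical(1))]
  if (length(num) == 0) abort("no numeric feature columns")
  lvls <- c("low", "medium", "high")
  rules <- list()
  out <- tibble::tibble(!!id_col := data[[id_col]])
  for (f in num) {
    v <- data[[f]]
    if (max(v) == min(v)) {
      warn(paste0("constant feature '", f, "': assigned medium"))
      out[[f]] <- factor("medium", levels = lvls, ordered = TRUE)
      rules[[f]] <- tibble::tibble(feature = f, rule = "constant",
                                   b1 = NA_real_, b2 = NA_real_)
      next
    }
    if (rule == "range") {
      b <- min(v) + (max(v) - min(v)) * c(1, 2) / 3
      lev <- ifelse(v < b[1], 0L, ifelse(v < b[2], 1L, 2L))
    } else {
      b <- quantile(v, c(0.33, 0.67), names = FALSE, type = 7)
      lev <- assign_levels(v, b[1], b[2])
    }
    out[[f]] <- factor(lvls[lev + 1L], levels = lvls, ordered = TRUE)
    rules[[f]] <- tibble::tibble(feature = f, rule = rule,
                                 b1 = b[1], b2 = b[2])
  }
  attr(out, "rules") <- dplyr::bind_rows(rules)
  class(out) <- c("discretized_features", class(out))
  out
}

#' Hierarchically cluster subjects on discretized features
#'
#' Maps low/medium/high to ordinals 0/1/2 and clusters subjects by
#' agglomerative hierarchical clustering on Euclidean distances of the
#' ordinal vectors.  Average linkage by default; the linkage is recorded
#' in the result.
#'
#' @param disc A [discretize_features()] result.
#' @param linkage Agglomeration method passed to `stats::hclust`.
#' @param id_col Subject identifier column.
#' @return List of class `integration_clust`: `hclust` (the fitted tree,
#'   labels = subject ids), `order` (leaf order, subject ids), `linkage`,
#'   `ordinal` (the numeric matrix used).
#' @export
integrate_and_cluster <- function(disc, linkage = "average",
                                  id_col = "subject_id") {
  feats <- setdiff(names(disc), id_col)
  if (nrow(disc) < 2) abort("need at least 2 subjects to cluster")
  ord <- vapply(disc[feats], function(f) as.integer(f) - 1L,
                integer(nrow(disc)))
  ord <- matrix(ord, nrow = nrow(disc),
                dimnames = list(disc[[id_col]], feats))
  hc <- hclust(dist(ord, method = "euclidean"), method = linkage)
  structure(
    list(hclust = hc, order = rownames(ord)[hc$order],
         linkage = linkage, ordinal = ord),
    class = "integration_clust"
  )
}

#' @export
print.integration_clust <- function(x, ...) {
  cat("<integration_clust>", nrow(x$ordinal), "subjects,",
      ncol(x$ordinal), "features,", x$linkage, "linkage\n")
  cat("leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}
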