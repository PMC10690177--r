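#' Total spike-in reads per sample
#' @param counts a [count_matrix].
#' @return named numeric vector of ERCC totals.
#' @export
ercc_totals <- function(counts) {
  sp <- spikein_rows(counts)
  if (length(sp) == 0) stop("count matrix contains no spike-in features")
  colSums(counts$counts[sp, , drop = FALSE])
}

#' ERCC-derived per-sample scale factors
#'
#' The spike-ins are added in fixed amount per cell-equivalent, so their total
#' read count measures how much sequencing each sample received. The factor
#' for sample s is `ercc_total(reference) / ercc_total(s)`; multiplying a
#' sample's counts by its factor equalizes total spike-in signal across
#' samples, exposing global shifts that library-size normalization erases.
#'
#' @param counts a [count_matrix] containing spike-in rows.
#' @param reference sample id to anchor factors to, or `"first"` (default):
#'   the first sample in column order. Factors are relative, so every
#'   downstream ratio is invariant to this choice.
#' @return a `scale_factors` object: `factor_of` (named vector, reference = 1),
#'   `reference`, `reference_ercc_total`, and the raw `ercc_total` vector.
#' @export
compute_scale_factors <- function(counts, reference = "first") {
  totals <- ercc_totals(counts)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0) {
    stop("sample '", zero[1], "' has zero spike-in reads; cannot normalize")
  }
  if (identical(reference, "first")) reference <- names(totals)[1]
  if (!reference %in% names(totals)) {
    stop("reference sample '", reference, "' not found")
  }
  structure(
    list(factor_of = totals[[reference]] / totals,
         reference = reference,
         reference_ercc_total = totals[[reference]],
         ercc_total = totals),
    class = "scale_factors"
  )
}

#' @export
print.scale_factors <- function(x, ...) {
  cat("scale_factors (reference:", x$reference, ")\n")
  print(round(x$factor_of, 4))
  invisible(x)
}

#' Total-library-size scale factors (comparison baseline)
#'
#' Conventional normalization by total gene reads (spike-ins excluded, as in
#' a pipeline without spike-ins). By construction this equalizes the
#' non-spike-in totals across samples, so any genuine global shift in
#' transcriptional output is invisible to it — the failure mode the ERCC
#' anchor exists to fix. Provided so the two normalizations can be compared
#' on the same data.
#'
#' @param counts a [count_matrix].
#' @param reference sample id or `"first"`.
#' @return a `scale_factors` object (with `method = "library_size"`).
#' @export
library_size_factors <- function(counts, reference = "first") {
  keep <- counts$class_of != "spikein"
  totals <- colSums(counts$counts[keep, , drop = FALSE])
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0) stop("sample '", zero[1], "' has zero gene reads")
  if (identical(reference, "first")) reference <- names(totals)[1]
  structure(
    list(factor_of = totals[[reference]] / totals,
         reference = reference,
         reference_ercc_total = totals[[reference]],
         ercc_total = totals, method = "library_size"),
    class = "scale_factors")
}

#' Apply ERCC scale factors to a count matrix
#'
#' Every count is multiplied by its sample's factor; after normalization the
#' total spike-in signal is identical across samples by construction, and the
#' reference sample is unchanged.
#'
#' @param counts a [count_matrix].
#' @param factors a `scale_factors` object covering all samples.
#' @return a `normalized_matrix`: `values` (non-negative reals), plus the
#'   class/condition maps and the factors used, kept as provenance.
#' @export
normalize_counts <- function(counts, factors) {
  missing <- setdiff(samples_of(counts), names(factors$factor_of))
  if (length(missing) > 0) {
    stop("sample '", missing[1], "' has no scale factor")
  }
  f <- factors$factor_of[samples_of(counts)]
  values <- sweep(counts$counts, 2, f, `*`)
  structure(
    list(values = values, class_of = counts$class_of,
         condition_of = counts$condition_of, factors = factors),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples (reference:", x$factors$reference, ")\n")
  invisible(x)
}

#' Class-level totals of normalized signal
#'
#' Sums normalized values per sample within each feature class, plus the
#' all-feature total excluding spike-ins. When the matrix carries condition
#' labels a condition-level view pooling replicates (sum over the condition's
#' samples) is returned as well: the study's headline readout is whether
#' these pooled class totals shift between conditions.
#'
#' @param norm a `normalized_matrix`.
#' @return list with `per_sample` and (if conditions known) `per_condition`
#'   data frames in long form (`class` includes `total_non_spikein`).
#' @export
compute_class_totals <- function(norm) {
  cls <- norm$class_of
  per_class <- rowsum(norm$values, group = cls)
  non_spike <- colSums(per_class[rownames(per_class) != "spikein", ,
                                 drop = FALSE])
  m <- rbind(per_class, total_non_spikein = non_spike)
  per_sample <- data.frame(
    sample = rep(colnames(m), each = nrow(m)),
    class = rep(rownames(m), times = ncol(m)),
    total = as.vector(m), stringsAsFactors = FALSE)
  out <- list(per_sample = per_sample)
  if (!is.null(norm$condition_of)) {
    cond <- norm$condition_of[colnames(m)]
    pooled <- t(rowsum(t(m), group = cond))
    out$per_condition <- data.frame(
      condition = rep(colnames(pooled), each = nrow(pooled)),
      class = rep(rownames(pooled), times = ncol(pooled)),
      total = as.vector(pooled), stringsAsFactors = FALSE)
  }
  out
}

#' ERCC-anchored RPKM for expression ranking
#'
#' RPKM computed from ERCC-normalized counts, further normalized by gene
#' length: for gene g, `rpkm = mean_norm(g) * 1e9 / (length_bp(g) * T)` where
#' `mean_norm` averages the condition's replicates and `T` is the condition's
#' total non-spike-in normalized signal (sum of the per-gene means). With all
#' factors at 1 this reduces to standard RPKM; any monotone variant preserves
#' the ranking this quantity exists for. Spike-ins are excluded.
#'
#' @param norm a `normalized_matrix` with condition labels.
#' @param annotation a [feature_annotation] giving gene lengths.
#' @param condition condition label whose replicates are averaged (the
#'   control cells, for the study's "ranked by RPKM in control" use).
#' @return data frame `feature_id`, `class`, `length_bp`, `mean_norm`,
#'   `rpkm`, sorted by `rpkm` descending with ties broken by `feature_id`.
#' @export
compute_rpkm <- function(norm, annotation, condition) {
  if (is.null(norm$condition_of)) stop("matrix has no condition labels")
  samples <- names(norm$condition_of)[norm$condition_of == condition]
  if (length(samples) == 0) stop("no samples with condition '", condition, "'")
  keep <- norm$class_of != "spikein"
  vals <- norm$values[keep, samples, drop = FALSE]
  mean_norm <- rowMeans(vals)
  ids <- rownames(vals)
  missing <- setdiff(ids, annotation$feature_id)
  if (length(missing) > 0) stop("no annotation for feature '", missing[1], "'")
  len <- annotation[ids, "length_bp"]
  if (any(len <= 0)) stop("feature '", ids[len <= 0][1], "' has length <= 0")
  total <- sum(mean_norm)
  rpkm <- if (total > 0) mean_norm * 1e9 / (len * total) else rep(0, length(ids))
  df <- data.frame(feature_id = ids, class = unname(norm$class_of[ids]),
                   length_bp = len, mean_norm = unname(mean_norm),
                   rpkm = unname(rpkm), stringsAsFactors = FALSE)
  df <- df[order(-df$rpkm, df$feature_id), ]
  rownames(df) <- NULL
  attr(df, "condition") <- condition
  df
}
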