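#' Exact one-tail Poisson two-sample test
#'
#' Tests whether a count differs between two samples (or pooled conditions)
#' with unequal sequencing exposure. With `X_ref ~ Poisson(lambda * s_ref)`
#' and `X_alt ~ Poisson(lambda * s_alt)`, conditioning on the total
#' `n = x_ref + x_alt` makes `X_alt ~ Binomial(n, p0)` under the null, with
#' `p0 = s_alt / (s_ref + s_alt)`. The exposures are the ERCC-derived
#' effective weights: a sample with a larger spike-in total was sequenced
#' deeper, so under the null it should receive proportionally more reads.
#' The test runs on raw integer counts; no rescaled non-integer values enter.
#'
#' @param x_ref,x_alt non-negative integer counts (vectorized).
#' @param s_ref,s_alt positive exposure weights (e.g. pooled ERCC totals).
#' @param tail `"greater"` returns `P(X >= x_alt)`, `"less"` `P(X <= x_alt)`.
#' @return p-values in (0, 1]; `x_ref + x_alt = 0` gives 1 (no evidence).
#' @export
poisson_two_sample_test <- function(x_ref, x_alt, s_ref = 1, s_alt = 1,
                                    tail = c("greater", "less")) {
  tail <- match.arg(tail)
  if (any(x_ref < 0) || any(x_alt < 0)) stop("counts must be non-negative")
  if (any(x_ref != round(x_ref)) || any(x_alt != round(x_alt))) {
    stop("counts must be integers")
  }
  if (any(s_ref <= 0) || any(s_alt <= 0)) stop("exposure weights must be > 0")
  n <- x_ref + x_alt
  p0 <- s_alt / (s_ref + s_alt)
  p <- if (tail == "greater") {
    stats::pbinom(x_alt - 1, n, p0, lower.tail = FALSE)
  } else {
    stats::pbinom(x_alt, n, p0)
  }
  p[n == 0] <- 1
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sorted ascending, `p_(i) * m / i`, running minimum
#' from the largest down, clipped at 1, returned in input order.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted values, order-preserving with the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  scaled <- m / seq_len(m) * p_values[o]
  adj_sorted <- pmin(1, rev(cummin(rev(scaled))))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

#' Call differentially expressed genes between two conditions
#'
#' Replicates are pooled by summing raw counts per condition (Poisson sums
#' are Poisson, so the pooled count is the sufficient statistic) and each
#' non-spike-in feature is tested with [poisson_two_sample_test] using pooled
#' ERCC totals as exposures, one tail in the direction of the observed
#' normalized fold change. BH adjustment runs jointly across all tested
#' features; a gene is called up when `fc >= fc_threshold` and
#' `fdr < fdr_threshold`, down when `fc <= 1/fc_threshold` and
#' `fdr < fdr_threshold`, otherwise unchanged.
#'
#' An alternative per-replicate-pair mode (`pool = FALSE`) tests each
#' replicate pair separately and keeps, per gene, the least significant pair
#' (a conservative intersection), for sensitivity analysis.
#'
#' @param counts a [count_matrix] with exactly two conditions.
#' @param factors `scale_factors` from [compute_scale_factors].
#' @param cfg an [analysis_config].
#' @param condition_of optional named sample -> condition map overriding the
#'   one stored in `counts`.
#' @param ref_condition reference (control) condition label; default the
#'   condition of the first sample.
#' @param pool pool replicates before testing (default TRUE).
#' @return `diff_result` data frame: `gene`, `class`, `count_ref`,
#'   `count_alt` (pooled raw), `fc`, `log2fc`, `p_value`, `fdr`, `call`,
#'   `mean_expression` (mean normalized count across all samples).
#' @export
call_degs <- function(counts, factors, cfg = analysis_config(),
                      condition_of = NULL, ref_condition = NULL,
                      pool = TRUE) {
  cond <- condition_of %||% counts$condition_of
  if (is.null(cond)) stop("no condition labels supplied")
  cond <- cond[samples_of(counts)]
  if (anyNA(cond)) stop("a sample lacks a condition label")
  levels <- unique(cond)
  if (length(levels) != 2) {
    stop("exactly two conditions required, found ", length(levels))
  }
  ref <- ref_condition %||% cond[[1]]
  alt <- setdiff(levels, ref)
  if (!ref %in% levels || length(alt) != 1) stop("bad reference condition")

  keep <- counts$class_of != "spikein"
  raw <- counts$counts[keep, , drop = FALSE]
  etot <- factors$ercc_total[samples_of(counts)]
  ref_samples <- names(cond)[cond == ref]
  alt_samples <- names(cond)[cond == alt]

  norm_all <- sweep(raw, 2, factors$factor_of[colnames(raw)], `*`)
  mean_expression <- rowMeans(norm_all)

  if (pool) {
    x_ref <- rowSums(raw[, ref_samples, drop = FALSE])
    x_alt <- rowSums(raw[, alt_samples, drop = FALSE])
    w_ref <- sum(etot[ref_samples])
    w_alt <- sum(etot[alt_samples])
    res <- .deg_one_pair(x_ref, x_alt, w_ref, w_alt, cfg)
  } else {
    if (length(ref_samples) != length(alt_samples)) {
      stop("per-replicate-pair mode needs equal replicate numbers")
    }
    pair <- lapply(seq_along(ref_samples), function(i) {
      .deg_one_pair(raw[, ref_samples[i]], raw[, alt_samples[i]],
                    etot[[ref_samples[i]]], etot[[alt_samples[i]]], cfg)
    })
    worst <- Reduce(function(a, b) {
      pick <- b$p_value > a$p_value
      a[pick, ] <- b[pick, ]
      a
    }, pair)
    res <- worst
    res$p_value <- pmin(1, res$p_value)
    x_ref <- rowSums(raw[, ref_samples, drop = FALSE])
    x_alt <- rowSums(raw[, alt_samples, drop = FALSE])
  }

  fdr <- bh_fdr(res$p_value)
  call <- rep("unchanged", nrow(raw))
  call[res$fc >= cfg$fc_threshold & fdr < cfg$fdr_threshold] <- "up"
  call[res$fc <= 1 / cfg$fc_threshold & fdr < cfg$fdr_threshold] <- "down"

  out <- data.frame(
    gene = rownames(raw),
    class = unname(counts$class_of[keep]),
    count_ref = unname(x_ref), count_alt = unname(x_alt),
    fc = res$fc, log2fc = log2(res$fc),
    p_value = res$p_value, fdr = fdr, call = call,
    mean_expression = unname(mean_expression),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ref_condition") <- ref
  attr(out, "alt_condition") <- alt
  class(out) <- c("diff_result", "data.frame")
  ns_log("call_degs: ", sum(call == "up"), " up, ", sum(call == "down"),
         " down of ", nrow(out), " tested (", ref, " vs ", alt, ")")
  out
}

.deg_one_pair <- function(x_ref, x_alt, w_ref, w_alt, cfg) {
  # normalized pooled counts on the reference exposure scale
  norm_ref <- as.numeric(x_ref)
  norm_alt <- as.numeric(x_alt) * w_ref / w_alt
  fc <- (norm_alt + cfg$pseudocount) / (norm_ref + cfg$pseudocount)
  p <- numeric(length(fc))
  up <- fc >= 1
  if (any(up)) {
    p[up] <- poisson_two_sample_test(x_ref[up], x_alt[up], w_ref, w_alt,
                                     tail = "greater")
  }
  if (any(!up)) {
    p[!up] <- poisson_two_sample_test(x_ref[!up], x_alt[!up], w_ref, w_alt,
                                      tail = "less")
  }
  data.frame(fc = unname(fc), p_value = unname(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-gene z-score matrix across samples
#'
#' For each gene, subtracts the mean abundance across all samples and divides
#' by the sample (n-1) standard deviation across those samples — the heatmap
#' scaling convention. Rows with zero standard deviation map to all zeros.
#'
#' @param norm a `normalized_matrix` (or plain numeric matrix).
#' @param genes optional character vector restricting the rows (order kept).
#' @return a `zscore_matrix`: list with `z` (matrix), `mean`, `sd`.
#' @export
zscore_matrix <- function(norm, genes = NULL) {
  m <- if (is.matrix(norm)) norm else norm$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) stop("gene '", missing[1], "' not in matrix")
    m <- m[genes, , drop = FALSE]
  }
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  structure(list(z = z, mean = mu, sd = sd), class = "zscore_matrix")
}

#' Top expression-ranked differential genes
#'
#' Restricts results to differential calls (`up` or `down`), ranks them by
#' control-condition RPKM descending (ties broken lexicographically by gene
#' id, a stable rule) and returns the first `n` — the "top highly expressed
#' DEGs" view. If fewer than `n` DEGs exist, all are returned.
#'
#' @param results a `diff_result` from [call_degs].
#' @param summary RPKM table from [compute_rpkm].
#' @param n slice size (default 100).
#' @return `diff_result` rows with an `rpkm` column, ranked.
#' @export
rank_and_slice_top <- function(results, summary, n = 100) {
  if (n < 1) stop("n must be >= 1")
  degs <- results[results$call != "unchanged", , drop = FALSE]
  rpkm <- stats::setNames(summary$rpkm, summary$feature_id)
  missing <- setdiff(degs$gene, names(rpkm))
  if (length(missing) > 0) stop("no RPKM for gene '", missing[1], "'")
  degs$rpkm <- unname(rpkm[degs$gene])
  degs <- degs[order(-degs$rpkm, degs$gene), , drop = FALSE]
  out <- utils::head(degs, n)
  rownames(out) <- NULL
  out
}

#' Gene-length comparison across differential-call groups
#'
#' Partitions genes into activated (`up`), repressed (`down`) and unchanged
#' groups and compares gene-body lengths pairwise with a two-sided Wilcoxon
#' rank-sum test: exact when both groups have <= 10 genes, normal
#' approximation (with continuity correction) above. An empty group yields
#' `NA` p-values for its pairs rather than an error.
#'
#' @param results a `diff_result`, or the ranked slice from
#'   [rank_and_slice_top] when `scope = "top_n"`.
#' @param annotation a [feature_annotation] giving lengths.
#' @param scope `"all_degs"` uses `results` as-is; `"top_n"` re-slices via
#'   [rank_and_slice_top] (requires `summary`).
#' @param summary RPKM table, needed for `scope = "top_n"`.
#' @param n slice size for `scope = "top_n"`.
#' @return a `length_comparison`: list with `lengths` (per group) and
#'   `tests` (data frame of pairwise results).
#' @export
compare_lengths <- function(results, annotation,
                            scope = c("all_degs", "top_n"),
                            summary = NULL, n = 100) {
  scope <- match.arg(scope)
  if (scope == "top_n") {
    if (is.null(summary)) stop("scope 'top_n' requires the RPKM summary")
    results <- rank_and_slice_top(results, summary, n)
  }
  len_of <- stats::setNames(annotation$length_bp, annotation$feature_id)
  groups <- list(
    activated = results$gene[results$call == "up"],
    unchanged = results$gene[results$call == "unchanged"],
    repressed = results$gene[results$call == "down"])
  lengths <- lapply(groups, function(g) unname(len_of[g]))
  pairs <- utils::combn(names(groups), 2)
  tests <- apply(pairs, 2, function(pr) {
    a <- lengths[[pr[1]]]; b <- lengths[[pr[2]]]
    if (length(a) == 0 || length(b) == 0) {
      return(data.frame(group1 = pr[1], group2 = pr[2],
                        n1 = length(a), n2 = length(b),
                        statistic = NA_real_, p_value = NA_real_,
                        method = "not-applicable", stringsAsFactors = FALSE))
    }
    exact <- length(a) <= 10 && length(b) <= 10
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact))
    p <- wt$p.value
    if (is.nan(p)) p <- 1  # fully tied groups carry no evidence
    data.frame(group1 = pr[1], group2 = pr[2], n1 = length(a),
               n2 = length(b), statistic = unname(wt$statistic),
               p_value = p,
               method = if (exact) "exact" else "normal-approx",
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  structure(list(lengths = lengths, tests = tests),
            class = "length_comparison")
}

#' @export
print.length_comparison <- function(x, ...) {
  cat("length_comparison: group medians (bp):",
      paste(sprintf("%s=%s", names(x$lengths),
                    vapply(x$lengths, function(v)
                      if (length(v)) format(stats::median(v)) else "-",
                      character(1))), collapse = ", "), "\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
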