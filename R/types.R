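#' @keywords internal
"_PACKAGE"

FEATURE_CLASSES <- c("rdna", "histone", "protein_coding", "spikein")

#' Construct a feature annotation table
#'
#' A feature annotation is a data frame with one row per feature and columns
#' `feature_id`, `chrom`, `start`, `end`, `strand`, `length_bp` and `class`.
#' Coordinates are 0-based half-open throughout the package (BED convention);
#' `length_bp` is the gene-body span `end - start`. Spike-in features need no
#' genomic location: their `chrom` may be a sentinel and their strand `"*"`.
#'
#' @param df data frame with columns `feature_id`, `chrom`, `start`, `end`,
#'   `strand`, `class` (`length_bp` is recomputed).
#' @return a `feature_annotation` data frame.
#' @export
feature_annotation <- function(df) {
  required <- c("feature_id", "chrom", "start", "end", "strand", "class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$feature_id <- as.character(df$feature_id)
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  df$class <- as.character(df$class)
  if (anyDuplicated(df$feature_id)) {
    dup <- df$feature_id[duplicated(df$feature_id)][1]
    stop("duplicate feature_id in annotation: '", dup, "'")
  }
  bad_class <- setdiff(unique(df$class), FEATURE_CLASSES)
  if (length(bad_class) > 0) {
    stop("unknown feature class: '", bad_class[1], "' (expected one of ",
         paste(FEATURE_CLASSES, collapse = ", "), ")")
  }
  if (any(!is.finite(df$start)) || any(!is.finite(df$end))) {
    stop("annotation coordinates must be finite")
  }
  bad <- which(df$end <= df$start)
  if (length(bad) > 0) {
    stop("feature '", df$feature_id[bad[1]], "' has end <= start")
  }
  bad_strand <- which(!(df$strand %in% c("+", "-")) & df$class != "spikein")
  if (length(bad_strand) > 0) {
    stop("feature '", df$feature_id[bad_strand[1]],
         "' has strand '", df$strand[bad_strand[1]],
         "'; strand must be '+' or '-' for non-spike-in features")
  }
  df$strand[df$class == "spikein" & !(df$strand %in% c("+", "-"))] <- "*"
  df$length_bp <- as.integer(df$end - df$start)
  rownames(df) <- df$feature_id
  df <- df[, c("feature_id", "chrom", "start", "end", "strand", "length_bp", "class")]
  class(df) <- c("feature_annotation", "data.frame")
  df
}

#' Construct a count matrix
#'
#' Raw integer counts, features x samples, with each feature carrying a class
#' label (`rdna`, `histone`, `protein_coding`, `spikein`) and each sample
#' optionally carrying a condition label. Spike-in rows are what anchors all
#' downstream normalization, so a matrix must contain at least one before
#' scale factors can be computed.
#'
#' @param counts integer matrix with feature rownames and sample colnames.
#' @param class_of named character vector mapping every feature to its class.
#' @param condition_of optional named character vector mapping samples to
#'   condition labels.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, class_of, condition_of = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at feature '", rownames(counts)[idx[1]],
         "', sample '", colnames(counts)[idx[2]], "'")
  }
  if (any(counts != round(counts))) {
    idx <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop("non-integer count at feature '", rownames(counts)[idx[1]],
         "', sample '", colnames(counts)[idx[2]], "'")
  }
  storage.mode(counts) <- "double"  # holds integers; avoids 32-bit overflow on sums
  missing_class <- setdiff(rownames(counts), names(class_of))
  if (length(missing_class) > 0) {
    stop("feature '", missing_class[1], "' has no class annotation")
  }
  cls <- class_of[rownames(counts)]
  bad_class <- setdiff(unique(cls), FEATURE_CLASSES)
  if (length(bad_class) > 0) {
    stop("unknown feature class: '", bad_class[1], "'")
  }
  if (!is.null(condition_of)) {
    missing_cond <- setdiff(colnames(counts), names(condition_of))
    if (length(missing_cond) > 0) {
      stop("sample '", missing_cond[1], "' has no condition label")
    }
    condition_of <- condition_of[colnames(counts)]
  }
  structure(
    list(counts = counts, class_of = cls, condition_of = condition_of),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$class_of)),
                                  table(x$class_of)), collapse = ", "), "\n")
  if (!is.null(x$condition_of)) {
    cat("  conditions:", paste(unique(x$condition_of), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

samples_of <- function(cm) colnames(cm$counts)
features_of <- function(cm) rownames(cm$counts)
spikein_rows <- function(cm) which(cm$class_of == "spikein")

#' Analysis configuration
#'
#' Bundles the thresholds and binning parameters shared across the pipeline.
#' Defaults follow the study design this package models: differential calls
#' at fold change > 1.5 and FDR < 0.05; screen hits at guide-level
#' adjusted p <= 0.01 and fold change >= 1.5; metagene flanks of 3 kb.
#'
#' @param fc_threshold minimum fold change for a differential call.
#' @param fdr_threshold BH-adjusted p-value cutoff for differential calls.
#' @param guide_padj_threshold adjusted p cutoff for a passing guide.
#' @param guide_fc_threshold minimum normalized fold change for a passing guide.
#' @param flank_bp metagene flank width in bp on each side of the gene body.
#' @param body_bins number of bins the gene body is rescaled to.
#' @param flank_bins number of fixed-width bins per flank.
#' @param pseudocount added to normalized pooled counts before fold change.
#' @param rng_seed default seed for simulation helpers.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(fc_threshold = 1.5,
                            fdr_threshold = 0.05,
                            guide_padj_threshold = 0.01,
                            guide_fc_threshold = 1.5,
                            flank_bp = 3000L,
                            body_bins = 100L,
                            flank_bins = 60L,
                            pseudocount = 1,
                            rng_seed = 1L) {
  stopifnot(fc_threshold > 0, fdr_threshold > 0, fdr_threshold < 1,
            guide_padj_threshold > 0, guide_fc_threshold > 0,
            flank_bp >= 0, body_bins >= 1, flank_bins >= 1,
            pseudocount >= 0)
  structure(
    list(fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
         guide_padj_threshold = guide_padj_threshold,
         guide_fc_threshold = guide_fc_threshold,
         flank_bp = as.integer(flank_bp), body_bins = as.integer(body_bins),
         flank_bins = as.integer(flank_bins), pseudocount = pseudocount,
         rng_seed = as.integer(rng_seed)),
    class = "analysis_config"
  )
}

#' Log a timestamped message to stderr
#'
#' @param ... message parts, pasted together.
#' @param level one of DEBUG, INFO, WARN.
#' @export
ns_log <- function(..., level = "INFO") {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3)
  min_level <- getOption("nascentshift.log_level", "INFO")
  if (levels[[level]] < levels[[min_level]]) return(invisible(NULL))
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...)))
  invisible(NULL)
}
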