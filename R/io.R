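#' Read a feature annotation file
#'
#' Two dialects are supported. `tsv`: a header line then six tab-separated
#' columns `feature_id chrom start end strand class`, with coordinates already
#' 0-based half-open. `gtf`: a standard 9-column GTF whose `gene` records are
#' used; 1-based inclusive coordinates are converted to 0-based half-open on
#' read, and classes come from `class_map` (GTF carries no class column).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gtf"`.
#' @param class_map named character vector feature_id -> class, consulted for
#'   GTF input (and allowed to override the TSV class column when given).
#' @param default_class class assigned to GTF genes absent from `class_map`;
#'   `NULL` (the default) makes an unmapped gene an error.
#' @return a [feature_annotation] data frame.
#' @export
read_annotation <- function(path, dialect = c("tsv", "gtf"),
                            class_map = NULL, default_class = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 1) stop("annotation file is empty: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1]]
    if (length(header) != 6) {
      stop("line 1: expected 6 tab-separated columns, found ", length(header))
    }
    body <- fields[-1]
    n_fields <- lengths(body)
    bad <- which(n_fields != 6)
    if (length(bad) > 0) {
      stop("line ", bad[1] + 1L, ": expected 6 tab-separated columns, found ",
           n_fields[bad[1]])
    }
    m <- do.call(rbind, body)
    start <- suppressWarnings(as.numeric(m[, 3]))
    end <- suppressWarnings(as.numeric(m[, 4]))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad) > 0) {
      stop("line ", bad[1] + 1L, ": non-numeric coordinate")
    }
    df <- data.frame(feature_id = m[, 1], chrom = m[, 2], start = start,
                     end = end, strand = m[, 5], class = m[, 6],
                     stringsAsFactors = FALSE)
    if (!is.null(class_map)) {
      hit <- df$feature_id %in% names(class_map)
      df$class[hit] <- class_map[df$feature_id[hit]]
    }
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GTF requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (length(gr) == 0) stop("no gene records found in GTF: ", path)
    ids <- gr$gene_id
    if (is.null(ids)) stop("GTF gene records carry no gene_id attribute")
    cls <- rep(NA_character_, length(ids))
    if (!is.null(class_map)) cls <- unname(class_map[ids])
    if (anyNA(cls)) {
      if (is.null(default_class)) {
        stop("no class for GTF gene '", ids[which(is.na(cls))[1]],
             "'; supply class_map or default_class")
      }
      cls[is.na(cls)] <- default_class
    }
    grd <- as.data.frame(gr)
    df <- data.frame(
      feature_id = ids,
      chrom = as.character(grd$seqnames),
      start = grd$start - 1L,  # 1-based inclusive -> 0-based half-open
      end = grd$end,
      strand = as.character(grd$strand),
      class = cls, stringsAsFactors = FALSE)
  }
  ann <- feature_annotation(df)
  ns_log("read ", nrow(ann), " features from ", path, " (", dialect, ")")
  ann
}

#' Write an annotation table as TSV
#' @param annotation a [feature_annotation].
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  df <- annotation[, c("feature_id", "chrom", "start", "end", "strand", "class")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample count table
#'
#' Expects a TSV whose header row names the samples and whose first column
#' holds feature ids; every feature must be covered by `annotation`. Row and
#' column order are preserved.
#'
#' @param path file path.
#' @param annotation a [feature_annotation] covering every feature row.
#' @param condition_of optional named character vector sample -> condition.
#' @return a [count_matrix].
#' @export
read_count_matrix <- function(path, annotation, condition_of = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("count table needs a feature_id column and >=1 sample")
  ids <- df[[1]]
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, names(df)[-1]))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric count at feature '", ids[idx[1]], "', sample '",
         colnames(vals)[idx[2]], "'")
  }
  missing <- setdiff(ids, annotation$feature_id)
  if (length(missing) > 0) {
    stop("feature '", missing[1], "' in count table has no annotation")
  }
  cls <- stats::setNames(annotation$class, annotation$feature_id)
  cm <- count_matrix(vals, cls, condition_of)
  ns_log("read counts: ", nrow(vals), " features x ", ncol(vals),
         " samples from ", path)
  cm
}

#' Write a count or normalized matrix as TSV
#' @param x a [count_matrix], `normalized_matrix`, or plain matrix.
#' @param path output path.
#' @export
write_count_matrix <- function(x, path) {
  m <- if (is.matrix(x)) x else if (!is.null(x$counts)) x$counts else x$values
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_results_table(df, path)
}

#' Write a results table with fixed float precision
#'
#' Writes a header even for zero rows; numeric columns are rendered at 6
#' significant digits so that write/read round-trips reproduce values to that
#' precision and diffs are stable across platforms.
#'
#' @param records a data frame (or list of identically named lists).
#' @param path output path.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  df <- as.data.frame(records)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), NA,
                        formatC(signif(df[[j]], 6), format = "g", digits = 6))
    }
  }
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_results_table]
#' @param path file path.
#' @return data frame with types re-inferred.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Construct a coverage track from bedGraph-style intervals
#'
#' Intervals are 0-based half-open; overlapping intervals are an error and
#' any base not covered by an interval reads as 0. Coverage is held as a
#' run-length-encoded vector per chromosome.
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `value`.
#' @return a `coverage_track`.
#' @export
coverage_track <- function(df) {
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  if (nrow(df) > 0) {
    if (any(!is.finite(df$value))) stop("non-finite coverage value")
    if (any(df$value < 0)) {
      stop("negative coverage value at ", df$chrom[df$value < 0][1], ":",
           df$start[df$value < 0][1])
    }
    if (any(df$end <= df$start)) stop("bedGraph interval with end <= start")
  }
  cov <- list()
  for (chrom in unique(df$chrom)) {
    sub <- df[df$chrom == chrom, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    if (sum(IRanges::width(ir)) != sum(IRanges::width(IRanges::reduce(ir)))) {
      stop("overlapping bedGraph intervals on ", chrom)
    }
    cov[[chrom]] <- IRanges::coverage(ir, weight = sub$value)
  }
  structure(list(cov = cov), class = "coverage_track")
}

#' Read a 4-column bedGraph file
#' @param path file path.
#' @return a [coverage_track]; an empty file yields all-zero coverage.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(structure(list(cov = list()), class = "coverage_track"))
  }
  fields <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(fields) != 4)
  if (length(bad) > 0) {
    stop("bedGraph line ", bad[1], ": expected 4 columns, found ",
         lengths(fields)[bad[1]])
  }
  m <- do.call(rbind, fields)
  df <- data.frame(chrom = m[, 1],
                   start = as.numeric(m[, 2]),
                   end = as.numeric(m[, 3]),
                   value = as.numeric(m[, 4]),
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value)) {
    stop("bedGraph contains a non-numeric coordinate or value")
  }
  coverage_track(df)
}

#' Write a coverage data frame as bedGraph
#' @param df data frame with columns `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @export
write_bedgraph <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Per-base coverage over a 0-based half-open window
#'
#' Bases outside any recorded interval (including beyond the last covered
#' base or on an unseen chromosome) read as 0.
#'
#' @param track a [coverage_track].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window.
#' @return numeric vector of length `end - start`.
#' @export
coverage_vector <- function(track, chrom, start, end) {
  n <- end - start
  if (n < 0) stop("end < start")
  out <- numeric(n)
  rle <- track$cov[[chrom]]
  if (is.null(rle)) return(out)
  len <- length(rle)
  lo <- max(start, 0)            # clip to the recorded extent
  hi <- min(end, len)
  if (hi > lo) {
    out[(lo - start + 1):(hi - start)] <-
      as.numeric(S4Vectors::window(rle, start = lo + 1L, end = hi))
  }
  out
}

#' Read a guide library table
#'
#' TSV with header and columns `guide_id`, `gene`, `sequence` (20-nt).
#'
#' @param path file path.
#' @return a `guide_library` data frame.
#' @export
read_guide_library <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  guide_library(df)
}

#' Construct a guide library
#' @param df data frame with columns `guide_id`, `gene`, `sequence`.
#' @return a `guide_library` data frame.
#' @export
guide_library <- function(df) {
  required <- c("guide_id", "gene", "sequence")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("guide library is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)[, required]
  df$sequence <- toupper(df$sequence)
  if (anyDuplicated(df$guide_id)) stop("duplicate guide_id in library")
  if (anyDuplicated(df$sequence)) stop("duplicate guide sequence in library")
  if (any(nchar(df$sequence) != 20)) {
    stop("guide '", df$guide_id[nchar(df$sequence) != 20][1],
         "' has a sequence that is not 20 nt")
  }
  if (any(grepl("[^ACGT]", df$sequence))) stop("guide sequence with non-ACGT base")
  class(df) <- c("guide_library", "data.frame")
  df
}
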