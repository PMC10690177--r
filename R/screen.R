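#' Extract guide counts from screen sequencing reads
#'
#' Each read is scanned for the first exact occurrence of `anchor5`; the 20 nt
#' that follow are the candidate guide and must be followed immediately by an
#' exact `anchor3`. Candidates are matched exactly against the library
#' (no mismatch tolerance: mismatch handling would change counts silently);
#' every read that fails any step counts as unassigned.
#'
#' @param reads path to a FASTQ file, or a character vector of read sequences.
#' @param library a [guide_library].
#' @param anchor5,anchor3 non-empty anchor sequences flanking the guide.
#' @return a `guide_pop_counts`: list with `counts` (named integer vector over
#'   all library guides, zeros included), `unassigned`, `total`.
#' @export
extract_guides <- function(reads, library, anchor5, anchor3) {
  if (!nzchar(anchor5) || !nzchar(anchor3)) stop("anchors must be non-empty")
  if (length(reads) == 1 && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  reads <- toupper(as.character(reads))
  anchor5 <- toupper(anchor5); anchor3 <- toupper(anchor3)
  n5 <- nchar(anchor5); n3 <- nchar(anchor3)
  pos <- regexpr(anchor5, reads, fixed = TRUE)
  guide_start <- pos + n5
  candidate <- substr(reads, guide_start, guide_start + 19L)
  after <- substr(reads, guide_start + 20L, guide_start + 20L + n3 - 1L)
  ok <- pos > 0 & nchar(candidate) == 20L & after == anchor3
  idx <- match(candidate[ok], library$sequence)
  assigned <- idx[!is.na(idx)]
  counts <- integer(nrow(library))
  names(counts) <- library$guide_id
  if (length(assigned) > 0) {
    tab <- tabulate(assigned, nbins = nrow(library))
    counts[] <- tab
  }
  unassigned <- length(reads) - length(assigned)
  structure(list(counts = counts, unassigned = unassigned,
                 total = sum(counts)),
            class = "guide_pop_counts")
}

#' Combine unsorted and sorted guide counts
#'
#' @param unsorted,sorted `guide_pop_counts` (from [extract_guides] or
#'   simulation) or named integer vectors over the same guides.
#' @return a `guide_counts` data frame: `guide_id`, `raw_unsorted`,
#'   `raw_sorted`, with per-population totals and unassigned tallies as
#'   attributes.
#' @export
guide_counts <- function(unsorted, sorted) {
  get <- function(x) if (inherits(x, "guide_pop_counts")) x$counts else x
  u <- get(unsorted); s <- get(sorted)
  if (!identical(names(u), names(s))) {
    s <- s[names(u)]
    if (anyNA(s)) stop("sorted and unsorted populations cover different guides")
  }
  df <- data.frame(guide_id = names(u), raw_unsorted = as.integer(u),
                   raw_sorted = as.integer(s), stringsAsFactors = FALSE)
  attr(df, "unassigned") <- c(
    unsorted = if (inherits(unsorted, "guide_pop_counts")) unsorted$unassigned else 0L,
    sorted = if (inherits(sorted, "guide_pop_counts")) sorted$unassigned else 0L)
  class(df) <- c("guide_counts", "data.frame")
  df
}

#' Normalized reads per guide
#'
#' `normalized = raw / total * 1e6 + 1`: reads-per-million with a +1 floor, so
#' an unobserved guide gets 1 and ratios stay finite.
#'
#' @param raw integer vector of raw guide counts for one population.
#' @param total population total; defaults to `sum(raw)`.
#' @return numeric vector of normalized abundances (all >= 1).
#' @export
normalize_guide_counts <- function(raw, total = sum(raw)) {
  if (any(raw < 0)) stop("negative guide count")
  if (total <= 0) stop("population total must be > 0")
  raw / total * 1e6 + 1
}

#' Score guide enrichment in the sorted population
#'
#' For each guide: normalized abundances in both populations, fold change
#' `norm_sorted / norm_unsorted`, `crispr_score = log2(fold change)`, a
#' one-tail exact Poisson p-value for enrichment in the sorted population
#' (raw counts, population totals as exposures — the same conditional
#' binomial machinery as the expression tests), and BH adjustment across all
#' guides jointly.
#'
#' @param counts a `guide_counts` data frame (see [guide_counts]).
#' @return a `guide_enrichment` data frame: `guide_id`, `raw_unsorted`,
#'   `raw_sorted`, `norm_unsorted`, `norm_sorted`, `fc`, `crispr_score`,
#'   `p_value`, `padj`.
#' @export
score_guides <- function(counts) {
  tot_u <- sum(counts$raw_unsorted)
  tot_s <- sum(counts$raw_sorted)
  norm_u <- normalize_guide_counts(counts$raw_unsorted, tot_u)
  norm_s <- normalize_guide_counts(counts$raw_sorted, tot_s)
  fc <- norm_s / norm_u
  p <- poisson_two_sample_test(counts$raw_unsorted, counts$raw_sorted,
                               s_ref = tot_u, s_alt = tot_s,
                               tail = "greater")
  out <- data.frame(guide_id = counts$guide_id,
                    raw_unsorted = counts$raw_unsorted,
                    raw_sorted = counts$raw_sorted,
                    norm_unsorted = norm_u, norm_sorted = norm_s,
                    fc = fc, crispr_score = log2(fc),
                    p_value = p, padj = bh_fdr(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("guide_enrichment", "data.frame")
  out
}

#' Gene-level hit calling from guide enrichments
#'
#' A guide passes when `padj <= guide_padj_threshold` and
#' `fc >= guide_fc_threshold`; a gene is a hit when at least one of its
#' guides passes. Reports per gene the number of passing guides, the
#' smallest adjusted p and the largest fold change among its guides.
#'
#' @param enrichments a `guide_enrichment` from [score_guides].
#' @param library a [guide_library] mapping guides to genes.
#' @param cfg an [analysis_config].
#' @return a `gene_hits` data frame: `gene`, `n_guides`, `n_guides_passing`,
#'   `best_padj`, `best_fc`, `is_hit`, sorted by `best_padj`.
#' @export
call_hit_genes <- function(enrichments, library, cfg = analysis_config()) {
  gene_of <- stats::setNames(library$gene, library$guide_id)
  missing <- setdiff(enrichments$guide_id, names(gene_of))
  if (length(missing) > 0) {
    stop("guide '", missing[1], "' has no gene in the library")
  }
  gene <- unname(gene_of[enrichments$guide_id])
  pass <- enrichments$padj <= cfg$guide_padj_threshold &
    enrichments$fc >= cfg$guide_fc_threshold
  sp <- split(seq_len(nrow(enrichments)), gene)
  out <- data.frame(
    gene = names(sp),
    n_guides = lengths(sp),
    n_guides_passing = vapply(sp, function(i) sum(pass[i]), integer(1)),
    best_padj = vapply(sp, function(i) min(enrichments$padj[i]), numeric(1)),
    best_fc = vapply(sp, function(i) max(enrichments$fc[i]), numeric(1)),
    stringsAsFactors = FALSE)
  out$is_hit <- out$n_guides_passing >= 1
  out <- out[order(out$best_padj, -out$best_fc, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("gene_hits", "data.frame")
  ns_log("call_hit_genes: ", sum(out$is_hit), " hit genes of ", nrow(out))
  out
}
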