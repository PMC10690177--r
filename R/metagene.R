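#' Scale a coverage track
#'
#' Multiplies every base's coverage by a spike-in-derived scale factor, the
#' track-level counterpart of [normalize_counts].
#'
#' @param track a [coverage_track].
#' @param factor positive multiplier.
#' @return a scaled [coverage_track].
#' @export
scale_coverage <- function(track, factor) {
  if (factor <= 0) stop("scale factor must be > 0")
  track$cov <- lapply(track$cov, function(rle) rle * factor)
  track
}

#' Average metagene coverage profile
#'
#' For each gene, the body is rescaled to `body_bins` bins (per-base coverage
#' averaged within each bin; base i of an L-bp body lands in bin
#' `floor(i * body_bins / L)`, a deterministic rule) and each flank is cut
#' into `flank_bins` fixed-width bins of `flank_bp / flank_bins` bp. Minus-
#' strand genes are reversed so bin 1 is always the 5' flank end. The profile
#' is the unweighted mean across genes per bin (each gene contributes
#' equally). Genes shorter than `body_bins` bp are skipped with a warning and
#' counted in `n_skipped`.
#'
#' @param track a [coverage_track].
#' @param genes a [feature_annotation] subset (non-spike-in, stranded).
#' @param flank_bp flank width in bp on each side (default 3000).
#' @param body_bins bins the body is rescaled to (default 100).
#' @param flank_bins fixed-width bins per flank (default 60, i.e. 50 bp).
#' @param label free-text label carried on the profile.
#' @return a `metagene_profile`: `values` (length `2*flank_bins+body_bins`),
#'   `bin_type` (`flank5`/`body`/`flank3` per bin), `n_genes`, `n_skipped`.
#' @export
build_metagene <- function(track, genes, flank_bp = 3000L, body_bins = 100L,
                           flank_bins = 60L, label = "") {
  stopifnot(body_bins >= 1, flank_bins >= 1, flank_bp >= 0)
  if (flank_bp %% flank_bins != 0) {
    stop("flank_bp must be divisible by flank_bins")
  }
  genes <- genes[genes$class != "spikein", , drop = FALSE]
  if (nrow(genes) == 0) stop("no genes to profile")
  if (any(!(genes$strand %in% c("+", "-")))) {
    stop("metagene genes must have strand '+' or '-'")
  }
  fw <- flank_bp %/% flank_bins
  n_bins <- 2L * flank_bins + body_bins
  acc <- numeric(n_bins)
  used <- 0L; skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    L <- g$length_bp
    if (L < body_bins) {
      ns_log("build_metagene: skipping '", g$feature_id, "' (", L,
             " bp < ", body_bins, " bins)", level = "WARN")
      skipped <- skipped + 1L
      next
    }
    win <- coverage_vector(track, g$chrom, g$start - flank_bp,
                           g$end + flank_bp)
    if (g$strand == "-") win <- rev(win)  # bin 1 is always 5'
    flank5 <- win[seq_len(flank_bp)]
    body <- win[flank_bp + seq_len(L)]
    flank3 <- win[flank_bp + L + seq_len(flank_bp)]
    body_bin <- floor((seq_len(L) - 1) * body_bins / L) + 1L
    prof <- c(
      if (flank_bp > 0) rowsum(flank5, rep(seq_len(flank_bins), each = fw)) / fw
      else numeric(flank_bins),
      rowsum(body, body_bin) / tabulate(body_bin, body_bins),
      if (flank_bp > 0) rowsum(flank3, rep(seq_len(flank_bins), each = fw)) / fw
      else numeric(flank_bins))
    acc <- acc + prof
    used <- used + 1L
  }
  if (used == 0) stop("all genes were shorter than body_bins")
  structure(
    list(values = acc / used,
         bin_type = rep(c("flank5", "body", "flank3"),
                        times = c(flank_bins, body_bins, flank_bins)),
         flank_bp = flank_bp, body_bins = body_bins, flank_bins = flank_bins,
         n_genes = used, n_skipped = skipped, label = label),
    class = "metagene_profile"
  )
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile", if (nzchar(x$label)) paste0("'", x$label, "'"),
      ":", x$n_genes, "genes (", x$n_skipped, "skipped ),",
      x$body_bins, "body bins +", x$flank_bins, "x2 flank bins\n")
  body <- x$values[x$bin_type == "body"]
  cat("  body coverage: mean", signif(mean(body), 4),
      "range [", signif(min(body), 4), ",", signif(max(body), 4), "]\n")
  invisible(x)
}

body_values <- function(profile) profile$values[profile$bin_type == "body"]

#' 5'/3' body-coverage ratio between conditions
#'
#' Per profile, `r5` is the mean of the first half of the body bins and `r3`
#' the mean of the last half (the middle bin of an odd split belongs to
#' neither). The cross-condition statistic is
#' `(alt r5/r3) / (ref r5/r3)`: a value near 1 means the perturbed
#' condition lost coverage uniformly along the body — repression at the
#' initiation stage — while a value above 1 means the loss was 3'-biased,
#' as elongation-level repression would produce.
#'
#' @param profile_ref,profile_alt `metagene_profile`s with identical binning.
#' @param window fraction of the body taken as each end's window
#'   (default 0.5: the half-split).
#' @return a `five_three_ratio`: per-condition `r5`, `r3` and `ratio`, and
#'   `ratio_of_ratios`.
#' @export
five_three_ratio <- function(profile_ref, profile_alt, window = 0.5) {
  stopifnot(window > 0, window <= 0.5)
  if (profile_ref$body_bins != profile_alt$body_bins) {
    stop("profiles have different body binning")
  }
  one <- function(p) {
    body <- body_values(p)
    k <- floor(length(body) * window)
    if (k < 1) stop("body window too small")
    r5 <- mean(body[seq_len(k)])
    r3 <- mean(body[(length(body) - k + 1):length(body)])
    if (r3 == 0) stop("3' body coverage is zero; ratio undefined")
    c(r5 = r5, r3 = r3, ratio = r5 / r3)
  }
  ref <- one(profile_ref); alt <- one(profile_alt)
  structure(
    list(r5_ref = ref[["r5"]], r3_ref = ref[["r3"]], ratio_ref = ref[["ratio"]],
         r5_alt = alt[["r5"]], r3_alt = alt[["r3"]], ratio_alt = alt[["ratio"]],
         ratio_of_ratios = alt[["ratio"]] / ref[["ratio"]]),
    class = "five_three_ratio"
  )
}

#' @export
print.five_three_ratio <- function(x, ...) {
  cat("five_three_ratio: ref r5/r3 =", signif(x$ratio_ref, 4),
      ", alt r5/r3 =", signif(x$ratio_alt, 4),
      ", ratio-of-ratios =", signif(x$ratio_of_ratios, 4), "\n")
  cat(if (abs(log(x$ratio_of_ratios)) < 0.1)
    "  (body-uniform change: initiation-level signature)\n"
    else "  (3'-biased change: elongation-level signature)\n")
  invisible(x)
}
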