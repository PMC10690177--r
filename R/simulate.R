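#' Configuration for the nascent-experiment simulator
#'
#' Defaults mirror the experimental design the analysis assumes: two
#' conditions (reference `ctrl`, perturbed `ir`) with two replicates each,
#' 92 spike-in species held biologically constant, a small set of very
#' highly transcribed rDNA-like features (100x the protein-coding baseline),
#' histone-like genes at an intermediate 10x baseline, and a global
#' perturbation that halves rDNA/histone output while a subset of
#' protein-coding genes is up-regulated. Per-gene baselines are drawn
#' log-uniformly within a class (spread `baseline_spread`) so an expression
#' ranking exists.
#'
#' @param n_protein_coding,n_histone,n_rdna,n_spikein feature counts per class.
#' @param baseline_mean_by_class named vector of expected reference-condition
#'   counts per feature class.
#' @param rdna_fraction_target optional target share of non-spike-in reads
#'   from the rdna class; when set, rdna baselines are rescaled to hit it in
#'   expectation.
#' @param global_shift named vector of per-class mean multipliers applied in
#'   the perturbed condition (spike-ins are always biologically unshifted).
#' @param frac_upregulated fraction of protein-coding genes given an extra
#'   up-regulation in the perturbed condition.
#' @param up_fc fold change of those up-regulated genes.
#' @param frac_downregulated fraction of protein-coding genes given an extra
#'   down-regulation (disjoint from the up-regulated set; default 0).
#' @param down_fc fold change of those down-regulated genes.
#' @param n_replicates replicates per condition.
#' @param depth_factor_by_sample optional named per-sample depth multipliers
#'   (sequencing depth, experienced by spike-ins and genes alike); default 1.
#' @param baseline_spread log-uniform half-range factor for per-gene baselines.
#' @param nb_size optional negative-binomial size parameter; `NULL` (default)
#'   keeps pure Poisson noise, matching the downstream tests' assumed model.
#' @param rng_seed integer seed; identical seeds give identical output.
#' @return a `nascent_sim_config` list.
#' @export
nascent_sim_config <- function(n_protein_coding = 2000L,
                               n_histone = 50L,
                               n_rdna = 20L,
                               n_spikein = 92L,
                               baseline_mean_by_class = c(
                                 rdna = 5000, histone = 500,
                                 protein_coding = 50, spikein = 100),
                               rdna_fraction_target = NULL,
                               global_shift = c(rdna = 0.5, histone = 0.5,
                                                protein_coding = 1,
                                                spikein = 1),
                               frac_upregulated = 0.15,
                               up_fc = 2,
                               frac_downregulated = 0,
                               down_fc = 0.5,
                               n_replicates = 2L,
                               depth_factor_by_sample = NULL,
                               baseline_spread = 10,
                               nb_size = NULL,
                               rng_seed = 1L) {
  stopifnot(n_protein_coding >= 0, n_histone >= 0, n_rdna >= 0,
            n_spikein >= 1, n_replicates >= 1,
            all(baseline_mean_by_class > 0), all(global_shift > 0),
            frac_upregulated >= 0, frac_upregulated <= 1, up_fc > 0,
            frac_downregulated >= 0, frac_upregulated + frac_downregulated <= 1,
            down_fc > 0, baseline_spread >= 1)
  if (!is.null(rdna_fraction_target)) {
    stopifnot(rdna_fraction_target > 0, rdna_fraction_target < 1)
  }
  if (!is.null(depth_factor_by_sample) && any(depth_factor_by_sample <= 0)) {
    stop("depth factors must be > 0")
  }
  structure(
    list(n_protein_coding = as.integer(n_protein_coding),
         n_histone = as.integer(n_histone), n_rdna = as.integer(n_rdna),
         n_spikein = as.integer(n_spikein),
         baseline_mean_by_class = baseline_mean_by_class,
         rdna_fraction_target = rdna_fraction_target,
         global_shift = global_shift,
         frac_upregulated = frac_upregulated, up_fc = up_fc,
         frac_downregulated = frac_downregulated, down_fc = down_fc,
         n_replicates = as.integer(n_replicates),
         depth_factor_by_sample = depth_factor_by_sample,
         baseline_spread = baseline_spread, nb_size = nb_size,
         rng_seed = as.integer(rng_seed)),
    class = "nascent_sim_config"
  )
}

# stable sub-seed per simulated artifact, so adding a generator call does
# not perturb earlier outputs; double arithmetic is exact here and the
# result stays below 2^31
.subseed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + stream * 12347) %% 2147483629)
}

#' Simulate a two-condition nascent-transcript count matrix
#'
#' Each count is Poisson (optionally negative-binomial) with mean
#' `baseline(gene) x fold_change(gene, condition) x depth_factor(sample)`.
#' Spike-in means are condition-independent — spike-ins experience
#' sequencing depth, never biology — which is exactly what makes them the
#' normalization anchor. The perturbed condition applies the class-level
#' `global_shift`, and a `frac_upregulated` subset of protein-coding genes
#' additionally gets `up_fc`.
#'
#' @param cfg a [nascent_sim_config].
#' @return list with `counts` (a [count_matrix], conditions attached),
#'   `annotation` (a [feature_annotation] with plausible gene bodies), and
#'   `truth`: `class_of`, `fc_of` (biological fold change per feature),
#'   `upregulated`/`downregulated` (gene ids), `baseline` (per-gene
#'   reference mean).
#' @export
simulate_nascent_experiment <- function(cfg = nascent_sim_config()) {
  withr::with_seed(.subseed(cfg$rng_seed, 1L), {
    n_by_class <- c(rdna = cfg$n_rdna, histone = cfg$n_histone,
                    protein_coding = cfg$n_protein_coding,
                    spikein = cfg$n_spikein)
    ids <- unlist(lapply(names(n_by_class), function(cl) {
      prefix <- c(rdna = "rDNA", histone = "Hist", protein_coding = "Gene",
                  spikein = "ERCC")[[cl]]
      if (n_by_class[[cl]] == 0) return(character(0))
      sprintf("%s-%05d", prefix, seq_len(n_by_class[[cl]]))
    }))
    cls <- rep(names(n_by_class), times = n_by_class)
    names(cls) <- ids

    spread <- log(cfg$baseline_spread)
    baseline <- cfg$baseline_mean_by_class[cls] *
      exp(stats::runif(length(ids), -spread, spread))
    names(baseline) <- ids
    if (!is.null(cfg$rdna_fraction_target)) {
      is_r <- cls == "rdna"
      other <- sum(baseline[!is_r & cls != "spikein"])
      target <- cfg$rdna_fraction_target
      baseline[is_r] <- baseline[is_r] *
        (target / (1 - target)) * other / sum(baseline[is_r])
    }

    fc <- cfg$global_shift[cls]
    fc[cls == "spikein"] <- 1
    names(fc) <- ids
    n_up <- round(cfg$frac_upregulated * cfg$n_protein_coding)
    n_down <- round(cfg$frac_downregulated * cfg$n_protein_coding)
    pc_ids <- ids[cls == "protein_coding"]
    picked <- sample(pc_ids, n_up + n_down)
    up_genes <- picked[seq_len(n_up)]
    down_genes <- picked[n_up + seq_len(n_down)]
    fc[up_genes] <- fc[up_genes] * cfg$up_fc
    fc[down_genes] <- fc[down_genes] * cfg$down_fc

    samples <- c(paste0("ctrl_rep", seq_len(cfg$n_replicates)),
                 paste0("ir_rep", seq_len(cfg$n_replicates)))
    condition <- stats::setNames(rep(c("ctrl", "ir"), each = cfg$n_replicates),
                                 samples)
    depth <- rep(1, length(samples)); names(depth) <- samples
    if (!is.null(cfg$depth_factor_by_sample)) {
      missing <- setdiff(samples, names(cfg$depth_factor_by_sample))
      if (length(missing) > 0) stop("no depth factor for sample ", missing[1])
      depth <- cfg$depth_factor_by_sample[samples]
    }

    mu <- outer(baseline, depth) *
      ifelse(rep(condition, each = length(ids)) == "ir", rep(fc, length(samples)), 1)
    dim(mu) <- c(length(ids), length(samples))
    dimnames(mu) <- list(ids, samples)
    draw <- if (is.null(cfg$nb_size)) {
      function(m) stats::rpois(length(m), m)
    } else {
      function(m) stats::rnbinom(length(m), size = cfg$nb_size, mu = m)
    }
    counts <- matrix(draw(mu), nrow = length(ids),
                     dimnames = dimnames(mu))

    # gene bodies laid out head-to-tail on one synthetic chromosome; length
    # distributions are class-realistic: rDNA repeat units ~13 kb, histone
    # genes short (~0.6 kb, intronless), protein-coding genes broad around
    # 2.5 kb, spike-in species sub-2 kb
    len_meanlog <- c(rdna = log(13000), histone = log(600),
                     protein_coding = log(2500), spikein = log(1000))[cls]
    len_sdlog <- c(rdna = 0.1, histone = 0.2, protein_coding = 0.8,
                   spikein = 0.3)[cls]
    body_len <- pmax(200L, as.integer(round(
      stats::rlnorm(length(ids), meanlog = len_meanlog, sdlog = len_sdlog))))
    starts <- cumsum(c(0, utils::head(body_len, -1) + 1000L))
    ann <- feature_annotation(data.frame(
      feature_id = ids, chrom = ifelse(cls == "spikein", "spike", "chrS"),
      start = starts, end = starts + body_len,
      strand = ifelse(cls == "spikein", "*",
                      rep_len(c("+", "-"), length(ids))),
      class = cls, stringsAsFactors = FALSE))

    list(counts = count_matrix(counts, cls, condition),
         annotation = ann,
         truth = list(class_of = cls, fc_of = fc,
                      upregulated = sort(up_genes),
                      downregulated = sort(down_genes), baseline = baseline,
                      depth_factor = depth))
  })
}

#' Simulate gene-body coverage tracks
#'
#' Produces bedGraph-style coverage over each annotated gene body, per
#' condition. `uniform` covers every body base at `level`; `ramp_5to3`
#' decreases linearly from `level` at the 5' end toward 0 at the 3' end in
#' transcription orientation (so on a minus-strand gene the genomic
#' left-to-right coverage increases). Each condition's factor multiplies the
#' whole body.
#'
#' @param annotation a [feature_annotation]; spike-ins are skipped.
#' @param shape `"uniform"` or `"ramp_5to3"`.
#' @param level positive per-base coverage at the 5' end.
#' @param condition_factors named vector of body-wide multipliers, one track
#'   per entry (default `c(ctrl = 1, ir = 1)`).
#' @return named list of data frames (`chrom`, `start`, `end`, `value`), one
#'   per condition, consumable by [coverage_track] or [write_bedgraph].
#' @export
simulate_coverage <- function(annotation, shape = c("uniform", "ramp_5to3"),
                              level, condition_factors = c(ctrl = 1, ir = 1)) {
  shape <- match.arg(shape)
  if (level <= 0) stop("level must be > 0")
  if (any(condition_factors <= 0)) stop("condition factors must be > 0")
  genes <- annotation[annotation$class != "spikein", , drop = FALSE]
  base <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (shape == "uniform") {
      data.frame(chrom = g$chrom, start = g$start, end = g$end,
                 value = level, stringsAsFactors = FALSE)
    } else {
      L <- g$length_bp
      pos5_offset <- seq_len(L) - 1L           # distance from 5' end, per base
      value <- level * (L - pos5_offset) / L
      if (g$strand == "-") value <- rev(value) # genomic left-to-right
      data.frame(chrom = g$chrom, start = g$start + seq_len(L) - 1L,
                 end = g$start + seq_len(L), value = value,
                 stringsAsFactors = FALSE)
    }
  }))
  lapply(condition_factors, function(f) {
    out <- base
    out$value <- out$value * f
    out
  })
}

#' Simulate a FACS-sorted pooled CRISPR screen
#'
#' Generates a guide library (unique random 20-mers, `guides_per_gene` per
#' gene) with a log-normal library skew, Poisson unsorted counts at
#' `depth_unsorted`, and sorted counts Poisson around the true relative
#' abundance reweighted by each guide's programmed fold change (regulator
#' guides get `regulator_guide_fc` on `guides_affected_per_regulator` of
#' their guides, all others 1) and renormalized to `depth_sorted`.
#'
#' @param n_genes number of genes in the library.
#' @param guides_per_gene guides per gene (study library: 5).
#' @param n_regulators number of true regulator genes.
#' @param regulator_guide_fc enrichment fold change of affected guides.
#' @param guides_affected_per_regulator how many of a regulator's guides
#'   carry the enrichment (the rest behave as null; real knockouts rarely
#'   work through every guide).
#' @param depth_unsorted,depth_sorted expected total reads per population.
#' @param skew_sdlog log-normal sdlog of the library skew.
#' @param seed integer seed.
#' @return list with `library` (a [guide_library]), `counts` (a
#'   `guide_counts` data frame), and `truth`: `regulators` (gene ids),
#'   `guide_fc` (named per-guide programmed fold change).
#' @export
simulate_screen <- function(n_genes = 2000L, guides_per_gene = 5L,
                            n_regulators = 20L, regulator_guide_fc = 4,
                            guides_affected_per_regulator = 3L,
                            depth_unsorted = 1e6, depth_sorted = 1e6,
                            skew_sdlog = 0.5, seed = 1L) {
  if (guides_affected_per_regulator > guides_per_gene) {
    stop("guides_affected_per_regulator exceeds guides_per_gene")
  }
  stopifnot(n_genes >= 1, guides_per_gene >= 1, n_regulators >= 0,
            n_regulators <= n_genes, regulator_guide_fc > 0,
            depth_unsorted > 0, depth_sorted > 0)
  withr::with_seed(.subseed(seed, 2L), {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    guide_gene <- rep(genes, each = guides_per_gene)
    guide_id <- paste0(guide_gene, "_g", rep(seq_len(guides_per_gene), n_genes))
    n_guides <- length(guide_id)
    repeat {
      seqs <- vapply(seq_len(n_guides), function(i)
        paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
              collapse = ""), character(1))
      if (!anyDuplicated(seqs)) break
    }
    lib <- guide_library(data.frame(guide_id = guide_id, gene = guide_gene,
                                    sequence = seqs, stringsAsFactors = FALSE))

    regulators <- sort(sample(genes, n_regulators))
    guide_fc <- rep(1, n_guides); names(guide_fc) <- guide_id
    for (g in regulators) {
      own <- guide_id[guide_gene == g]
      affected <- sample(own, guides_affected_per_regulator)
      guide_fc[affected] <- regulator_guide_fc
    }

    skew <- stats::rlnorm(n_guides, meanlog = 0, sdlog = skew_sdlog)
    rel_unsorted <- skew / sum(skew)
    rel_sorted <- rel_unsorted * guide_fc
    rel_sorted <- rel_sorted / sum(rel_sorted)
    raw_unsorted <- stats::rpois(n_guides, depth_unsorted * rel_unsorted)
    raw_sorted <- stats::rpois(n_guides, depth_sorted * rel_sorted)
    names(raw_unsorted) <- names(raw_sorted) <- guide_id

    list(library = lib,
         counts = guide_counts(raw_unsorted, raw_sorted),
         truth = list(regulators = regulators, guide_fc = guide_fc))
  })
}

#' Emit FASTQ reads realizing a guide count table
#'
#' Writes one read per counted guide instance: `anchor5 + 20-nt guide +
#' anchor3 + random filler` padded to `read_length`, order shuffled by the
#' seed, constant quality. Round-tripping through [extract_guides] with the
#' same anchors reproduces the input table exactly.
#'
#' @param counts named integer vector of per-guide read counts.
#' @param library a [guide_library]; every counted guide must be present.
#' @param anchor5,anchor3 anchor sequences to embed.
#' @param path output FASTQ path.
#' @param read_length total read length (filler-padded; minimum the construct
#'   length).
#' @param seed integer seed for the shuffle and filler.
#' @return `path`, invisibly.
#' @export
simulate_guide_fastq <- function(counts, library, anchor5, anchor3, path,
                                 read_length = 75L, seed = 1L) {
  missing <- setdiff(names(counts)[counts > 0], library$guide_id)
  if (length(missing) > 0) {
    stop("guide '", missing[1], "' absent from library")
  }
  withr::with_seed(.subseed(seed, 3L), {
    seq_of <- stats::setNames(library$sequence, library$guide_id)
    counts <- counts[counts > 0]
    ids <- rep(names(counts), times = counts)
    if (length(ids) > 0) ids <- sample(ids)
    construct <- paste0(anchor5, seq_of[ids], anchor3)
    pad <- read_length - (nchar(anchor5) + nchar(anchor3) + 20L)
    filler <- if (length(ids) > 0 && pad > 0) {
      # filler drawn from a pool of random sequences: content is irrelevant
      # to extraction, sampling a pool keeps generation fast at depth 1e6+
      pool <- vapply(seq_len(256), function(i)
        paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
              collapse = ""), character(1))
      pool[sample.int(256, length(ids), replace = TRUE)]
    } else ""
    reads <- paste0(construct, filler)
    con <- file(path, "w")
    on.exit(close(con))
    if (length(ids) > 0) {
      qual <- strrep("I", nchar(reads))
      writeLines(paste0("@read", seq_along(ids), "\n", reads, "\n+\n", qual),
                 con)
    }
  })
  invisible(path)
}
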