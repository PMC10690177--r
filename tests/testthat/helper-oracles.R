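# Independent oracles and small fixture builders, kept deliberately naive:
# they must not share machinery with the implementation they check.

# Binomial tail probability by explicit log-space term summation.
binom_tail_oracle <- function(x_alt, n, p0, tail) {
  if (n == 0) return(1)
  ks <- if (tail == "greater") x_alt:n else 0:x_alt
  ks <- ks[ks >= 0 & ks <= n]
  if (length(ks) == 0) return(if (tail == "greater") 0 else stop("bad range"))
  sum(exp(lchoose(n, ks) + ks * log(p0) + (n - ks) * log1p(-p0)))
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# choose(n1+n2, n1) group assignments (no ties assumed).
wilcox_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Tiny two-condition count matrix: one sample per condition, explicit
# per-gene counts plus one spike-in row giving both samples equal ERCC
# totals (so all factors are 1).
toy_matrix <- function(gene_ref, gene_alt, ercc = c(1000, 1000)) {
  genes <- names(gene_ref)
  m <- rbind(cbind(gene_ref, gene_alt), `ERCC-1` = ercc)
  colnames(m) <- c("A", "B")
  cls <- c(stats::setNames(rep("protein_coding", length(genes)), genes),
           `ERCC-1` = "spikein")
  count_matrix(m, cls, c(A = "ctrl", B = "ir"))
}

# Annotation covering a vector of feature ids with chosen lengths.
toy_annotation <- function(ids, lengths, classes = "protein_coding",
                           strand = "+") {
  classes <- rep_len(classes, length(ids))
  strand <- rep_len(strand, length(ids))
  starts <- cumsum(c(0, head(lengths, -1) + 500))
  feature_annotation(data.frame(
    feature_id = ids, chrom = "chr1", start = starts,
    end = starts + lengths, strand = strand, class = classes,
    stringsAsFactors = FALSE))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
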