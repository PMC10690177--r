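test_that("TSV annotation reads 0-based half-open coordinates and computes span length", {
  path <- write_tsv_lines(c(
    "feature_id\tchrom\tstart\tend\tstrand\tclass",
    "geneA\tchr1\t100\t1100\t+\tprotein_coding",
    "rdna1\tchr1\t5000\t18000\t-\trdna",
    "ERCC-00002\tspike\t0\t1061\t.\tspikein"))
  ann <- read_annotation(path, "tsv")
  expect_equal(ann["geneA", "length_bp"], 1000L)
  expect_equal(ann["rdna1", "length_bp"], 13000L)
  expect_equal(ann["ERCC-00002", "class"], "spikein")
  expect_equal(ann["ERCC-00002", "strand"], "*")  # sentinel allowed for spike-ins
})

test_that("annotation contract errors carry locations and names", {
  bad_strand <- write_tsv_lines(c(
    "feature_id\tchrom\tstart\tend\tstrand\tclass",
    "geneA\tchr1\t100\t1100\t.\tprotein_coding"))
  expect_error(read_annotation(bad_strand, "tsv"), "strand")

  bad_cols <- write_tsv_lines(c(
    "feature_id\tchrom\tstart\tend\tstrand\tclass",
    "geneA\tchr1\t100\t1100\t+\tprotein_coding",
    "geneB\tchr1\t100"))
  expect_error(read_annotation(bad_cols, "tsv"), "line 3")

  bad_class <- write_tsv_lines(c(
    "feature_id\tchrom\tstart\tend\tstrand\tclass",
    "geneA\tchr1\t100\t1100\t+\tlincRNA"))
  expect_error(read_annotation(bad_class, "tsv"), "unknown feature class")

  dup <- write_tsv_lines(c(
    "feature_id\tchrom\tstart\tend\tstrand\tclass",
    "geneA\tchr1\t100\t1100\t+\tprotein_coding",
    "geneA\tchr1\t200\t1200\t+\tprotein_coding"))
  expect_error(read_annotation(dup, "tsv"), "duplicate")
})

test_that("GTF gene records convert from 1-based inclusive coordinates", {
  skip_if_not_installed("rtracklayer")
  path <- write_tsv_lines(c(
    paste("chr1", "test", "gene", "2000", "2999", ".", "+", ".",
          'gene_id "geneX";', sep = "\t"),
    paste("chr1", "test", "exon", "2000", "2400", ".", "+", ".",
          'gene_id "geneX";', sep = "\t")),
    tempfile(fileext = ".gtf"))
  ann <- read_annotation(path, "gtf", class_map = c(geneX = "protein_coding"))
  expect_equal(nrow(ann), 1L)           # exon record ignored
  expect_equal(ann$start, 1999)         # converted to 0-based half-open
  expect_equal(ann$end, 2999)
  expect_equal(ann$length_bp, 1000L)
  expect_error(read_annotation(path, "gtf"), "class")
})

test_that("count matrix reader attaches classes and rejects bad cells", {
  ann <- toy_annotation(c("g1", "g2", "ERCC-00002"), c(1000, 2000, 1061),
                        classes = c("protein_coding", "protein_coding", "spikein"))
  path <- write_tsv_lines(c("feature_id\ts1\ts2",
                            "g1\t0\t0", "g2\t0\t0", "ERCC-00002\t0\t0"))
  cm <- read_count_matrix(path, ann)
  expect_true(all(cm$counts == 0))
  expect_equal(unname(cm$class_of["ERCC-00002"]), "spikein")
  expect_equal(rownames(cm$counts), c("g1", "g2", "ERCC-00002"))

  neg <- write_tsv_lines(c("feature_id\ts1\ts2", "g1\t5\t-5"))
  expect_error(read_count_matrix(neg, ann), "g1.*s2")
  frac <- write_tsv_lines(c("feature_id\ts1\ts2", "g1\t5\t2.5"))
  expect_error(read_count_matrix(frac, ann), "non-integer")
  unknown <- write_tsv_lines(c("feature_id\ts1\ts2", "gX\t5\t2"))
  expect_error(read_count_matrix(unknown, ann), "gX")
})

test_that("bedGraph intervals are half-open, zero-filled, and overlap-checked", {
  path <- write_tsv_lines(c("chr1\t0\t10\t5.0"), tempfile(fileext = ".bedGraph"))
  track <- read_bedgraph(path)
  v <- coverage_vector(track, "chr1", 0, 11)
  expect_equal(v, c(rep(5, 10), 0))

  empty <- read_bedgraph(write_tsv_lines(character(0)))
  expect_equal(coverage_vector(empty, "chr1", 0, 5), rep(0, 5))

  expect_error(read_bedgraph(write_tsv_lines(
    c("chr1\t0\t10\t5", "chr1\t9\t20\t3"))), "overlap")
  expect_error(read_bedgraph(write_tsv_lines("chr1\t0\t10\t-2")), "negative")
  # adjacent (book-ended) intervals are not overlapping
  ok <- read_bedgraph(write_tsv_lines(c("chr1\t0\t10\t5", "chr1\t10\t20\t3")))
  expect_equal(coverage_vector(ok, "chr1", 8, 12), c(5, 5, 3, 3))
})

test_that("coverage sums agree with a brute-force per-base expansion", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 20
    widths <- sample(1:10, n, replace = TRUE)
    gaps <- sample(0:15, n, replace = TRUE)
    ends <- cumsum(widths + gaps)
    starts <- ends - widths
    df <- data.frame(chrom = "c", start = starts, end = ends,
                     value = round(stats::runif(n, 0, 9), 2))
    brute <- numeric(600)
    for (i in seq_len(nrow(df))) {
      brute[(df$start[i] + 1):df$end[i]] <- df$value[i]
    }
    track <- coverage_track(df)
    expect_equal(coverage_vector(track, "c", 0, 600), brute)
    win <- sort(sample(0:600, 2))
    expect_equal(sum(coverage_vector(track, "c", win[1], win[2])),
                 sum(brute[seq(win[1] + 1, length.out = win[2] - win[1])]))
  }
})

test_that("readers are order-insensitive on permuted valid lines", {
  set.seed(7)
  body <- c("g1\tchr1\t0\t1000\t+\tprotein_coding",
            "g2\tchr1\t2000\t2600\t-\thistone",
            "g3\tchr2\t0\t13000\t+\trdna",
            "E1\tspike\t0\t500\t*\tspikein")
  header <- "feature_id\tchrom\tstart\tend\tstrand\tclass"
  ref <- read_annotation(write_tsv_lines(c(header, body)), "tsv")
  for (i in 1:5) {
    perm <- read_annotation(write_tsv_lines(c(header, sample(body))), "tsv")
    expect_setequal(perm$feature_id, ref$feature_id)
    expect_equal(perm[ref$feature_id, ], ref[ref$feature_id, ])
  }
  bg <- c("chr1\t0\t10\t5", "chr1\t10\t20\t3", "chr2\t5\t8\t1.5")
  ref_cov <- coverage_vector(read_bedgraph(write_tsv_lines(bg)), "chr1", 0, 25)
  for (i in 1:5) {
    t2 <- read_bedgraph(write_tsv_lines(sample(bg)))
    expect_equal(coverage_vector(t2, "chr1", 0, 25), ref_cov)
  }
})

test_that("results tables round-trip through TSV at fixed precision", {
  tmp <- tempfile(fileext = ".tsv")
  write_results_table(data.frame(gene = character(0), fc = numeric(0)), tmp)
  empty <- read_results_table(tmp)
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), c("gene", "fc"))

  set.seed(1)
  df <- data.frame(gene = sprintf("g%03d", 1:100),
                   fc = exp(stats::rnorm(100)),
                   p_value = stats::runif(100)^3,
                   call = sample(c("up", "down", "unchanged"), 100, TRUE),
                   stringsAsFactors = FALSE)
  write_results_table(df, tmp)
  back <- read_results_table(tmp)
  expect_equal(back$gene, df$gene)
  expect_equal(back$call, df$call)
  expect_equal(back$fc, df$fc, tolerance = 1e-5)       # 6 significant digits
  expect_equal(back$p_value, df$p_value, tolerance = 1e-5)
  expect_error(write_results_table(df, file.path(tempdir(), "no_dir", "x.tsv")),
               "cannot open")
})
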