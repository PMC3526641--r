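rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

test_that("the candidate filter applies the triple condition exactly", {
  s27 <- strrep("ACG", 9)
  ar <- make_annotated(
    sequences = c(s27, s27, s27, strrep("AC", 11), strrep("ACTG", 7)),
    n_loci = c(5L, 6L, 1L, 3L, 3L),
    category = c("unannotated", "unannotated", "miRNA", "unannotated",
                 "unannotated"))
  # boundary: 27 nt, 5 loci retained; 6 loci excluded; wrong category
  # excluded; 22 nt too short; 28 nt retained
  cand <- select_rasirna_candidates(ar)
  expect_identical(nrow(cand$reads), 2L)
  expect_identical(cand$reads$n_loci, c(5L, 3L))
  expect_identical(cand$reads$sequence, c(s27, strrep("ACTG", 7)))

  # predicate oracle over a random table
  set.seed(41)
  n <- 10000L
  lens <- sample(18:35, n, replace = TRUE)
  tbl <- make_annotated(
    sequences = vapply(lens, function(L) strrep("A", L), character(1)),
    n_loci = sample(0:8, n, replace = TRUE),
    category = sample(c("unannotated", "miRNA", "repeat:LINE", "unmapped"),
                      n, replace = TRUE))
  got <- select_rasirna_candidates(tbl)
  brute <- with(tbl$reads, nchar(sequence) >= 23 & nchar(sequence) <= 32 &
                  category == "unannotated" & n_loci >= 1 & n_loci <= 5)
  expect_identical(nrow(got$reads), sum(brute))
  # idempotence
  twice <- select_rasirna_candidates(got)
  expect_identical(twice$reads, got$reads)
})

test_that("fivep_bias estimates positional frequencies correctly", {
  # all reads starting with T: position-1 U frequency is 1
  allT <- make_annotated(paste0("T", rand_seq(50, 25)), rep(1L, 50),
                         rep("unannotated", 50))
  b <- fivep_bias(allT)
  expect_identical(b$u1_fraction, 1)
  expect_equal(rowSums(b$matrix), rep(1, nrow(b$matrix)), tolerance = 1e-9)

  # planted 0.8 first-base U: binomial oracle, 3 s.d.
  set.seed(42)
  n <- 4000L
  first <- ifelse(runif(n) < 0.8, "T", sample(c("A", "C", "G"), n, TRUE))
  planted <- make_annotated(paste0(first, rand_seq(n, 26)), rep(1L, n),
                            rep("unannotated", n))
  b <- fivep_bias(planted)
  expect_lt(abs(b$u1_fraction - 0.8), 3 * sqrt(0.8 * 0.2 / n))

  # uniform random reads: every cell near 0.25
  unif <- make_annotated(rand_seq(3000, 24), rep(1L, 3000),
                         rep("unannotated", 3000))
  b <- fivep_bias(unif)
  expect_true(all(abs(b$matrix - 0.25) < 3 * sqrt(0.25 * 0.75 / 3000)))

  # empty candidate set
  e <- fivep_bias(make_annotated(character(0), integer(0), character(0),
                                 integer(0)))
  expect_true(is.na(e$u1_fraction))
  expect_identical(e$n_reads, 0L)
})

test_that("chrom_distribution normalizes by chromosome length", {
  g <- Biostrings::DNAStringSet(c(cA = strrep("A", 1000),
                                  cB = strrep("A", 2000)))
  hits <- data.frame(read = 1:20,
                     chrom = rep(c("cA", "cB"), each = 10),
                     start = 1L, end = 24L, strand = "+",
                     stringsAsFactors = FALSE)
  ar <- make_annotated(rand_seq(20, 24), rep(1L, 20),
                       rep("unannotated", 20), hits = hits)
  cd <- chrom_distribution(ar, g, GenomicRanges::GRanges())
  expect_equal(cd$density_unique[cd$chrom == "cA"] /
                 cd$density_unique[cd$chrom == "cB"], 2)

  # fractional attribution: one read with 2 loci on different chromosomes
  h2 <- data.frame(read = c(1L, 1L), chrom = c("cA", "cB"),
                   start = 1L, end = 24L, strand = "+")
  a2 <- make_annotated(rand_seq(1, 24), 2L, "unannotated", hits = h2)
  cd2 <- chrom_distribution(a2, g, GenomicRanges::GRanges())
  expect_equal(cd2$n_unique, c(0.5, 0.5))

  # no candidates -> zero densities; unknown chromosome -> error
  e <- chrom_distribution(make_annotated(character(0), integer(0),
                                         character(0), integer(0)),
                          g, GenomicRanges::GRanges())
  expect_true(all(e$density_unique == 0))
  bad <- make_annotated("A", 1L, "unannotated",
                        hits = data.frame(read = 1L, chrom = "cZ", start = 1L,
                                          end = 1L, strand = "+"))
  expect_error(chrom_distribution(bad, g, GenomicRanges::GRanges()), "cZ")
})

test_that("feature_density equals a per-base recount", {
  set.seed(43)
  chrom_len <- 20000L
  tr <- GenomicRanges::GRanges(
    seqnames = "c", ranges = IRanges::IRanges(
      start = sample.int(chrom_len - 400L, 40L),
      width = sample(50:400, 40L, replace = TRUE)),
    strand = sample(c("+", "-"), 40L, TRUE),
    category = "exon", name = sprintf("e%02d", 1:40))
  dt <- feature_density(tr, "exon", "c", chrom_len,
                        window_size = 5000L, step = 500L)
  # per-base oracle
  cov <- logical(chrom_len)
  for (i in seq_along(tr)) {
    cov[GenomicRanges::start(tr)[i]:GenomicRanges::end(tr)[i]] <- TRUE
  }
  for (k in seq_along(dt$window_start)) {
    lo <- dt$window_start[k] + 1L; hi <- dt$window_end[k]
    expect_equal(dt$value[k], mean(cov[lo:hi]), tolerance = 1e-12)
  }

  # degenerate cases
  none <- feature_density(GenomicRanges::GRanges(), "exon", "c", 10000L)
  expect_true(all(none$value == 0))
  full <- GenomicRanges::GRanges("c", IRanges::IRanges(1L, 10000L),
                                 category = "exon", name = "e")
  d1 <- feature_density(full, "exon", "c", 10000L, 1000L, 1000L)
  expect_true(all(d1$value == 1))

  # invariance to splitting an interval into adjacent pieces
  whole <- GenomicRanges::GRanges("c", IRanges::IRanges(101L, 400L),
                                  category = "exon", name = "w")
  parts <- GenomicRanges::GRanges(
    "c", IRanges::IRanges(start = c(101L, 201L, 301L), end = c(200L, 300L, 400L)),
    category = "exon", name = c("p1", "p2", "p3"))
  dw <- feature_density(whole, "exon", "c", 1000L, 200L, 100L)
  dp <- feature_density(parts, "exon", "c", 1000L, 200L, 100L)
  expect_equal(dw$value, dp$value)
})

test_that("read_density counts 5' ends, strand-aware and conservatively", {
  g_len <- 10000L
  h <- data.frame(read = 1L, chrom = "c", start = 2500L, end = 2526L,
                  strand = "+", stringsAsFactors = FALSE)
  ar <- make_annotated(rand_seq(1, 27), 1L, "unannotated", hits = h)
  dt <- read_density(ar, "c", "+", g_len, window_size = 1000L, step = 200L)
  inside <- dt$window_start < 2500L & dt$window_end >= 2500L
  expect_true(all(dt$value[inside] == 1))
  expect_true(all(dt$value[!inside] == 0))

  # invalid strand symbol
  expect_error(read_density(ar, "c", "x", g_len), "strand")

  # strand exchange symmetry
  h2 <- h; h2$strand <- "-"
  ar2 <- make_annotated(ar$reads$sequence, 1L, "unannotated", hits = h2)
  dminus <- read_density(ar2, "c", "-", g_len, 1000L, 200L)
  dplus0 <- read_density(ar2, "c", "+", g_len, 1000L, 200L)
  expect_true(all(dplus0$value == 0))
  # 5' end of the minus-strand read is its right end
  inside2 <- dminus$window_start < 2526L & dminus$window_end >= 2526L
  expect_true(all(dminus$value[inside2] == 1))

  # brute-force recount with multi-locus weighting
  set.seed(44)
  n <- 400L
  hits <- data.frame(read = rep(seq_len(n), each = 2),
                     chrom = "c",
                     start = sample.int(g_len - 30L, 2L * n, replace = TRUE),
                     strand = sample(c("+", "-"), 2L * n, replace = TRUE))
  hits$end <- hits$start + 26L
  arn <- make_annotated(rand_seq(n, 27), rep(2L, n),
                        rep("unannotated", n), hits = hits)
  dt <- read_density(arn, "c", "+", g_len, 500L, 100L)
  p5 <- ifelse(hits$strand == "+", hits$start, hits$end)
  for (k in sample(seq_along(dt$window_start), 25L)) {
    manual <- sum(0.5 * (hits$strand == "+" & p5 > dt$window_start[k] &
                           p5 <= dt$window_end[k]))
    expect_equal(dt$value[k], manual)
  }

  # conservation when step = window: total fractional count on the strand
  dtc <- read_density(arn, "c", "+", g_len, 500L, 500L)
  expect_equal(sum(dtc$value), sum(hits$strand == "+") * 0.5)

  # upstream filter contract is asserted
  bad <- make_annotated("A", 7L, "unannotated",
                        hits = data.frame(read = 1L, chrom = "c", start = 1L,
                                          end = 1L, strand = "+"))
  expect_error(read_density(bad, "c", "+", g_len), "max_loci")
})

test_that("testis-like candidates keep the planted 24/27 bimodality", {
  ta <- fx_testis_annotated()
  cand <- select_rasirna_candidates(ta$annotated)
  h <- length_histogram(cand$reads, "unique")
  counts <- stats::setNames(h$count, h$length)
  expect_gt(counts[["24"]], counts[["23"]])
  expect_gt(counts[["24"]], counts[["25"]])
  expect_gt(counts[["27"]], counts[["26"]])
  expect_gt(counts[["27"]], counts[["28"]])
})
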