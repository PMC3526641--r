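# a hand-built two-hairpin annotation world for controlled clustering tests
tiny_mirna_world <- function() {
  # random (aperiodic) sequence so substrings locate uniquely
  set.seed(777)
  chr <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrM = chr))
  # hairpins at 11-90 and 201-280; matures sit on the right (3') arm,
  # local coordinates 41-62 of each 80 nt hairpin
  hp <- GenomicRanges::GRanges(
    seqnames = "chrM", ranges = IRanges::IRanges(start = c(11L, 201L),
                                                 width = 80L),
    strand = "+", category = "miRNA_hairpin", name = c("hp1", "hp2"))
  mature <- GenomicRanges::GRanges(
    seqnames = "chrM", ranges = IRanges::IRanges(start = c(51L, 241L),
                                                 width = 22L),
    strand = "+", category = "miRNA_mature", name = c("mir-1", "mir-2"))
  sub <- function(s, e) substr(chr, s, e)
  structure(list(
    tracks = hp, mature = mature,
    mirna = data.frame(hairpin_id = c("hp1", "hp2"),
                       mature_id = c("mir-1", "mir-2"),
                       stringsAsFactors = FALSE),
    hairpin_seq = Biostrings::DNAStringSet(
      c(hp1 = sub(11, 90), hp2 = sub(201, 280))),
    mature_seq = Biostrings::DNAStringSet(
      c(`mir-1` = sub(51, 72), `mir-2` = sub(241, 262)))
  ), class = "annotation_set")
}

mirna_annotated <- function(seqs, counts, starts, width = nchar(seqs)) {
  n <- length(seqs)
  hits <- data.frame(read = seq_len(n), chrom = "chrM", start = starts,
                     end = starts + width - 1L, strand = "+",
                     stringsAsFactors = FALSE)
  make_annotated(seqs, rep(1L, n), rep("miRNA", n), counts = counts,
                 hits = hits)
}

test_that("cluster_isomirs picks the max-count reference with tiebreaks", {
  w <- tiny_mirna_world()
  canonical <- as.character(w$mature_seq[["mir-1"]])
  shift_p1 <- substr(as.character(w$hairpin_seq[["hp1"]]), 42, 63)  # +1 shift
  shift_m1 <- substr(as.character(w$hairpin_seq[["hp1"]]), 40, 61)  # -1 shift

  ar <- mirna_annotated(c(canonical, shift_p1, shift_m1),
                        counts = c(50L, 30L, 20L),
                        starts = c(51L, 52L, 50L))
  cl <- cluster_isomirs(ar, w)
  expect_identical(unique(cl$mature_id), "mir-1")
  expect_identical(cl$sequence[cl$is_reference], canonical)

  # single member is its own reference
  ar1 <- mirna_annotated(canonical, 7L, 51L)
  cl1 <- cluster_isomirs(ar1, w)
  expect_identical(cl1$sequence[cl1$is_reference], canonical)

  # equal counts: brute-force argmax with lexicographic tiebreak
  ar2 <- mirna_annotated(c(canonical, shift_p1), c(10L, 10L),
                         c(51L, 52L))
  cl2 <- cluster_isomirs(ar2, w)
  brute <- sort(c(canonical, shift_p1))[1]
  expect_identical(cl2$sequence[cl2$is_reference], brute)
})

test_that("seven-group classification follows the decision table", {
  w <- tiny_mirna_world()
  mat <- as.character(w$mature_seq)
  hp <- as.character(w$hairpin_seq)
  pairing <- w$mirna

  classify1 <- function(seq) {
    cl <- data.frame(mature_id = "q", hairpin_id = "q", sequence = seq,
                     count = 1L, total_count = 1L, is_reference = TRUE,
                     stringsAsFactors = FALSE)
    classify_seven_groups(cl, mat, hp, pairing)$group
  }

  h1 <- hp[["hp1"]]
  expect_identical(classify1(mat[["mir-1"]]), "gp1a")          # exact mature
  expect_identical(classify1(substr(h1, 42, 63)), "gp1b")      # shifted, on hairpin
  expect_identical(classify1(substr(h1, 64, 80)), "gp3a")      # same arm, off mature
  expect_identical(classify1(substr(h1, 2, 23)), "gp3b")       # star arm
  # mature with 2 nt trimmed at the 3' end, hairpin context removed
  trimmed <- substr(mat[["mir-1"]], 1, 20)
  expect_identical(
    classify_seven_groups(
      data.frame(mature_id = "q", hairpin_id = "q", sequence = trimmed,
                 count = 1L, total_count = 1L, is_reference = TRUE),
      mat, hp["hp2"], pairing[2, ])$group, "gp2a")
  # antisense of a known mature
  expect_identical(classify1(revcomp(mat[["mir-2"]])), "gp2b")
  # unrelated sequence
  expect_identical(classify1(strrep("AC", 11)), "gp4a")

  # empty library: all group counts zero
  empty <- cluster_isomirs(make_annotated(character(0), integer(0),
                                          character(0), integer(0)), w)
  g <- classify_seven_groups(empty, mat, hp, pairing)
  tab <- group_table(empty, g)
  expect_true(all(tab$matures_library == 0L))
})

test_that("normalize_cpm is exact and guards the total", {
  expect_identical(normalize_cpm(1, 1e6), 1)
  expect_identical(normalize_cpm(c(5, 0), 5), c(1e6, 0))
  expect_error(normalize_cpm(1, 0), "positive")
  expect_error(normalize_cpm(-1, 10), "non-negative")
  set.seed(8)
  counts <- rpois(50, 40); total <- 123456
  expect_equal(normalize_cpm(counts, total), counts / total * 1e6)
})

test_that("audic_claverie_test matches the exact tail-sum oracle", {
  expect_identical(audic_claverie_test(0, 0, 1e6, 1e6), 1)
  expect_equal(audic_claverie_test(5, 5, 1e6, 1e6),
               ac_oracle(5, 5, 1e6, 1e6), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:40) {
    x <- sample(0:200, 1); y <- sample(0:200, 1)
    na <- sample(c(1e5, 1e6, 8190484), 1); nb <- sample(c(1e5, 2e6), 1)
    p <- audic_claverie_test(x, y, na, nb)
    o <- ac_oracle(x, y, na, nb)
    expect_lt(abs(p - o) / o, 1e-10)
  }
  expect_error(audic_claverie_test(-1, 0, 10, 10), "non-negative")
  expect_error(audic_claverie_test(1.5, 0, 10, 10), "integers")
})

test_that("audic_claverie_test is exactly swap-symmetric", {
  set.seed(10)
  for (i in 1:50) {
    x <- sample(0:300, 1); y <- sample(0:300, 1)
    na <- runif(1, 1e4, 1e7); nb <- runif(1, 1e4, 1e7)
    expect_identical(audic_claverie_test(x, y, na, nb),
                     audic_claverie_test(y, x, nb, na))
  }
})

test_that("a count jump like miR-148a between gonads is significant", {
  # counts of the magnitude reported for testis vs ovary libraries
  p <- audic_claverie_test(146, 19754, 11121041, 8190484)
  expect_lt(p, 1e-100)
})

test_that("differential_table applies BH correctly", {
  w <- tiny_mirna_world()
  canonical <- as.character(w$mature_seq[["mir-1"]])
  ar <- mirna_annotated(canonical, 1L, 51L)
  ar$reads$count_a <- 4L; ar$reads$count_b <- 9L; ar$reads$count <- NULL
  cl <- cluster_isomirs(ar, w)
  de <- differential_table(cl, "a", "b", 100, 100)
  expect_identical(nrow(de), 1L)
  expect_identical(de$fdr, de$p_value)  # single feature: fdr = p

  # null: identical libraries yield no BH discovery beyond its guarantee
  set.seed(12)
  n <- 150
  seqs <- vapply(seq_len(n), function(i) paste(
    sample(c("A", "C", "G", "T"), 22, TRUE), collapse = ""), character(1))
  counts <- rpois(n, 30)
  fake <- data.frame(mature_id = sprintf("m%03d", seq_len(n)),
                     hairpin_id = sprintf("h%03d", seq_len(n)),
                     sequence = seqs, count_a = counts, count_b = counts,
                     total_count = 2L * counts, is_reference = TRUE)
  de0 <- differential_table(fake, "a", "b", sum(counts), sum(counts))
  expect_identical(sum(de0$significant), 0L)
  # BH fdr is monotone in p-rank and capped at 1
  expect_true(all(diff(de0$fdr) >= -1e-12))
  expect_true(all(de0$fdr <= 1))
})
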