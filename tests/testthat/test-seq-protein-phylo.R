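NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                    c("A","C","G","T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# independent brute-force ORF enumeration over the three forward frames
brute_orf <- function(s) {
  best <- NULL
  n <- nchar(s)
  for (f in 0:2) {
    starts <- seq(1 + f, n - 2, by = 3)
    codons <- substring(s, starts, starts + 2)
    for (a in which(codons == "ATG")) {
      stops <- which(codons %in% c("TAA", "TAG", "TGA"))
      stops <- stops[stops > a]
      # in-frame stop closest to this ATG, with no earlier stop in between
      if (length(stops) == 0) next
      k <- stops[1]
      len <- (k - a + 1) * 3
      if (is.null(best) || len > best$len ||
          (len == best$len && starts[a] < best$start)) {
        best <- list(start = starts[a], end = starts[k] + 2, len = len)
      }
    }
  }
  best
}

test_that("find_orf locates and translates the longest forward ORF", {
  tm <- find_orf("ATGTAA")
  expect_identical(tm$orf_start, 1L)
  expect_identical(tm$orf_end, 6L)
  expect_identical(tm$protein$residues, "M")
  expect_identical(tm$protein$length, 1L)

  # no ORF: explicit empty result, not an exception
  tm0 <- find_orf("CCCCCCCCC")
  expect_true(is.na(tm0$orf_start))
  expect_null(tm0$protein)

  expect_error(find_orf("ACGTN"), "A, C, G, T")
  expect_error(find_orf("ACG"), "at least 6")
})

test_that("a 142 + 2595 + 667 nt transcript yields an 864-residue protein", {
  set.seed(51)
  utr5 <- paste(sample(c("C", "T", "G"), 142, replace = TRUE), collapse = "")
  utr3 <- paste(sample(c("C", "T", "G"), 667, replace = TRUE), collapse = "")
  orf <- paste0("ATG",
                paste(sample(NONSTOP_CODONS, 863, replace = TRUE),
                      collapse = ""), "TAA")
  tx <- paste0(utr5, orf, utr3, strrep("A", 30))
  tm <- find_orf(tx)
  expect_identical(tm$utr5_len, 142L)
  expect_identical(tm$orf_end - tm$orf_start + 1L, 2595L)
  expect_identical(tm$utr3_len, 667L)
  expect_true(tm$has_polyA)
  expect_identical(tm$protein$length, 864L)
  # invariant: residue count = orf length / 3 - 1
  expect_identical(tm$protein$length,
                   as.integer((tm$orf_end - tm$orf_start + 1L) / 3L - 1L))
})

test_that("find_orf agrees with brute-force enumeration on random input", {
  set.seed(52)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(60:240, 1),
                      replace = TRUE), collapse = "")
    got <- find_orf(s, polya_min = 1000L)
    want <- brute_orf(s)
    if (is.null(want)) {
      expect_true(is.na(got$orf_start))
    } else {
      expect_identical(got$orf_start, as.integer(want$start))
      expect_identical(got$orf_end, as.integer(want$end))
    }
  }
})

test_that("protein_mw follows the additivity identity", {
  expect_equal(protein_mw("G"), 75.07, tolerance = 0.01)
  expect_error(protein_mw(""), "empty")
  expect_error(protein_mw("MGX"), "position 3")
  set.seed(53)
  aas <- c("A","R","N","D","C","E","Q","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
  for (i in 1:20) {
    s1 <- paste(sample(aas, 12, TRUE), collapse = "")
    s2 <- paste(sample(aas, 9, TRUE), collapse = "")
    expect_equal(protein_mw(paste0(s1, s2)),
                 protein_mw(s1) + protein_mw(s2) - 18.02,
                 tolerance = 1e-9)
  }
})

test_that("protein_pI brackets known extremes and matches a grid scan", {
  expect_gt(protein_pI("RRRRR"), 10)
  expect_lt(protein_pI("DDDDD"), 4.5)

  # independent fine-grid oracle over the same charge model (EMBOSS pKas)
  grid_pI <- function(s) {
    pka <- c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
             D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
    aa <- strsplit(s, "")[[1]]
    ph <- seq(0, 14, by = 1e-4)
    chg <- 1 / (1 + 10^(ph - pka["Nterm"])) -
      1 / (1 + 10^(pka["Cterm"] - ph))
    for (r in c("K", "R", "H")) {
      chg <- chg + sum(aa == r) / (1 + 10^(ph - pka[r]))
    }
    for (r in c("D", "E", "C", "Y")) {
      chg <- chg - sum(aa == r) / (1 + 10^(pka[r] - ph))
    }
    ph[which.max(chg <= 0)]
  }
  set.seed(54)
  aas <- c("A","R","N","D","C","E","Q","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
  for (i in 1:10) {
    s <- paste(sample(aas, 50, TRUE), collapse = "")
    expect_equal(protein_pI(s), grid_pI(s), tolerance = 0.01)
  }
  # the Bjellqvist table is selectable and gives a different but close value
  s <- paste(sample(aas, 50, TRUE), collapse = "")
  expect_false(isTRUE(all.equal(protein_pI(s), protein_pI(s, "Bjellqvist"))))
})

test_that("upgma handles the two-taxon base case and rejects bad input", {
  d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(d)
  expect_identical(tr$newick, "(A:2,B:2);")
  expect_equal(unname(leaf_depths(tr)), c(2, 2))

  asym <- d; asym[1, 2] <- 5
  expect_error(upgma(asym), "symmetric")
  neg <- d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(upgma(neg), "negative")
  expect_error(upgma(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "two taxa")
})

test_that("upgma recovers ultrametric matrices exactly (round-trip)", {
  for (seed in c(61, 62, 63)) {
    n <- sample(5:8, 1)
    m <- random_ultrametric(n, seed)
    tr <- upgma(m)
    cop <- cophenetic_upgma(tr)
    expect_equal(cop[rownames(m), colnames(m)], m, tolerance = 1e-9)
    # ultrametricity: equal root-to-leaf depths
    dep <- leaf_depths(tr)
    expect_lt(max(dep) - min(dep), 1e-9)
  }
})

test_that("upgma tiebreak is deterministic under permutation", {
  # two pairs tied at distance 2: (A,B) and (C,D); A,B merge first
  d <- matrix(6, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  t1 <- upgma(d)
  perm <- c("D", "B", "A", "C")
  t2 <- upgma(d[perm, perm])
  expect_identical(t1$newick, t2$newick)
})

test_that("p_distance counts mismatches over ungapped columns", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">a", "MK-LV", ">b", "MKQIV", ">c", "MKQII"), f)
  m <- p_distance(f)
  expect_equal(m["a", "b"], 1 / 4)   # L vs I over 4 ungapped columns
  expect_equal(m["b", "c"], 1 / 5)
  tr <- upgma(m)
  expect_s3_class(tr, "upgma_tree")
  file.remove(f)
})
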