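# Shared fixtures, built lazily and cached for the whole run. Everything is
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small world: 850 kb genome, default annotation
fx_genome <- function() fixture("genome", function() {
  make_genome(genome_spec(seed = 11L))
})

fx_annots <- function() fixture("annots", function() {
  make_annotations(fx_genome(), annotation_spec(seed = 12L))
})

# a mid-sized testis-like simulation shared by several files
fx_testis_sim <- function() fixture("testis_sim", function() {
  simulate_library(fx_genome(), fx_annots(),
                   library_archetype("testis_like", n_reads = 20000L,
                                     seed = 13L))
})

fx_testis_annotated <- function() fixture("testis_annotated", function() {
  sim <- fx_testis_sim()
  cl <- clean_reads(list(ids = sim$ids, reads = sim$reads, quals = sim$quals))
  ur <- collapse_unique(cl, "testis")
  list(clean = cl, unique = ur,
       annotated = annotate_reads(ur, fx_genome(), fx_annots()))
})

# construct an annotated_reads object directly (unit-test scaffolding)
make_annotated <- function(sequences, n_loci, category, counts = NULL,
                           hits = NULL) {
  reads <- data.frame(sequence = sequences, count = counts %||% rep(1L,
                      length(sequences)), stringsAsFactors = FALSE)
  reads$n_loci <- n_loci
  reads$category <- category
  if (is.null(hits)) {
    hits <- data.frame(read = integer(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), stringsAsFactors = FALSE)
  }
  structure(list(reads = reads, hits = hits), class = "annotated_reads")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent naive exact mapper: gregexpr on both strands
naive_map <- function(reads, genome) {
  chrom_str <- vapply(seq_along(genome),
                      function(i) as.character(genome[[i]]), character(1))
  names(chrom_str) <- names(genome)
  rows <- list()
  for (r in seq_along(reads)) {
    w <- nchar(reads[r])
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(reads[r])))
    for (ch in names(chrom_str)) {
      for (variant in c("+", "-")) {
        pat <- if (variant == "+") reads[r] else rc
        m <- gregexpr(pat, chrom_str[[ch]], fixed = TRUE)[[1]]
        if (m[1] != -1L) {
          rows[[length(rows) + 1L]] <- data.frame(
            read = r, chrom = ch, start = as.integer(m),
            end = as.integer(m) + w - 1L, strand = variant,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(read = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$read, out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# independent Audic-Claverie oracle: direct tail summation of the negative
# binomial mass via the term recurrence, upper tails summed smallest-first
ac_oracle <- function(x, y, n_a, n_b, kmax = 4000L) {
  tails <- function(obs, size, prob) {
    q <- 1 - prob
    k <- 0:kmax
    logt <- lchoose(size - 1 + k, k) + size * log(prob) + k * log(q)
    t <- exp(logt)
    lower <- cumsum(t)[obs + 1L]
    upper <- rev(cumsum(rev(t)))[obs + 1L]
    c(lower = lower, upper = upper)
  }
  p_a <- n_a / (n_a + n_b); p_b <- n_b / (n_a + n_b)
  t1 <- tails(y, x + 1, p_a)
  t2 <- tails(x, y + 1, p_b)
  min(1, 2 * min(c(t1, t2)))
}

# random ultrametric tree -> cophenetic matrix, for UPGMA round-trips
random_ultrametric <- function(n, seed) {
  set.seed(seed)
  labels <- sprintf("t%02d", seq_len(n))
  heights <- sort(runif(n - 1, 0.5, 10))  # distinct merge heights
  # agglomerate random pairs at increasing heights, record cophenetic dists
  clusters <- as.list(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (h in heights) {
    pick <- sample.int(length(clusters), 2)
    a <- clusters[[pick[1]]]; b <- clusters[[pick[2]]]
    m[a, b] <- 2 * h; m[b, a] <- 2 * h
    clusters[[pick[1]]] <- c(a, b)
    clusters <- clusters[-pick[2]]
  }
  m
}
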