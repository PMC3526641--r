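## Exhaustive exact-match mapping of unique reads on both genome strands,
## followed by a priority-cascade annotation: each read receives exactly one
## category, the highest-priority one among the features overlapped by any
## of its hits. Overlap is same-strand for ncRNA/miRNA/exon/intron features
## and strand-agnostic for repeats (repeat-associated small RNAs arise from
## bidirectional transcription of repeats).

#' Default annotation priority
#'
#' Highest first. `unmapped` and `unannotated` are implicit outcomes, not
#' assignable track categories.
#' @export
DEFAULT_PRIORITY <- c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA",
                      "repeat:LINE", "repeat:LTR", "repeat:satellite",
                      "repeat:other", "exon", "intron")

## track-category -> cascade-category
CASCADE_MAP <- c(
  rRNA = "rRNA", tRNA = "tRNA", snRNA = "snRNA", snoRNA = "snoRNA",
  miRNA_hairpin = "miRNA", miRNA_mature = "miRNA",
  LINE = "repeat:LINE", LTR = "repeat:LTR", satellite = "repeat:satellite",
  other_repeat = "repeat:other", exon = "exon", intron = "intron"
)

STRAND_AGNOSTIC <- c("repeat:LINE", "repeat:LTR", "repeat:satellite",
                     "repeat:other")

#' Map reads to all exact-match loci on both strands
#'
#' Minus-strand hits are reported in plus-strand coordinates of the matched
#' substring. All loci are returned; a read matching both strands at one
#' locus (a reverse-complement palindrome) yields two hits.
#'
#' @param reads character vector of sequences over A/C/G/T.
#' @param genome named `DNAStringSet`.
#' @return data.frame with columns `read` (index into `reads`), `chrom`,
#'   `start`, `end` (1-based, closed), `strand`; sorted by read, chrom,
#'   start, strand.
#' @export
map_exact <- function(reads, genome) {
  if (length(reads) == 0L) {
    return(data.frame(read = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  if (any(grepl("[^ACGT]", reads))) {
    stop("reads must contain only A, C, G, T")
  }
  widths <- nchar(reads)
  rows <- vector("list", 0L)
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    fwd <- Biostrings::DNAStringSet(reads[idx])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (ch in names(genome)) {
      subj <- genome[[ch]]
      if (length(subj) < w) next
      sf <- Biostrings::startIndex(Biostrings::matchPDict(pd_f, subj))
      sr <- Biostrings::startIndex(Biostrings::matchPDict(pd_r, subj))
      nf <- lengths(sf); nr <- lengths(sr)
      if (sum(nf) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          read = rep(idx, nf), chrom = ch,
          start = unlist(sf, use.names = FALSE), strand = "+",
          stringsAsFactors = FALSE)
      }
      if (sum(nr) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          read = rep(idx, nr), chrom = ch,
          start = unlist(sr, use.names = FALSE), strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(read = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  hits$end <- hits$start + widths[hits$read] - 1L
  hits <- hits[order(hits$read, hits$chrom, hits$start, hits$strand),
               c("read", "chrom", "start", "end", "strand")]
  rownames(hits) <- NULL
  hits
}

#' Assign one category per read by priority cascade
#'
#' @param unique_reads data.frame with a `sequence` column and one or more
#'   count columns (from [collapse_unique()] or [merge_unique()]).
#' @param hits hit table from [map_exact()] over `unique_reads$sequence`.
#' @param tracks an `annotation_set` or a `GRanges` with `category` metadata
#'   (track vocabulary: rRNA, tRNA, snRNA, snoRNA, miRNA_hairpin,
#'   miRNA_mature, LINE, LTR, satellite, other_repeat, exon, intron).
#' @param priority cascade order, highest first (cascade vocabulary, see
#'   [DEFAULT_PRIORITY]).
#' @return object of class `annotated_reads`: list with `reads` (the input
#'   data.frame plus `n_loci` and `category`) and `hits`.
#' @export
annotate_cascade <- function(unique_reads, hits, tracks,
                             priority = DEFAULT_PRIORITY) {
  gr <- if (inherits(tracks, "annotation_set")) {
    c(tracks$tracks, tracks$mature)
  } else tracks
  if (length(gr) > 0L) {
    check_categories(gr$category, names(CASCADE_MAP))
  }
  bad <- setdiff(priority, DEFAULT_PRIORITY)
  if (length(bad) > 0L) {
    stop(sprintf("unknown category in priority: %s", paste(bad, collapse = ", ")))
  }

  n <- nrow(unique_reads)
  n_loci <- tabulate(hits$read, nbins = n)
  category <- ifelse(n_loci == 0L, "unmapped", "unannotated")

  if (nrow(hits) > 0L && length(gr) > 0L) {
    hit_gr <- GenomicRanges::GRanges(
      seqnames = hits$chrom,
      ranges = IRanges::IRanges(start = hits$start, end = hits$end),
      strand = hits$strand)
    casc <- unname(CASCADE_MAP[gr$category])
    ## strand-aware overlaps for stranded feature classes
    ov_s <- GenomicRanges::findOverlaps(hit_gr, gr, minoverlap = 1L,
                                        ignore.strand = FALSE)
    ## strand-agnostic overlaps for repeats
    ov_a <- GenomicRanges::findOverlaps(hit_gr, gr, minoverlap = 1L,
                                        ignore.strand = TRUE)
    keep_s <- !(casc[S4Vectors::subjectHits(ov_s)] %in% STRAND_AGNOSTIC)
    keep_a <- casc[S4Vectors::subjectHits(ov_a)] %in% STRAND_AGNOSTIC
    q <- c(S4Vectors::queryHits(ov_s)[keep_s],
           S4Vectors::queryHits(ov_a)[keep_a])
    s <- c(S4Vectors::subjectHits(ov_s)[keep_s],
           S4Vectors::subjectHits(ov_a)[keep_a])
    if (length(q) > 0L) {
      rd <- hits$read[q]
      rank <- match(casc[s], priority)
      ok <- !is.na(rank)
      best <- tapply(rank[ok], rd[ok], min)
      category[as.integer(names(best))] <- priority[best]
    }
  }

  reads <- unique_reads
  reads$n_loci <- n_loci
  reads$category <- category
  structure(list(reads = reads, hits = hits), class = "annotated_reads")
}

#' Map and annotate in one step
#'
#' @inheritParams annotate_cascade
#' @param genome named `DNAStringSet`.
#' @return an `annotated_reads` object.
#' @export
annotate_reads <- function(unique_reads, genome, tracks,
                           priority = DEFAULT_PRIORITY) {
  hits <- map_exact(unique_reads$sequence, genome)
  annotate_cascade(unique_reads, hits, tracks, priority)
}

#' Per-category unique-read and copy-count table
#'
#' @param ar an `annotated_reads` object.
#' @return data.frame with one row per observed category: `category`,
#'   `n_unique`, `n_copies`, `frac_unique`, `frac_copies`. Fractions each
#'   sum to 1 over the table (empty input gives an empty table).
#' @export
category_table <- function(ar) {
  stopifnot(inherits(ar, "annotated_reads"))
  df <- ar$reads
  if (nrow(df) == 0L) {
    return(data.frame(category = character(0), n_unique = integer(0),
                      n_copies = integer(0), frac_unique = numeric(0),
                      frac_copies = numeric(0), stringsAsFactors = FALSE))
  }
  cc <- grep("^count", names(df), value = TRUE)
  copies <- if (length(cc) > 0L) rowSums(df[, cc, drop = FALSE]) else
    rep(1, nrow(df))
  agg_u <- tapply(rep(1L, nrow(df)), df$category, sum)
  agg_c <- tapply(copies, df$category, sum)
  out <- data.frame(category = names(agg_u),
                    n_unique = as.integer(agg_u),
                    n_copies = as.numeric(agg_c[names(agg_u)]),
                    stringsAsFactors = FALSE)
  out$frac_unique <- out$n_unique / sum(out$n_unique)
  out$frac_copies <- out$n_copies / sum(out$n_copies)
  ## stable, cascade-flavoured ordering
  lev <- c(DEFAULT_PRIORITY, "unannotated", "unmapped")
  out <- out[order(match(out$category, lev)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an annotated-read table as TSV
#'
#' Hits are serialized as semicolon-joined `chrom:start-end:strand` strings
#' (1-based, closed coordinates).
#'
#' @param ar an `annotated_reads` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotated_tsv <- function(ar, path) {
  df <- ar$reads
  hp <- if (nrow(ar$hits) > 0L) {
    s <- sprintf("%s:%d-%d:%s", ar$hits$chrom, ar$hits$start,
                 ar$hits$end, ar$hits$strand)
    tapply(s, ar$hits$read, paste, collapse = ";")
  } else NULL
  df$hits <- character(nrow(df))
  if (!is.null(hp)) df$hits[as.integer(names(hp))] <- unname(hp)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
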