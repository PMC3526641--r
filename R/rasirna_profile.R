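## rasiRNA-like candidate selection and characterization. Candidates are
## the unannotated unique reads of 23-32 nt mapping to 1-5 discrete genomic
## loci; they are profiled by positional base composition (5'-uridine bias),
## chromosome-length-normalized abundance, and strand-resolved sliding-window
## densities alongside exon/repeat feature densities.

#' Select rasiRNA candidates
#'
#' Retains reads with length in `[min_len, max_len]`, category
#' `"unannotated"` and `min_loci <= n_loci <= max_loci`. The filter is
#' idempotent and order-independent.
#'
#' @param ar an `annotated_reads` object.
#' @param min_len,max_len length window (nt).
#' @param min_loci,max_loci locus-count window.
#' @return an `annotated_reads` object restricted to candidates (hits
#'   restricted accordingly); carries attribute `max_loci`.
#' @export
select_rasirna_candidates <- function(ar, min_len = 23L, max_len = 32L,
                                      min_loci = 1L, max_loci = 5L) {
  stopifnot(inherits(ar, "annotated_reads"))
  df <- ar$reads
  len <- nchar(df$sequence)
  keep <- len >= min_len & len <= max_len &
    df$category == "unannotated" &
    df$n_loci >= min_loci & df$n_loci <= max_loci
  idx <- which(keep)
  hits <- ar$hits[ar$hits$read %in% idx, , drop = FALSE]
  ## reindex hits to the filtered table
  hits$read <- match(hits$read, idx)
  reads <- df[idx, , drop = FALSE]
  rownames(reads) <- NULL
  out <- structure(list(reads = reads, hits = hits),
                   class = "annotated_reads")
  attr(out, "max_loci") <- max_loci
  out
}

#' Positional base composition and first-base U fraction
#'
#' Frequencies are computed over unique reads, unweighted by copy number;
#' position `k` is averaged over the reads of length `>= k`. Reported in the
#' RNA alphabet (T counted as U).
#'
#' @param candidates an `annotated_reads` object (typically from
#'   [select_rasirna_candidates()]).
#' @return list of class `positional_base_matrix`: `matrix` (positions x
#'   A/C/G/U frequencies), `coverage` (reads covering each position),
#'   `u1_fraction` (first-base U fraction; `NA` on empty input), `n_reads`.
#' @export
fivep_bias <- function(candidates) {
  stopifnot(inherits(candidates, "annotated_reads"))
  seqs <- candidates$reads$sequence
  bases <- c("A", "C", "G", "U")
  if (length(seqs) == 0L) {
    return(structure(list(matrix = matrix(numeric(0), ncol = 4,
                                          dimnames = list(NULL, bases)),
                          coverage = integer(0), u1_fraction = NA_real_,
                          n_reads = 0L),
                     class = "positional_base_matrix"))
  }
  L <- max(nchar(seqs))
  mat <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, bases))
  cov <- integer(L)
  split_seqs <- strsplit(seqs, "")
  for (s in split_seqs) {
    k <- length(s)
    cov[seq_len(k)] <- cov[seq_len(k)] + 1L
    u <- chartr("T", "U", s)
    for (p in seq_len(k)) mat[p, u[p]] <- mat[p, u[p]] + 1
  }
  freq <- mat / cov
  structure(list(matrix = freq, coverage = cov,
                 u1_fraction = unname(freq[1, "U"]), n_reads = length(seqs)),
            class = "positional_base_matrix")
}

## fractional per-chromosome (and optionally per-strand) attribution of
## candidate hits: each read contributes 1/n_loci per hit
.fractional_hits <- function(candidates) {
  hits <- candidates$hits
  if (nrow(hits) == 0L) return(hits[0, ])
  n_loci <- candidates$reads$n_loci[hits$read]
  hits$weight <- 1 / n_loci
  cc <- grep("^count", names(candidates$reads), value = TRUE)
  hits$copies <- if (length(cc) > 0L) {
    rowSums(candidates$reads[hits$read, cc, drop = FALSE])
  } else rep(1, nrow(hits))
  hits
}

#' Chromosome-normalized candidate distribution
#'
#' Multi-locus reads contribute `1/n_loci` to each hit chromosome.
#' Densities are reads per megabase of chromosome; both unique-read and
#' copy-number weightings are reported, together with the merged exon and
#' repeat base fractions of each chromosome.
#'
#' @param candidates an `annotated_reads` object.
#' @param genome named `DNAStringSet` (chromosome lengths).
#' @param tracks an `annotation_set` or `GRanges` with `category`.
#' @return data.frame, one row per chromosome: `chrom`, `length`,
#'   `n_unique`, `n_copies` (fractional counts), `density_unique`,
#'   `density_copies` (per Mb), `exon_base_fraction`,
#'   `repeat_base_fraction`.
#' @export
chrom_distribution <- function(candidates, genome, tracks) {
  gr <- if (inherits(tracks, "annotation_set")) tracks$tracks else tracks
  chroms <- names(genome)
  lens <- stats::setNames(Biostrings::width(genome), chroms)
  hits <- .fractional_hits(candidates)
  bad <- setdiff(unique(hits$chrom), chroms)
  if (length(bad) > 0L) {
    stop(sprintf("chromosome absent from genome: %s", paste(bad, collapse = ", ")))
  }
  nu <- nc <- stats::setNames(numeric(length(chroms)), chroms)
  if (nrow(hits) > 0L) {
    tu <- tapply(hits$weight, hits$chrom, sum)
    tc <- tapply(hits$weight * hits$copies, hits$chrom, sum)
    nu[names(tu)] <- tu; nc[names(tc)] <- tc
  }
  base_frac <- function(cats) {
    sel <- gr[gr$category %in% cats]
    out <- stats::setNames(numeric(length(chroms)), chroms)
    if (length(sel) > 0L) {
      red <- GenomicRanges::reduce(sel, ignore.strand = TRUE)
      tb <- tapply(GenomicRanges::width(red),
                   as.character(GenomicRanges::seqnames(red)), sum)
      out[names(tb)] <- tb
    }
    out / lens
  }
  data.frame(
    chrom = chroms, length = as.integer(lens),
    n_unique = as.numeric(nu), n_copies = as.numeric(nc),
    density_unique = as.numeric(nu / (lens / 1e6)),
    density_copies = as.numeric(nc / (lens / 1e6)),
    exon_base_fraction = as.numeric(base_frac("exon")),
    repeat_base_fraction = as.numeric(
      base_frac(c("LINE", "LTR", "satellite", "other_repeat"))),
    stringsAsFactors = FALSE)
}

## window grid anchored at 0: starts 0, step, 2*step, ... while < chrom_len;
## ends truncated at the chromosome end (partial final windows flagged)
.window_grid <- function(chrom_len, window_size, step) {
  if (step <= 0 || window_size < step) {
    stop("require window_size >= step > 0")
  }
  starts <- seq(0L, max(0L, chrom_len - 1L), by = step)
  ends <- pmin(starts + window_size, chrom_len)
  list(start = starts, end = ends, partial = (starts + window_size) > chrom_len)
}

#' Windowed base-coverage density of a feature track
#'
#' Overlapping feature intervals are merged (strand-agnostic) before
#' counting; each window's value is the fraction of its bases covered.
#' Windows are anchored at coordinate 0 and advance by `step`; final partial
#' windows are truncated and flagged.
#'
#' @param tracks an `annotation_set` or `GRanges` with `category`.
#' @param category feature categories to include (track vocabulary).
#' @param chrom chromosome name.
#' @param chrom_len chromosome length (nt).
#' @param window_size,step window geometry (nt).
#' @return object of class `density_track` (fields `chrom`, `window_start`
#'   0-based, `window_end`, `value`, `partial`, `strand = "both"`, `kind`).
#' @export
feature_density <- function(tracks, category, chrom, chrom_len,
                            window_size = 50000L, step = 1000L) {
  gr <- if (inherits(tracks, "annotation_set")) tracks$tracks else tracks
  g <- .window_grid(chrom_len, window_size, step)
  sel <- gr[gr$category %in% category &
              as.character(GenomicRanges::seqnames(gr)) == chrom]
  vals <- numeric(length(g$start))
  if (length(sel) > 0L) {
    red <- GenomicRanges::reduce(sel, ignore.strand = TRUE)
    rs <- GenomicRanges::start(red); re <- GenomicRanges::end(red)
    ## covered bases within [ws+1, we] (1-based closed) per window
    for (i in seq_along(g$start)) {
      lo <- g$start[i] + 1L; hi <- g$end[i]
      ov <- pmin(re, hi) - pmax(rs, lo) + 1L
      vals[i] <- sum(pmax(ov, 0L)) / (hi - lo + 1L)
    }
  }
  structure(list(chrom = chrom, window_start = g$start, window_end = g$end,
                 value = vals, partial = g$partial,
                 window_size = window_size, step = step,
                 strand = "both", kind = paste(category, collapse = "+")),
            class = "density_track")
}

#' Strand-resolved sliding-window read density
#'
#' A candidate read is counted in a window when its 5' end (strand-aware:
#' `start` on "+", `end` on "-") lies in `[window_start, window_end)`; each
#' hit is weighted `1/n_loci`. The weighting argument `weight` selects
#' unique-read (`"unique"`) or copy-number (`"copies"`) counting.
#'
#' @param candidates an `annotated_reads` object restricted to 1-5 loci
#'   (asserted).
#' @param chrom chromosome name.
#' @param strand `"+"`, `"-"` or `"both"`.
#' @param chrom_len chromosome length (nt).
#' @param window_size,step window geometry (nt).
#' @param weight `"unique"` or `"copies"`.
#' @return a `density_track`.
#' @export
read_density <- function(candidates, chrom, strand, chrom_len,
                         window_size = 5000L, step = 100L,
                         weight = c("unique", "copies")) {
  weight <- match.arg(weight)
  if (!strand %in% c("+", "-", "both")) {
    stop(sprintf("invalid strand symbol '%s'", strand))
  }
  max_loci <- attr(candidates, "max_loci")
  if (is.null(max_loci)) max_loci <- 5L
  if (nrow(candidates$reads) > 0L &&
      any(candidates$reads$n_loci < 1L | candidates$reads$n_loci > max_loci)) {
    stop("candidates must be restricted to the 1..max_loci window upstream")
  }
  g <- .window_grid(chrom_len, window_size, step)
  hits <- .fractional_hits(candidates)
  hits <- hits[hits$chrom == chrom, , drop = FALSE]
  if (strand != "both") hits <- hits[hits$strand == strand, , drop = FALSE]
  vals <- numeric(length(g$start))
  if (nrow(hits) > 0L) {
    p5 <- ifelse(hits$strand == "+", hits$start, hits$end)  # 1-based
    w <- if (weight == "unique") hits$weight else hits$weight * hits$copies
    for (i in seq_along(g$start)) {
      sel <- p5 > g$start[i] & p5 <= g$end[i]
      vals[i] <- sum(w[sel])
    }
  }
  structure(list(chrom = chrom, window_start = g$start, window_end = g$end,
                 value = vals, partial = g$partial,
                 window_size = window_size, step = step,
                 strand = strand, kind = "reads"),
            class = "density_track")
}
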