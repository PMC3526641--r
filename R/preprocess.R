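## Read cleaning and collapsing. Raw reads carry a 3' adapter; cleaning
## trims it, drops contaminants (adapter dimers / no insert, N-containing
## reads), low-quality reads (mean Phred below a floor) and inserts outside
## the length window, and reports a balanced accounting. Identical clean
## reads are then collapsed into unique families with copy counts.

#' Read a Sanger FASTQ file
#'
#' Minimal strict reader: every record must be 4 lines with `@`/`+` markers
#' and equal sequence/quality lengths; a malformed record aborts with its
#' record index.
#'
#' @param path FASTQ file.
#' @return list with `ids`, `reads`, `quals` character vectors.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  ## tolerate a single trailing empty line
  if (length(lines) > 0L && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) {
    return(list(ids = character(0), reads = character(0), quals = character(0)))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ: truncated record %d",
                 length(lines) %/% 4L + 1L))
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1, length(lines), 4)]
  seqs <- lines[seq(2, length(lines), 4)]
  plus <- lines[seq(3, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad) > 0L) {
    stop(sprintf("malformed FASTQ record %d in %s", bad[1], path))
  }
  list(ids = sub("^@", "", sub("\\s.*$", "", hdr)), reads = seqs, quals = quals)
}

#' Clean raw small-RNA reads
#'
#' The 3' adapter is located by an exact match of its first
#' `adapter_min_match` nucleotides; the read is trimmed at that point. Reads
#' with no adapter match are kept untrimmed. Discard rules, applied in
#' order: empty insert (adapter dimer / no insert) and N-containing inserts
#' are contaminants; mean Phred quality of the insert below `quality_floor`
#' is low quality; insert length outside `[min_len, max_len]` is a length
#' discard.
#'
#' @param x a FASTQ path, a [read_fastq()] list, or a `sim_library`.
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len retained insert length window (nt).
#' @param quality_floor minimum mean Phred quality (Sanger +33 encoding).
#' @param adapter_min_match minimum exact adapter prefix length.
#' @return list of class `clean_reads`: `reads`, `ids`, `quals` for the
#'   retained inserts and `report`, a `cleaning_report` with fields `n_raw`,
#'   `n_discarded_low_quality`, `n_discarded_contaminant`,
#'   `n_discarded_length`, `n_clean` and `length_histogram`.
#' @export
clean_reads <- function(x, adapter = archetype_defaults()$adapter,
                        min_len = 18L, max_len = 30L,
                        quality_floor = 20, adapter_min_match = 8L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (is.character(x) && length(x) == 1L) x <- read_fastq(x)
  ids <- x$ids; reads <- x$reads; quals <- x$quals
  n_raw <- length(reads)
  if (n_raw == 0L) {
    report <- structure(list(
      n_raw = 0L, n_discarded_low_quality = 0L,
      n_discarded_contaminant = 0L, n_discarded_length = 0L, n_clean = 0L,
      length_histogram = integer(0)), class = "cleaning_report")
    return(structure(list(reads = character(0), ids = character(0),
                          quals = character(0), report = report),
                     class = "clean_reads"))
  }

  key <- substr(adapter, 1L, adapter_min_match)
  pos <- as.integer(regexpr(key, reads, fixed = TRUE))
  ins_len <- ifelse(pos > 0L, pos - 1L, nchar(reads))
  inserts <- substr(reads, 1L, ins_len)
  iquals <- substr(quals, 1L, ins_len)

  mean_q <- vapply(iquals, function(q) {
    if (nchar(q) == 0L) return(0)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)

  is_contam <- ins_len == 0L | grepl("N", inserts, fixed = TRUE)
  is_lowq <- !is_contam & mean_q < quality_floor
  is_len <- !is_contam & !is_lowq & (ins_len < min_len | ins_len > max_len)
  keep <- !is_contam & !is_lowq & !is_len

  hist_clean <- table(factor(ins_len[keep], levels = min_len:max_len))
  report <- structure(list(
    n_raw = n_raw,
    n_discarded_low_quality = sum(is_lowq),
    n_discarded_contaminant = sum(is_contam),
    n_discarded_length = sum(is_len),
    n_clean = sum(keep),
    length_histogram = stats::setNames(as.integer(hist_clean),
                                       names(hist_clean))
  ), class = "cleaning_report")
  stopifnot(report$n_raw == report$n_clean + report$n_discarded_low_quality +
              report$n_discarded_contaminant + report$n_discarded_length)
  structure(list(reads = inserts[keep], ids = ids[keep],
                 quals = iquals[keep], report = report),
            class = "clean_reads")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "cleaning report: %d raw; %d clean (%.2f%%); discarded: %d low-quality, %d contaminant, %d length\n",
    x$n_raw, x$n_clean, if (x$n_raw > 0) 100 * x$n_clean / x$n_raw else 0,
    x$n_discarded_low_quality, x$n_discarded_contaminant,
    x$n_discarded_length))
  invisible(x)
}

#' Collapse identical reads into unique families
#'
#' @param reads character vector of clean reads, or a `clean_reads` object.
#' @param library_label label stored with the collection.
#' @return data.frame of class `unique_reads` with columns `sequence`,
#'   `count`, ordered by descending count then lexicographically.
#' @export
collapse_unique <- function(reads, library_label = "library") {
  if (inherits(reads, "clean_reads")) reads <- reads$reads
  if (length(reads) == 0L) {
    out <- data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    tab <- table(reads)
    out <- data.frame(sequence = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "library") <- library_label
  class(out) <- c("unique_reads", class(out))
  out
}

#' Merge per-library unique-read collections
#'
#' @param x named list of `unique_reads` (names become count column
#'   suffixes).
#' @return data.frame with `sequence` and one `count_<lib>` column per
#'   library, ordered by descending total count then sequence.
#' @export
merge_unique <- function(x) {
  stopifnot(is.list(x), length(x) > 0L, !is.null(names(x)))
  all_seq <- sort(unique(unlist(lapply(x, function(u) u$sequence))))
  out <- data.frame(sequence = all_seq, stringsAsFactors = FALSE)
  for (lib in names(x)) {
    m <- match(all_seq, x[[lib]]$sequence)
    out[[paste0("count_", lib)]] <- ifelse(is.na(m), 0L, x[[lib]]$count[m])
  }
  tot <- rowSums(out[, -1, drop = FALSE])
  out <- out[order(-tot, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write collapsed reads as FASTA with embedded counts
#'
#' Headers follow the `>u<rank>_<count>` dialect: rank in the collection,
#' then the copy count, separated by an underscore.
#'
#' @param ur a `unique_reads` data.frame.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(ur, path) {
  s <- Biostrings::DNAStringSet(ur$sequence)
  names(s) <- sprintf("u%d_%d", seq_len(nrow(ur)), ur$count)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
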