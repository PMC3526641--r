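#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so generator functions are deterministic without
#' clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Assert a scalar probability (or rate) lies in [0, 1].
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name))
  }
  x
}

## Normalize a non-negative weight vector to a probability vector,
## insisting it already sums to 1 within tolerance when strict.
check_mixture <- function(p, name, strict = TRUE) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0)) {
    stop(sprintf("'%s' must be non-negative and free of NA", name))
  }
  s <- sum(p)
  if (s <= 0) stop(sprintf("'%s' must have positive total weight", name))
  if (strict && abs(s - 1) > 1e-9) {
    stop(sprintf("'%s' must sum to 1 (got %.12f)", name, s))
  }
  p / s
}

## Fixed category vocabulary shared by the generator and annotator.
ANNOTATION_CATEGORIES <- c(
  "rRNA", "tRNA", "snRNA", "snoRNA", "miRNA_hairpin",
  "LINE", "LTR", "satellite", "other_repeat", "exon"
)

## Read categories the simulator can emit ("intergenic" has no track).
SOURCE_CATEGORIES <- c(ANNOTATION_CATEGORIES, "intergenic")

#' Write intervals as BED6
#'
#' @param gr a `GRanges` with a `name` metadata column (optional).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(gr, path) {
  if (length(gr) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  nm <- if (!is.null(gr$name)) gr$name else paste0("feat", seq_along(gr))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based; BED is 0-based
    end   = GenomicRanges::end(gr),
    name  = nm,
    score = 0L,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file into a GRanges
#'
#' @param path BED6 file (0-based, half-open).
#' @return a `GRanges` with `name` and `score` columns.
#' @export
read_bed6 <- function(path) {
  if (file.size(path) == 0L) {
    return(GenomicRanges::GRanges())
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end",
                                        "name", "score", "strand"))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"),
    name = df$name, score = df$score
  )
}

#' Write a windowed density track as bedGraph
#'
#' @param track a `density_track` (see [feature_density()], [read_density()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "density_track"))
  df <- data.frame(track$chrom, track$window_start,
                   track$window_end, track$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## sample() that treats a length-1 vector as a value, not as 1:n
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

## stop() unless all names are in the fixed vocabulary; names the offender.
check_categories <- function(x, vocab = ANNOTATION_CATEGORIES) {
  bad <- setdiff(unique(x), vocab)
  if (length(bad) > 0L) {
    stop(sprintf("unknown category: %s", paste(bad, collapse = ", ")))
  }
  invisible(x)
}
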