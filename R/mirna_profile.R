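## miRNA cataloguing: reads annotated as miRNA are clustered per mature
## locus into isomiR families, the most abundant member becomes the
## quantification reference, clusters are binned into seven confidence
## groups, and two libraries are compared feature-by-feature with the
## Audic-Claverie exact count statistic under Benjamini-Hochberg control.

#' Cluster miRNA reads into isomiR families per mature locus
#'
#' Each miRNA-annotated read is assigned to the mature locus its hits
#' overlap (same strand); a read overlapping several matures goes to the one
#' with the largest overlap, ties broken by mature (hairpin) order and
#' logged via `message()`. The reference isomiR of a cluster is the member
#' with maximal total count, ties broken by the lexicographically smallest
#' sequence.
#'
#' @param ar an `annotated_reads` object.
#' @param annots an `annotation_set` (supplies mature loci and pairing).
#' @return data.frame of class `isomir_clusters`: one row per member with
#'   `mature_id`, `hairpin_id`, `sequence`, count columns, `total_count`
#'   and `is_reference`.
#' @export
cluster_isomirs <- function(ar, annots) {
  stopifnot(inherits(ar, "annotated_reads"), inherits(annots, "annotation_set"))
  df <- ar$reads
  cc <- grep("^count", names(df), value = TRUE)
  mi <- which(df$category == "miRNA")
  empty <- data.frame(mature_id = character(0), hairpin_id = character(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  if (length(mi) == 0L || length(annots$mature) == 0L) {
    for (k in cc) empty[[k]] <- integer(0)
    empty$total_count <- integer(0); empty$is_reference <- logical(0)
    class(empty) <- c("isomir_clusters", class(empty))
    return(empty)
  }
  hits <- ar$hits[ar$hits$read %in% mi, , drop = FALSE]
  hit_gr <- GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    strand = hits$strand)
  ov <- GenomicRanges::findOverlaps(hit_gr, annots$mature, minoverlap = 1L,
                                    ignore.strand = FALSE)
  if (length(ov) == 0L) {
    for (k in cc) empty[[k]] <- integer(0)
    empty$total_count <- integer(0); empty$is_reference <- logical(0)
    class(empty) <- c("isomir_clusters", class(empty))
    return(empty)
  }
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ovw <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(hit_gr)[qh], GenomicRanges::ranges(annots$mature)[sh]))
  cand <- data.frame(read = hits$read[qh], mature = sh, ow = ovw)
  ## per read: mature with largest overlap, tie -> lowest mature index
  cand <- cand[order(cand$read, -cand$ow, cand$mature), , drop = FALSE]
  multi <- tapply(cand$mature, cand$read, function(m) length(unique(m)))
  n_multi <- sum(multi > 1L)
  if (n_multi > 0L) {
    message(sprintf("cluster_isomirs: %d read(s) overlapped >1 mature locus; assigned by largest overlap", n_multi))
  }
  pick <- cand[!duplicated(cand$read), , drop = FALSE]

  mature_id <- annots$mature$name[pick$mature]
  hairpin_id <- annots$mirna$hairpin_id[
    match(mature_id, annots$mirna$mature_id)]
  out <- data.frame(mature_id = mature_id, hairpin_id = hairpin_id,
                    sequence = df$sequence[pick$read],
                    stringsAsFactors = FALSE)
  for (k in cc) out[[k]] <- df[[k]][pick$read]
  out$total_count <- as.integer(rowSums(out[, cc, drop = FALSE]))
  ## reference per cluster: max total count, tie -> lexicographically least
  out <- out[order(out$mature_id, -out$total_count, out$sequence), ,
             drop = FALSE]
  out$is_reference <- !duplicated(out$mature_id)
  rownames(out) <- NULL
  class(out) <- c("isomir_clusters", class(out))
  out
}

#' Seven-group confidence classification of miRNA clusters
#'
#' A reconstruction of the conventional high-to-mid confidence binning of
#' small-RNA-seq miRNA catalogues; the decision table (applied to each
#' cluster's reference sequence) is:
#' \itemize{
#'   \item gp1a: exactly matches a known mature sequence.
#'   \item gp1b: lies on a known hairpin, overlapping the annotated mature
#'     region but not identical to it (end-shifted variant).
#'   \item gp2a: within two 3'-end shifts of a known mature whose hairpin is
#'     not available.
#'   \item gp2b: antisense of a known mature or hairpin.
#'   \item gp3a: on a known hairpin, same arm as the mature but not
#'     overlapping it.
#'   \item gp3b: on a known hairpin, loop or opposite (star) arm.
#'   \item gp4a: none of the above (candidate novel).
#' }
#'
#' @param clusters an `isomir_clusters` data.frame.
#' @param mature_seq named character vector / `DNAStringSet` of known mature
#'   sequences (DNA alphabet).
#' @param hairpin_seq named known hairpin sequences; names must contain the
#'   mature's hairpin when pairing is known.
#' @param pairing optional data.frame (`hairpin_id`, `mature_id`) linking
#'   the two sets; defaults to pairing by shared order.
#' @return data.frame: one row per cluster (`mature_id`, `hairpin_id`,
#'   `reference_sequence`, `group`).
#' @export
classify_seven_groups <- function(clusters, mature_seq, hairpin_seq,
                                  pairing = NULL) {
  mature_seq <- stats::setNames(as.character(mature_seq), names(mature_seq))
  hairpin_seq <- stats::setNames(as.character(hairpin_seq),
                                 names(hairpin_seq))
  refs <- clusters[clusters$is_reference, , drop = FALSE]
  if (nrow(refs) == 0L) {
    return(data.frame(mature_id = character(0), hairpin_id = character(0),
                      reference_sequence = character(0), group = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(pairing) && !is.null(names(mature_seq)) &&
      !is.null(names(hairpin_seq)) &&
      length(mature_seq) == length(hairpin_seq)) {
    pairing <- data.frame(hairpin_id = names(hairpin_seq),
                          mature_id = names(mature_seq),
                          stringsAsFactors = FALSE)
  }

  ## position of the annotated mature within each hairpin (5'-anchored)
  mat_pos <- rep(NA_integer_, length(hairpin_seq))
  mat_len <- rep(NA_integer_, length(hairpin_seq))
  if (!is.null(pairing)) {
    for (i in seq_len(nrow(pairing))) {
      hs <- hairpin_seq[[pairing$hairpin_id[i]]]
      ms <- mature_seq[[pairing$mature_id[i]]]
      p <- regexpr(ms, hs, fixed = TRUE)
      if (p > 0) {
        j <- match(pairing$hairpin_id[i], names(hairpin_seq))
        mat_pos[j] <- as.integer(p)
        mat_len[j] <- nchar(ms)
      }
    }
  }

  ## does r sit within <=2 3'-end shifts of mature m? (5' ends equal,
  ## 3' end trimmed or extended by at most 2 relative to m, judged on the
  ## sequences alone via prefix relations)
  shift3_match <- function(r, m) {
    lr <- nchar(r); lm <- nchar(m)
    if (abs(lr - lm) > 2L) return(FALSE)
    if (lr <= lm) startsWith(m, r) else startsWith(r, m)
  }

  grp <- character(nrow(refs))
  for (i in seq_len(nrow(refs))) {
    r <- refs$sequence[i]
    if (r %in% mature_seq) { grp[i] <- "gp1a"; next }
    hp_hit <- which(vapply(hairpin_seq, function(h) {
      grepl(r, h, fixed = TRUE)
    }, logical(1)))
    if (length(hp_hit) > 0L) {
      j <- hp_hit[1]
      h <- hairpin_seq[[j]]
      p <- as.integer(regexpr(r, h, fixed = TRUE))
      if (!is.na(mat_pos[j])) {
        ms <- mat_pos[j]; me <- mat_pos[j] + mat_len[j] - 1L
        rs <- p; re <- p + nchar(r) - 1L
        if (re >= ms && rs <= me) { grp[i] <- "gp1b"; next }
        ## same arm = same side of the hairpin midpoint as the mature
        mid <- nchar(h) / 2
        same_arm <- ((ms + me) / 2 <= mid) == ((rs + re) / 2 <= mid)
        grp[i] <- if (same_arm) "gp3a" else "gp3b"
        next
      }
      grp[i] <- "gp3b"; next
    }
    if (any(vapply(mature_seq, function(m) shift3_match(r, m), logical(1)))) {
      grp[i] <- "gp2a"; next
    }
    rc <- revcomp(r)
    anti <- rc %in% mature_seq ||
      any(vapply(hairpin_seq, function(h) grepl(rc, h, fixed = TRUE),
                 logical(1)))
    grp[i] <- if (anti) "gp2b" else "gp4a"
  }
  data.frame(mature_id = refs$mature_id, hairpin_id = refs$hairpin_id,
             reference_sequence = refs$sequence, group = grp,
             stringsAsFactors = FALSE)
}

#' Seven-group summary in a catalogue-table layout
#'
#' For each group and each library, reports the number of expressed mature
#' miRNAs (`matures_<lib>`, clusters with nonzero count in that library) and
#' of their distinct hairpins (`hairpins_<lib>`). Both columns are emitted
#' and labelled explicitly.
#'
#' @param clusters an `isomir_clusters` data.frame.
#' @param groups output of [classify_seven_groups()].
#' @return data.frame, one row per group `gp1a..gp4a`.
#' @export
group_table <- function(clusters, groups) {
  cc <- grep("^count", names(clusters), value = TRUE)
  libs <- sub("^count_?", "", cc)
  libs[libs == ""] <- "library"
  lev <- c("gp1a", "gp1b", "gp2a", "gp2b", "gp3a", "gp3b", "gp4a")
  out <- data.frame(group = lev, stringsAsFactors = FALSE)
  for (k in seq_along(cc)) {
    per_cluster <- tapply(clusters[[cc[k]]], clusters$mature_id, sum)
    expressed <- names(per_cluster)[per_cluster > 0]
    g <- groups[groups$mature_id %in% expressed, , drop = FALSE]
    out[[paste0("matures_", libs[k])]] <-
      as.integer(table(factor(g$group, levels = lev)))
    hp <- tapply(g$hairpin_id, factor(g$group, levels = lev),
                 function(x) length(unique(x)))
    hp[is.na(hp)] <- 0L
    out[[paste0("hairpins_", libs[k])]] <- as.integer(hp)
  }
  out
}

#' Counts-per-million normalization
#'
#' @param counts non-negative counts.
#' @param library_total positive library size.
#' @return `counts / library_total * 1e6`.
#' @export
normalize_cpm <- function(counts, library_total) {
  if (!is.numeric(library_total) || length(library_total) != 1L ||
      is.na(library_total) || library_total <= 0) {
    stop("library_total must be a single positive number")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  counts / library_total * 1e6
}

#' Audic-Claverie exact test for two observed counts
#'
#' Compares a feature's count `x` in library A (total `n_a`) with `y` in
#' library B (total `n_b`). Under the Audic-Claverie model the conditional
#' law of `y` given `x` is negative binomial with size `x + 1` and success
#' probability `n_a / (n_a + n_b)`; tails are evaluated in log space via
#' `pnbinom`. The two-sided p-value is `min(1, 2 * m)` where `m` is the
#' smallest of the four tail probabilities obtained from both conditioning
#' orientations, which makes the statistic exactly symmetric under the
#' simultaneous swap `(x, n_a) <-> (y, n_b)`.
#'
#' @param x,y non-negative integer counts.
#' @param n_a,n_b positive library totals.
#' @return two-sided p-value in `(0, 1]` (underflow is clamped to the
#'   smallest positive double).
#' @export
audic_claverie_test <- function(x, y, n_a, n_b) {
  if (any(c(x, y) < 0)) stop("counts must be non-negative")
  if (any(c(n_a, n_b) <= 0)) stop("library totals must be positive")
  if (any(c(x, y) != round(c(x, y)))) stop("counts must be integers")
  p_a <- n_a / (n_a + n_b)
  p_b <- n_b / (n_a + n_b)
  ## orientation 1: y | x ~ NB(x + 1, p_a)
  lo_xy <- stats::pnbinom(y, size = x + 1, prob = p_a)
  up_xy <- stats::pnbinom(y - 1, size = x + 1, prob = p_a,
                          lower.tail = FALSE)
  ## orientation 2: x | y ~ NB(y + 1, p_b)
  lo_yx <- stats::pnbinom(x, size = y + 1, prob = p_b)
  up_yx <- stats::pnbinom(x - 1, size = y + 1, prob = p_b,
                          lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lo_xy, up_xy, lo_yx, up_yx))
  pmax(p, .Machine$double.xmin)
}

#' Differential expression table for two libraries
#'
#' One row per cluster (mature miRNA); member counts are summed per library,
#' normalized to counts per million of the given totals, tested with
#' [audic_claverie_test()] and adjusted by Benjamini-Hochberg.
#'
#' @param clusters an `isomir_clusters` data.frame carrying `count_<a>` and
#'   `count_<b>` columns.
#' @param lib_a,lib_b library labels (count column suffixes).
#' @param total_a,total_b normalization totals (by convention the number of
#'   clean reads per library); default to the summed miRNA counts.
#' @param alpha significance level used for the `significant` flag.
#' @return data.frame of class `de_table`, sorted by p-value: `mature_id`,
#'   `count_a`, `count_b`, `norm_a`, `norm_b`, `p_value`, `fdr`,
#'   `direction` (`"up"` means higher in B), `significant`.
#' @export
differential_table <- function(clusters, lib_a, lib_b,
                               total_a = NULL, total_b = NULL, alpha = 0.05) {
  ca <- paste0("count_", lib_a); cb <- paste0("count_", lib_b)
  if (!all(c(ca, cb) %in% names(clusters))) {
    stop(sprintf("clusters lack count columns for '%s'/'%s'", lib_a, lib_b))
  }
  xa <- tapply(clusters[[ca]], clusters$mature_id, sum)
  xb <- tapply(clusters[[cb]], clusters$mature_id, sum)
  ids <- names(xa)
  xa <- as.integer(xa); xb <- as.integer(xb[ids])
  expressed <- xa + xb > 0
  ids <- ids[expressed]; xa <- xa[expressed]; xb <- xb[expressed]
  if (is.null(total_a)) total_a <- max(sum(xa), 1L)
  if (is.null(total_b)) total_b <- max(sum(xb), 1L)
  if (length(ids) == 0L) {
    return(structure(data.frame(mature_id = character(0), count_a = integer(0),
                                count_b = integer(0), norm_a = numeric(0),
                                norm_b = numeric(0), p_value = numeric(0),
                                fdr = numeric(0), direction = character(0),
                                significant = logical(0)),
                     class = c("de_table", "data.frame")))
  }
  p <- audic_claverie_test(xa, xb, total_a, total_b)
  na <- normalize_cpm(xa, total_a); nb <- normalize_cpm(xb, total_b)
  out <- data.frame(
    mature_id = ids, count_a = xa, count_b = xb,
    norm_a = na, norm_b = nb, p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    direction = ifelse(nb > na, "up", ifelse(nb < na, "down", "none")),
    stringsAsFactors = FALSE)
  out$significant <- out$fdr < alpha
  out <- out[order(out$p_value, out$mature_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_table", class(out))
  out
}
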