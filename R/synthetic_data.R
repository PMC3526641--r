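## Synthetic-data generator: toy genome, annotation tracks and small-RNA
## libraries with ground-truth labels. The three library archetypes emulate
## the structure typical of germline small-RNA sequencing: an ovary-like
## library dominated by 22 nt miRNAs, a testis-like library with a bimodal
## 24/27 nt length profile, a large repeat-derived fraction and 5'-uridine
## bias, and an IP-like library (small RNAs co-purified with a PIWI protein)
## peaking at 24-25 nt with miRNAs depleted.

#' Specify a toy genome
#'
#' @param chrom_names character vector of chromosome labels.
#' @param chrom_lengths integer vector of lengths (nt), same length as
#'   `chrom_names`, all positive.
#' @param gc_fraction target GC content in `[0, 1]`.
#' @param seed integer seed; identical specs yield identical genomes.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_names = c("chr1", "chr2", "chr3", "chrZ", "chrW"),
                        chrom_lengths = c(300000L, 200000L, 150000L,
                                          120000L, 80000L),
                        gc_fraction = 0.42,
                        seed = 1L) {
  if (length(chrom_names) != length(chrom_lengths)) {
    stop("'chrom_names' and 'chrom_lengths' must have equal length")
  }
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (!is.numeric(chrom_lengths) || any(is.na(chrom_lengths)) ||
      any(chrom_lengths <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  check_prob(gc_fraction, "gc_fraction")
  structure(
    list(chrom_names = as.character(chrom_names),
         chrom_lengths = as.integer(chrom_lengths),
         gc_fraction = gc_fraction,
         seed = as.integer(seed)),
    class = "genome_spec"
  )
}

#' Generate a toy genome
#'
#' Draws each base independently with per-base probabilities
#' `((1-gc)/2, gc/2, gc/2, (1-gc)/2)` for A, C, G, T.
#'
#' @param spec a [genome_spec()].
#' @param out_fasta optional path; when given, the genome is also written as
#'   FASTA.
#' @return a named [Biostrings::DNAStringSet].
#' @export
make_genome <- function(spec, out_fasta = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  gc <- spec$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(spec$seed, {
    vapply(spec$chrom_lengths, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- spec$chrom_names
  if (!is.null(out_fasta)) {
    Biostrings::writeXStringSet(genome, out_fasta, width = 70L)
  }
  genome
}

#' Specify annotation tracks for a toy genome
#'
#' For each category a number of intervals and a length range are requested.
#' Repeat intervals (LINE, LTR, satellite, other_repeat) can be placed with
#' per-chromosome weights, which is how a repeat-loaded sex chromosome is
#' emulated.
#'
#' @param counts named integer vector over the category vocabulary
#'   (rRNA, tRNA, snRNA, snoRNA, miRNA_hairpin, LINE, LTR, satellite,
#'   other_repeat, exon); missing names default to 0.
#' @param length_ranges named list of `c(min, max)` interval lengths.
#' @param repeat_chrom_weights optional named numeric vector of placement
#'   weights for repeat categories (names = chromosomes); `NULL` weights all
#'   chromosomes by length.
#' @param mature_len_range `c(min, max)` mature miRNA length inside a hairpin.
#' @param seed integer seed.
#' @return an object of class `annotation_spec`.
#' @export
annotation_spec <- function(counts = c(rRNA = 12L, tRNA = 40L, snRNA = 20L,
                                       snoRNA = 20L, miRNA_hairpin = 120L,
                                       LINE = 60L, LTR = 40L, satellite = 30L,
                                       other_repeat = 30L, exon = 150L),
                            length_ranges = list(
                              rRNA = c(120L, 1500L), tRNA = c(70L, 90L),
                              snRNA = c(100L, 300L), snoRNA = c(60L, 200L),
                              miRNA_hairpin = c(70L, 100L),
                              LINE = c(300L, 800L), LTR = c(200L, 600L),
                              satellite = c(150L, 500L),
                              other_repeat = c(100L, 400L),
                              exon = c(100L, 300L)),
                            repeat_chrom_weights = c(chr1 = 0.07, chr2 = 0.07,
                                                     chr3 = 0.06, chrZ = 0.25,
                                                     chrW = 0.55),
                            mature_len_range = c(20L, 23L),
                            seed = 1L) {
  check_categories(names(counts))
  check_categories(names(length_ranges))
  full <- stats::setNames(integer(length(ANNOTATION_CATEGORIES)),
                          ANNOTATION_CATEGORIES)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("interval counts must be non-negative")
  for (cat in names(length_ranges)) {
    lr <- length_ranges[[cat]]
    if (length(lr) != 2L || lr[1] <= 0 || lr[2] < lr[1]) {
      stop(sprintf("invalid length range for %s", cat))
    }
  }
  structure(
    list(counts = full, length_ranges = length_ranges,
         repeat_chrom_weights = repeat_chrom_weights,
         mature_len_range = as.integer(mature_len_range),
         seed = as.integer(seed)),
    class = "annotation_spec"
  )
}

REPEAT_CATEGORIES <- c("LINE", "LTR", "satellite", "other_repeat")

#' Generate annotation tracks and a miRNA reference for a toy genome
#'
#' Intervals are placed uniformly (repeats optionally with per-chromosome
#' weights), strands alternate at random, and every mature miRNA is an exact
#' subsequence of its hairpin (both are cut from the same genomic strand).
#'
#' @param genome a named [Biostrings::DNAStringSet] from [make_genome()].
#' @param spec an [annotation_spec()].
#' @param out_dir optional directory; when given, one BED6 file per category
#'   plus `hairpin.fa` / `mature.fa` are written.
#' @return an object of class `annotation_set`: list with `tracks` (a
#'   `GRanges` with `category` and `name` columns), `mirna` (data.frame of
#'   hairpin/mature pairing), `hairpin_seq` and `mature_seq`
#'   (`DNAStringSet`s).
#' @export
make_annotations <- function(genome, spec, out_dir = NULL) {
  stopifnot(inherits(spec, "annotation_spec"))
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))

  place <- function(cat, n) {
    if (n == 0L) return(NULL)
    lr <- spec$length_ranges[[cat]]
    if (is.null(lr)) stop(sprintf("no length range for category %s", cat))
    if (lr[2] > max(chrom_len)) {
      stop(sprintf("requested %s interval length %d exceeds the longest chromosome (%d)",
                   cat, lr[2], max(chrom_len)))
    }
    w <- if (cat %in% REPEAT_CATEGORIES && !is.null(spec$repeat_chrom_weights)) {
      wt <- spec$repeat_chrom_weights[names(chrom_len)]
      wt[is.na(wt)] <- 0
      wt
    } else {
      chrom_len / sum(chrom_len)
    }
    lens <- resample(seq(lr[1], lr[2]), n, replace = TRUE)
    chroms <- character(n); starts <- integer(n)
    for (i in seq_len(n)) {
      ok <- chrom_len >= lens[i]
      if (!any(ok)) stop(sprintf("%s interval of %d nt fits no chromosome",
                                 cat, lens[i]))
      wi <- w * ok
      ch <- sample(names(chrom_len), 1L, prob = wi / sum(wi))
      chroms[i] <- ch
      starts[i] <- sample.int(chrom_len[[ch]] - lens[i] + 1L, 1L)
    }
    GenomicRanges::GRanges(
      seqnames = chroms,
      ranges = IRanges::IRanges(start = starts, width = lens),
      strand = sample(c("+", "-"), n, replace = TRUE),
      category = cat,
      name = sprintf("%s_%03d", cat, seq_len(n))
    )
  }

  with_seed(spec$seed, {
    parts <- lapply(ANNOTATION_CATEGORIES, function(cat) {
      place(cat, spec$counts[[cat]])
    })
    tracks <- do.call(c, c(parts[!vapply(parts, is.null, logical(1))],
                           list(GenomicRanges::GRanges())))

    ## Mature miRNAs: one per hairpin, an internal window of the hairpin on
    ## the hairpin's own strand, so mature is a substring of the hairpin.
    hp <- tracks[tracks$category == "miRNA_hairpin"]
    mirna <- NULL
    mature_gr <- GenomicRanges::GRanges()
    if (length(hp) > 0L) {
      mlr <- spec$mature_len_range
      mlen <- resample(seq(mlr[1], mlr[2]), length(hp), replace = TRUE)
      off <- vapply(seq_along(hp), function(i) {
        sample.int(GenomicRanges::width(hp)[i] - mlen[i] + 1L, 1L) - 1L
      }, integer(1))
      ## offset is measured from the hairpin's 5' end, i.e. from the left on
      ## "+" hairpins and from the right on "-" hairpins
      plus <- as.character(GenomicRanges::strand(hp)) == "+"
      mstart <- ifelse(plus,
                       GenomicRanges::start(hp) + off,
                       GenomicRanges::end(hp) - off - mlen + 1L)
      mature_gr <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(hp),
        ranges = IRanges::IRanges(start = mstart, width = mlen),
        strand = GenomicRanges::strand(hp),
        category = "miRNA_mature",
        name = sprintf("mir-%03d", seq_along(hp))
      )
      mirna <- data.frame(hairpin_id = hp$name,
                          mature_id = mature_gr$name,
                          stringsAsFactors = FALSE)
    }

    extract <- function(gr) {
      if (length(gr) == 0L) return(Biostrings::DNAStringSet())
      s <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
        ch <- as.character(GenomicRanges::seqnames(gr))[i]
        x <- as.character(Biostrings::subseq(
          genome[[ch]], GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))
        if (as.character(GenomicRanges::strand(gr))[i] == "-") revcomp(x) else x
      }, character(1)))
      names(s) <- gr$name
      s
    }
    hairpin_seq <- extract(hp)
    mature_seq <- extract(mature_gr)

    out <- structure(
      list(tracks = tracks, mature = mature_gr, mirna = mirna,
           hairpin_seq = hairpin_seq, mature_seq = mature_seq),
      class = "annotation_set"
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (cat in ANNOTATION_CATEGORIES) {
        write_bed6(tracks[tracks$category == cat],
                   file.path(out_dir, paste0(cat, ".bed")))
      }
      write_bed6(mature_gr, file.path(out_dir, "miRNA_mature.bed"))
      Biostrings::writeXStringSet(hairpin_seq, file.path(out_dir, "hairpin.fa"))
      Biostrings::writeXStringSet(mature_seq, file.path(out_dir, "mature.fa"))
    }
    out
  })
}

#' Load the versioned default archetype parameters
#'
#' @return the parsed configuration list.
#' @export
archetype_defaults <- function() {
  path <- system.file("extdata", "archetype_defaults.json", package = "srnakit")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Build a library archetype
#'
#' @param name one of `"ovary_like"`, `"testis_like"`, `"ip_like"`.
#' @param n_reads number of raw reads to emit.
#' @param seed integer seed.
#' @param ... overrides for any archetype field (`length_mixture` over
#'   18-32 nt, `category_mixture`, `fivep_u_bias`, `isomir_shift_probs`,
#'   `adapter_dimer_rate`, `low_quality_rate`, `adapter`).
#' @return an object of class `library_archetype`.
#' @export
library_archetype <- function(name = c("ovary_like", "testis_like", "ip_like"),
                              n_reads = 50000L, seed = 1L, ...) {
  name <- match.arg(name)
  cfg <- archetype_defaults()
  a <- cfg$archetypes[[name]]
  arch <- list(
    name = name,
    lengths = as.integer(cfg$lengths),
    length_mixture = as.numeric(a$length_mixture),
    category_mixture = unlist(a$category_mixture),
    fivep_u_bias = a$fivep_u_bias,
    isomir_offsets = as.integer(cfg$isomir_shift_probs$offsets),
    isomir_shift_probs = as.numeric(cfg$isomir_shift_probs$probs),
    adapter_dimer_rate = a$adapter_dimer_rate,
    low_quality_rate = a$low_quality_rate,
    adapter = cfg$adapter,
    n_reads = as.integer(n_reads),
    seed = as.integer(seed)
  )
  dots <- list(...)
  for (k in names(dots)) {
    if (!k %in% names(arch)) stop(sprintf("unknown archetype field '%s'", k))
    arch[[k]] <- dots[[k]]
  }
  arch$length_mixture <- check_mixture(arch$length_mixture, "length_mixture")
  arch$category_mixture <- check_mixture(arch$category_mixture,
                                         "category_mixture")
  check_categories(names(arch$category_mixture), SOURCE_CATEGORIES)
  arch$isomir_shift_probs <- check_mixture(arch$isomir_shift_probs,
                                           "isomir_shift_probs")
  check_prob(arch$fivep_u_bias, "fivep_u_bias")
  check_prob(arch$adapter_dimer_rate, "adapter_dimer_rate")
  check_prob(arch$low_quality_rate, "low_quality_rate")
  if (length(arch$length_mixture) != length(arch$lengths)) {
    stop("length_mixture must have one entry per length 18..32")
  }
  structure(arch, class = "library_archetype")
}

## Categories whose reads receive the 5'-uridine bias treatment: repeats and
## intergenic space (the rasiRNA-like compartment).
BIASED_CATEGORIES <- c(REPEAT_CATEGORIES, "intergenic")

#' Simulate one small-RNA library
#'
#' Emits raw reads (insert plus 3' adapter) with Sanger-encoded qualities and
#' a ground-truth table. Reads are drawn category-first from the archetype's
#' mixtures; miRNA reads come from mature loci with isomiR end-offsets under
#' log-normal per-mature expression weights; repeat and intergenic reads have
#' their first (5', strand-aware) base constrained so that the marginal
#' probability of starting with uridine equals `fivep_u_bias`. Intergenic
#' reads are placed on chromosomes with probability proportional to annotated
#' repeat bases (plus a floor), emulating the concentration of unannotated
#' germline small RNAs on repeat-rich sex chromosomes. Contaminant reads
#' (adapter dimers, low-quality reads) are flagged in the truth table.
#'
#' @param genome a named `DNAStringSet`.
#' @param annots an `annotation_set` from [make_annotations()].
#' @param archetype a [library_archetype()].
#' @param out_fastq,out_truth optional output paths (FASTQ / TSV).
#' @return list with `reads` (character), `quals` (character), `ids`,
#'   and `truth` (data.frame: read_id, category, chrom, start, end, strand,
#'   intended_length, contamination), class `sim_library`.
#' @export
simulate_library <- function(genome, annots, archetype,
                             out_fastq = NULL, out_truth = NULL) {
  stopifnot(inherits(archetype, "library_archetype"),
            inherits(annots, "annotation_set"))
  mix <- archetype$category_mixture
  tracks <- annots$tracks
  for (cat in names(mix)[mix > 0]) {
    if (cat == "intergenic") next
    if (sum(tracks$category == cat) == 0L) {
      stop(sprintf("category '%s' has positive weight but no intervals", cat))
    }
  }
  if (isTRUE(mix["miRNA_hairpin"] > 0) && length(annots$mature) == 0L) {
    stop("category 'miRNA_hairpin' has positive weight but no mature loci")
  }

  n <- archetype$n_reads
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  chrom_seq <- lapply(seq_along(genome), function(i) {
    strsplit(as.character(genome[[i]]), "")[[1]]
  })
  names(chrom_seq) <- names(genome)

  ## intergenic chromosome weights: repeat bases + 5% floor; intergenic
  ## reads emulate unannotated (rasiRNA-like) loci, which concentrate on
  ## repeat-rich chromosomes while avoiding the annotated intervals proper
  rep_gr <- tracks[tracks$category %in% REPEAT_CATEGORIES]
  rep_bases <- stats::setNames(numeric(length(genome)), names(genome))
  if (length(rep_gr) > 0L) {
    red <- GenomicRanges::reduce(rep_gr, ignore.strand = TRUE)
    tb <- tapply(GenomicRanges::width(red),
                 as.character(GenomicRanges::seqnames(red)), sum)
    rep_bases[names(tb)] <- tb
  }
  ig_w <- rep_bases + 0.05 * sum(chrom_len)
  ig_w <- ig_w / sum(ig_w)

  ## merged annotated intervals per chromosome, for rejection sampling of
  ## intergenic read placements (sorted, non-overlapping)
  ann_iv <- lapply(stats::setNames(nm = names(genome)), function(ch) {
    sel <- tracks[as.character(GenomicRanges::seqnames(tracks)) == ch]
    if (length(sel) == 0L) return(list(start = integer(0), end = integer(0)))
    red <- GenomicRanges::reduce(sel, ignore.strand = TRUE)
    red <- red[order(GenomicRanges::start(red))]
    list(start = GenomicRanges::start(red), end = GenomicRanges::end(red))
  })
  overlaps_annotation <- function(ch, s, e) {
    iv <- ann_iv[[ch]]
    if (length(iv$start) == 0L) return(FALSE)
    k <- findInterval(e, iv$start)
    k >= 1L && iv$end[k] >= s
  }

  empty_truth <- data.frame(
    read_id = character(0), category = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    intended_length = integer(0), contamination = character(0),
    stringsAsFactors = FALSE)

  ## plain-vector views of the tracks for the per-read loop
  trk <- list(
    chrom = as.character(GenomicRanges::seqnames(tracks)),
    start = GenomicRanges::start(tracks),
    end = GenomicRanges::end(tracks),
    strand = as.character(GenomicRanges::strand(tracks)),
    cat = tracks$category, name = tracks$name
  )
  mat <- list(
    chrom = as.character(GenomicRanges::seqnames(annots$mature)),
    start = GenomicRanges::start(annots$mature),
    end = GenomicRanges::end(annots$mature),
    strand = as.character(GenomicRanges::strand(annots$mature))
  )
  hp_row <- if (!is.null(annots$mirna)) {
    match(annots$mirna$hairpin_id, trk$name)  # mature j -> hairpin track row
  } else integer(0)
  COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

  res <- with_seed(archetype$seed, {
    if (n == 0L) {
      return(list(reads = character(0), quals = character(0),
                  ids = character(0), truth = empty_truth))
    }
    n_mature <- length(mat$chrom)
    expr_w <- if (n_mature > 0L) {
      w <- stats::rlnorm(n_mature, meanlog = 0, sdlog = 1.5)
      w / sum(w)
    } else numeric(0)

    u <- stats::runif(n)
    contam <- ifelse(u < archetype$adapter_dimer_rate, "adapter_dimer",
              ifelse(u < archetype$adapter_dimer_rate +
                       archetype$low_quality_rate, "low_quality", "none"))
    cats <- sample(names(mix), n, replace = TRUE, prob = mix)
    lens <- sample(archetype$lengths, n, replace = TRUE,
                   prob = archetype$length_mixture)
    force_u <- cats %in% BIASED_CATEGORIES &
      stats::runif(n) < archetype$fivep_u_bias

    cat_idx <- lapply(stats::setNames(nm = ANNOTATION_CATEGORIES),
                      function(cat) which(trk$cat == cat))

    seq_out <- character(n)
    chrom <- rep(NA_character_, n); start <- rep(NA_integer_, n)
    end <- rep(NA_integer_, n); strand <- rep(NA_character_, n)

    ## strand-aware 5' base of a candidate placement
    first_base <- function(ch, s, e, str) {
      if (str == "+") chrom_seq[[ch]][s] else COMP[[chrom_seq[[ch]][e]]]
    }

    for (i in seq_len(n)) {
      if (contam[i] == "adapter_dimer") next
      cat <- cats[i]
      if (cat == "miRNA_hairpin") {
        j <- sample.int(n_mature, 1L, prob = expr_w)
        k <- hp_row[j]
        off5 <- sample(archetype$isomir_offsets, 1L,
                       prob = archetype$isomir_shift_probs)
        off3 <- sample(archetype$isomir_offsets, 1L,
                       prob = archetype$isomir_shift_probs)
        str <- mat$strand[j]
        if (str == "+") {
          s <- mat$start[j] + off5
          e <- mat$end[j] + off3
        } else {
          s <- mat$start[j] - off3
          e <- mat$end[j] - off5
        }
        s <- max(s, trk$start[k])
        e <- min(e, trk$end[k])
        ch <- mat$chrom[j]
      } else {
        L <- lens[i]
        if (cat == "intergenic") {
          ch <- sample(names(chrom_len), 1L, prob = ig_w)
          for (try in 1:80) {
            s <- sample.int(chrom_len[[ch]] - L + 1L, 1L)
            e <- s + L - 1L
            str <- sample(c("+", "-"), 1L)
            if (overlaps_annotation(ch, s, e)) next
            if ((first_base(ch, s, e, str) == "T") == force_u[i]) break
          }
        } else {
          idx <- cat_idx[[cat]]
          k <- idx[sample.int(length(idx), 1L)]
          iv_s <- trk$start[k]
          iv_e <- trk$end[k]
          Li <- min(L, iv_e - iv_s + 1L)
          ch <- trk$chrom[k]
          str <- trk$strand[k]
          draw <- function() iv_s + sample.int(iv_e - iv_s - Li + 2L, 1L) - 1L
          s <- draw(); e <- s + Li - 1L
          if (cat %in% BIASED_CATEGORIES) {
            for (try in 1:40) {
              hit_u <- first_base(ch, s, e, str) == "T"
              if (hit_u == force_u[i]) break
              s <- draw(); e <- s + Li - 1L
            }
          }
        }
      }
      chars <- chrom_seq[[ch]][s:e]
      if (str == "-") chars <- rev(COMP[chars])
      seq_out[i] <- paste(chars, collapse = "")
      chrom[i] <- ch; start[i] <- s; end[i] <- e; strand[i] <- str
    }

    ids <- sprintf("read%07d", seq_len(n))
    adapter <- archetype$adapter
    raw <- ifelse(contam == "adapter_dimer", adapter,
                  paste0(seq_out, adapter))
    qual <- vapply(seq_len(n), function(i) {
      L <- nchar(raw[i])
      if (contam[i] == "low_quality") {
        ## a run of Phred 5 over the whole insert drags mean quality below 20
        strrep("&", L)
      } else {
        strrep("I", L)
      }
    }, character(1))

    truth <- data.frame(
      read_id = ids,
      category = ifelse(contam == "adapter_dimer", "none", cats),
      chrom = chrom, start = start, end = end, strand = strand,
      intended_length = ifelse(contam == "adapter_dimer", 0L,
                               nchar(seq_out)),
      contamination = contam,
      stringsAsFactors = FALSE)
    list(reads = raw, quals = qual, ids = ids, truth = truth)
  })

  if (!is.null(out_fastq)) write_fastq(res$ids, res$reads, res$quals, out_fastq)
  if (!is.null(out_truth)) {
    utils::write.table(res$truth, out_truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  structure(res, class = "sim_library")
}

#' Write reads as Sanger FASTQ
#'
#' @param ids,reads,quals parallel character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, reads, quals, path) {
  stopifnot(length(ids) == length(reads), length(reads) == length(quals))
  if (length(ids) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  out <- character(4L * length(ids))
  out[seq(1, length(out), 4)] <- paste0("@", ids)
  out[seq(2, length(out), 4)] <- reads
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- quals
  writeLines(out, path)
  invisible(path)
}
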