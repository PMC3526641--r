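## End-to-end orchestration: simulate (or load) the three libraries, clean,
## collapse, map and annotate once over the union of unique reads, then emit
## the catalogue-shaped outputs: per-length histograms, per-category tables,
## the seven-group miRNA table, the differential-expression table, and the
## rasiRNA characterization tables and density tracks.

#' Build and validate a pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived from it.
#' @param n_reads reads per simulated library.
#' @param archetypes archetype names to simulate.
#' @param min_len,max_len cleaning length window (nt).
#' @param quality_floor minimum mean Phred quality.
#' @param rasirna_min_len,rasirna_max_len,max_loci rasiRNA candidate filter.
#' @param priority annotation cascade order.
#' @param de_alpha FDR threshold for the differential table.
#' @param feature_window,feature_step exon/repeat density geometry (nt).
#' @param read_window,read_step read density geometry (nt).
#' @param density_chrom chromosome profiled by the density tracks.
#' @param genome_spec,annotation_spec generator specs (defaults used when
#'   `NULL`).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_reads = 20000L,
                            archetypes = c("testis_like", "ovary_like",
                                           "ip_like"),
                            min_len = 18L, max_len = 30L, quality_floor = 20,
                            rasirna_min_len = 23L, rasirna_max_len = 32L,
                            max_loci = 5L, priority = DEFAULT_PRIORITY,
                            de_alpha = 0.05,
                            feature_window = 50000L, feature_step = 1000L,
                            read_window = 5000L, read_step = 100L,
                            density_chrom = "chrW",
                            genome_spec = NULL, annotation_spec = NULL) {
  if (missing(out_dir) || !is.character(out_dir)) {
    stop("config invalid: out_dir is required")
  }
  if (min_len > max_len || rasirna_min_len > rasirna_max_len) {
    stop("config invalid: length windows must satisfy min <= max")
  }
  if (n_reads < 0) stop("config invalid: n_reads must be non-negative")
  if (feature_window < feature_step || read_window < read_step) {
    stop("config invalid: window must be >= step")
  }
  check_prob(de_alpha, "de_alpha")
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), n_reads = as.integer(n_reads),
    archetypes = archetypes, min_len = min_len, max_len = max_len,
    quality_floor = quality_floor, rasirna_min_len = rasirna_min_len,
    rasirna_max_len = rasirna_max_len, max_loci = max_loci,
    priority = priority, de_alpha = de_alpha,
    feature_window = feature_window, feature_step = feature_step,
    read_window = read_window, read_step = read_step,
    density_chrom = density_chrom,
    genome_spec = genome_spec, annotation_spec = annotation_spec
  ), class = "pipeline_config")
}

#' Serialize / reload a pipeline configuration
#'
#' JSON round-trip: `read_pipeline_config(write_pipeline_config(cfg, f))`
#' reconstructs an equal configuration (generator specs included).
#'
#' @param config a `pipeline_config`.
#' @param path JSON file.
#' @return `path` (write) or the reloaded `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$genome_spec)) x$genome_spec <- unclass(x$genome_spec)
  if (!is.null(x$annotation_spec)) {
    a <- unclass(x$annotation_spec)
    a$counts <- as.list(a$counts)
    a$repeat_chrom_weights <- as.list(a$repeat_chrom_weights)
    x$annotation_spec <- a
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  gs <- if (!is.null(x$genome_spec)) {
    do.call(genome_spec, x$genome_spec)
  } else NULL
  as_ <- if (!is.null(x$annotation_spec)) {
    a <- x$annotation_spec
    annotation_spec(counts = unlist(a$counts),
                    length_ranges = lapply(a$length_ranges, as.integer),
                    repeat_chrom_weights = unlist(a$repeat_chrom_weights),
                    mature_len_range = as.integer(a$mature_len_range),
                    seed = a$seed)
  } else NULL
  pipeline_config(
    out_dir = x$out_dir, seed = x$seed, n_reads = x$n_reads,
    archetypes = x$archetypes, min_len = x$min_len, max_len = x$max_len,
    quality_floor = x$quality_floor, rasirna_min_len = x$rasirna_min_len,
    rasirna_max_len = x$rasirna_max_len, max_loci = x$max_loci,
    priority = x$priority, de_alpha = x$de_alpha,
    feature_window = x$feature_window, feature_step = x$feature_step,
    read_window = x$read_window, read_step = x$read_step,
    density_chrom = x$density_chrom,
    genome_spec = gs, annotation_spec = as_)
}

#' Per-length histogram of collapsed reads
#'
#' @param ur a `unique_reads` data.frame (or any data.frame with `sequence`
#'   and count columns).
#' @param weight `"unique"` (each family once) or `"copies"`.
#' @param lengths integer lengths to tabulate.
#' @return data.frame `length`, `count`.
#' @export
length_histogram <- function(ur, weight = c("unique", "copies"),
                             lengths = 18:32) {
  weight <- match.arg(weight)
  len <- nchar(ur$sequence)
  cc <- grep("^count", names(ur), value = TRUE)
  w <- if (weight == "unique") rep(1, nrow(ur)) else
    rowSums(ur[, cc, drop = FALSE])
  counts <- vapply(lengths, function(L) sum(w[len == L]), numeric(1))
  data.frame(length = lengths, count = counts)
}

## restrict a merged annotated_reads object to one library's expressed reads
subset_library <- function(ar, lib) {
  col <- paste0("count_", lib)
  idx <- which(ar$reads[[col]] > 0L)
  hits <- ar$hits[ar$hits$read %in% idx, , drop = FALSE]
  hits$read <- match(hits$read, idx)
  reads <- ar$reads[idx, , drop = FALSE]
  reads$count <- reads[[col]]
  rownames(reads) <- NULL
  structure(list(reads = reads, hits = hits), class = "annotated_reads")
}

#' Run the full characterization pipeline
#'
#' Deterministic under the config seed; every table is written as TSV under
#' `out_dir` with column headers, density tracks as bedGraph, and the
#' validated config plus a stage log alongside. Read-count conservation
#' (raw = clean + discards; per-library copies reconcile between the
#' cleaning report and the annotated table) is asserted on every run.
#'
#' @param config a [pipeline_config()].
#' @return invisible list bundle: `genome`, `annots`, `libraries` (per
#'   library: `sim`, `clean`, `unique`), `merged`, `annotated`, `tables`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  gs <- if (is.null(config$genome_spec)) genome_spec(seed = config$seed) else
    config$genome_spec
  as_ <- if (is.null(config$annotation_spec)) {
    annotation_spec(seed = config$seed + 1000L)
  } else config$annotation_spec

  genome <- stage("genome", make_genome(
    gs, out_fasta = file.path(config$out_dir, "genome.fa")))
  annots <- stage("annotations", make_annotations(
    genome, as_, out_dir = file.path(config$out_dir, "tracks")))
  logf("genome: %d chromosomes, %d nt", length(genome),
       sum(Biostrings::width(genome)))

  libs <- list()
  uniq <- list()
  for (k in seq_along(config$archetypes)) {
    name <- config$archetypes[k]
    arch <- library_archetype(name, n_reads = config$n_reads,
                              seed = config$seed + k)
    sim <- stage(paste0("simulate:", name), simulate_library(
      genome, annots, arch,
      out_fastq = file.path(config$out_dir, paste0(name, ".fastq")),
      out_truth = file.path(config$out_dir, paste0(name, ".truth.tsv"))))
    cl <- stage(paste0("clean:", name), clean_reads(
      list(ids = sim$ids, reads = sim$reads, quals = sim$quals),
      adapter = arch$adapter, min_len = config$min_len,
      max_len = config$max_len, quality_floor = config$quality_floor))
    rep <- cl$report
    stopifnot(rep$n_raw == rep$n_clean + rep$n_discarded_low_quality +
                rep$n_discarded_contaminant + rep$n_discarded_length)
    logf("%s: raw=%d clean=%d lowq=%d contaminant=%d length=%d",
         name, rep$n_raw, rep$n_clean, rep$n_discarded_low_quality,
         rep$n_discarded_contaminant, rep$n_discarded_length)
    ur <- collapse_unique(cl, name)
    stopifnot(sum(ur$count) == rep$n_clean)
    libs[[name]] <- list(sim = sim, clean = cl, unique = ur)
    uniq[[name]] <- ur
    for (w in c("unique", "copies")) {
      utils::write.table(
        length_histogram(ur, w),
        file.path(config$out_dir, sprintf("length_hist_%s_%s.tsv", name, w)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  merged <- merge_unique(uniq)
  ar <- stage("map-annotate",
              annotate_reads(merged, genome, annots, config$priority))
  ## conservation: per-library copies in the annotated table equal n_clean
  for (name in names(libs)) {
    stopifnot(sum(ar$reads[[paste0("count_", name)]]) ==
                libs[[name]]$clean$report$n_clean)
  }
  write_annotated_tsv(ar, file.path(config$out_dir, "annotated_reads.tsv"))

  tables <- list()
  for (name in names(libs)) {
    sub <- subset_library(ar, name)
    tables[[paste0("category_", name)]] <- category_table(sub)
    utils::write.table(
      tables[[paste0("category_", name)]],
      file.path(config$out_dir, sprintf("category_table_%s.tsv", name)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  clusters <- stage("mirna", cluster_isomirs(ar, annots))
  groups <- classify_seven_groups(clusters, annots$mature_seq,
                                  annots$hairpin_seq, annots$mirna)
  tables$group_table <- group_table(clusters, groups)
  utils::write.table(tables$group_table,
                     file.path(config$out_dir, "mirna_group_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (all(c("testis_like", "ovary_like") %in% names(libs))) {
    de <- stage("mirna-de", differential_table(
      clusters, "testis_like", "ovary_like",
      total_a = libs$testis_like$clean$report$n_clean,
      total_b = libs$ovary_like$clean$report$n_clean,
      alpha = config$de_alpha))
    tables$de_table <- de
    utils::write.table(de, file.path(config$out_dir, "mirna_de_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("mirna-de: %d clusters tested, %d significant at fdr<%.2f",
         nrow(de), sum(de$significant), config$de_alpha)
  }

  ## rasiRNA characterization on the testis-like library when present,
  ## otherwise on the first library
  target <- if ("testis_like" %in% names(libs)) "testis_like" else
    names(libs)[1]
  sub <- subset_library(ar, target)
  cand <- stage("rasirna", select_rasirna_candidates(
    sub, config$rasirna_min_len, config$rasirna_max_len,
    max_loci = config$max_loci))
  tables$rasirna_candidates <- cand$reads
  bias <- fivep_bias(cand)
  utils::write.table(
    cbind(position = seq_len(nrow(bias$matrix)),
          as.data.frame(bias$matrix), coverage = bias$coverage),
    file.path(config$out_dir, "rasirna_base_bias.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  tables$base_bias <- bias
  cd <- chrom_distribution(cand, genome, annots)
  tables$chrom_distribution <- cd
  utils::write.table(cd, file.path(config$out_dir, "chrom_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("rasirna[%s]: %d candidates, first-base U fraction %.3f",
       target, nrow(cand$reads),
       ifelse(is.na(bias$u1_fraction), NA, bias$u1_fraction))

  ch <- config$density_chrom
  if (ch %in% names(genome)) {
    clen <- Biostrings::width(genome)[match(ch, names(genome))]
    fx <- feature_density(annots, "exon", ch, clen,
                          config$feature_window, config$feature_step)
    fr <- feature_density(annots, c("LINE", "LTR", "satellite",
                                    "other_repeat"), ch, clen,
                          config$feature_window, config$feature_step)
    rp <- read_density(cand, ch, "+", clen,
                       config$read_window, config$read_step)
    rm_ <- read_density(cand, ch, "-", clen,
                        config$read_window, config$read_step)
    write_bedgraph(fx, file.path(config$out_dir,
                                 sprintf("density_exon_%s.bedgraph", ch)))
    write_bedgraph(fr, file.path(config$out_dir,
                                 sprintf("density_repeat_%s.bedgraph", ch)))
    write_bedgraph(rp, file.path(config$out_dir,
                                 sprintf("density_reads_plus_%s.bedgraph", ch)))
    write_bedgraph(rm_, file.path(config$out_dir,
                                  sprintf("density_reads_minus_%s.bedgraph", ch)))
    tables$density <- list(exon = fx, repeats = fr, plus = rp, minus = rm_)
  }

  ## provenance: serialize the validated config
  write_pipeline_config(config, file.path(config$out_dir, "config.json"))
  logf("done")
  invisible(list(genome = genome, annots = annots, libraries = libs,
                 merged = merged, annotated = ar, tables = tables))
}
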