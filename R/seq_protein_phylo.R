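## Cloning-support computations: forward-strand ORF discovery with
## translation, protein molecular weight (average masses) and isoelectric
## point (bisection on the Henderson-Hasselbalch net charge), and UPGMA
## clustering of a distance matrix into an ultrametric tree with Newick
## output.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the longest forward-strand ORF and translate it
#'
#' Scans the three forward frames for ATG-initiated, in-frame,
#' stop-terminated spans and returns the longest (ties: leftmost start).
#' The ORF interval includes the stop codon; the protein excludes it. A
#' trailing poly(A) run (>= `polya_min` A's) is detected and excluded from
#' the 3' UTR length.
#'
#' @param sequence cDNA sequence over A/C/G/T, length >= 6.
#' @param polya_min minimum trailing A-run length for poly(A) detection.
#' @return list of class `transcript_model`: `sequence`, `orf_start`,
#'   `orf_end` (1-based, closed, including stop; `NA` when no ORF),
#'   `utr5_len`, `utr3_len`, `has_polyA`, and `protein`, a
#'   `protein_record` list (`residues`, `length`) or `NULL` when no ORF.
#' @export
find_orf <- function(sequence, polya_min = 10L) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stop("sequence must be over A, C, G, T")
  n <- nchar(sequence)
  if (n < 6L) stop("sequence must be at least 6 nt")

  polya_len <- 0L
  m <- regexpr("A+$", sequence)
  if (m > 0 && attr(m, "match.length") >= polya_min) {
    polya_len <- attr(m, "match.length")
  }

  best <- NULL
  for (frame in 0:2) {
    starts <- seq(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(sequence, starts, starts + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    ## for each stop, the ORF starts at the first ATG after the previous stop
    prev_stop <- 0L
    for (k in which(is_stop)) {
      atg <- which(is_atg[(prev_stop + 1L):(k - 1L)])
      if (length(atg) > 0L) {
        a <- prev_stop + atg[1L]
        len <- (k - a + 1L) * 3L
        if (is.null(best) || len > best$len ||
            (len == best$len && starts[a] < best$start)) {
          best <- list(start = starts[a], end = starts[k] + 2L, len = len)
        }
      }
      prev_stop <- k
    }
  }

  if (is.null(best)) {
    return(structure(list(sequence = sequence, orf_start = NA_integer_,
                          orf_end = NA_integer_, utr5_len = NA_integer_,
                          utr3_len = NA_integer_, has_polyA = polya_len > 0L,
                          protein = NULL),
                     class = "transcript_model"))
  }
  orf <- substr(sequence, best$start, best$end - 3L)  # without stop
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
  structure(list(
    sequence = sequence,
    orf_start = best$start, orf_end = best$end,
    utr5_len = best$start - 1L,
    utr3_len = n - best$end - polya_len,
    has_polyA = polya_len > 0L,
    protein = structure(list(residues = aa, length = nchar(aa)),
                        class = "protein_record")
  ), class = "transcript_model")
}

## average residue masses (Da); add one water for the intact chain
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.02

#' Protein molecular weight (average masses)
#'
#' @param residues amino-acid string over the standard 20-letter alphabet.
#' @return mass in Daltons: sum of average residue masses plus one water.
#' @export
protein_mw <- function(residues) {
  if (nchar(residues) == 0L) stop("empty residue string")
  aa <- strsplit(toupper(residues), "")[[1]]
  bad <- which(!aa %in% names(RESIDUE_MASS))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]))
  }
  sum(RESIDUE_MASS[aa]) + WATER_MASS
}

## ionizable-group pKa tables
PKA_TABLES <- list(
  EMBOSS = c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
             D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
  Bjellqvist = c(Nterm = 7.5, Cterm = 3.55, K = 10.0, R = 12.0, H = 5.98,
                 D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
)

## net charge at a given pH; strictly decreasing in pH
protein_charge <- function(residues, pH, pka) {
  aa <- strsplit(toupper(residues), "")[[1]]
  pos_groups <- c(Nterm = 1, K = sum(aa == "K"), R = sum(aa == "R"),
                  H = sum(aa == "H"))
  neg_groups <- c(Cterm = 1, D = sum(aa == "D"), E = sum(aa == "E"),
                  C = sum(aa == "C"), Y = sum(aa == "Y"))
  pos <- sum(pos_groups / (1 + 10^(pH - pka[names(pos_groups)])))
  neg <- sum(neg_groups / (1 + 10^(pka[names(neg_groups)] - pH)))
  pos - neg
}

#' Protein isoelectric point
#'
#' Bisection on the Henderson-Hasselbalch net-charge function; the charge
#' is strictly decreasing in pH, so the root is unique.
#'
#' @param residues amino-acid string.
#' @param pka_set `"EMBOSS"` (default) or `"Bjellqvist"` pKa table.
#' @param tol bisection tolerance in pH units.
#' @return the pH at which the net charge is zero.
#' @export
protein_pI <- function(residues, pka_set = c("EMBOSS", "Bjellqvist"),
                       tol = 1e-4) {
  if (nchar(residues) == 0L) stop("empty residue string")
  aa <- strsplit(toupper(residues), "")[[1]]
  bad <- which(!aa %in% names(RESIDUE_MASS))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]))
  }
  pka <- PKA_TABLES[[match.arg(pka_set)]]
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(residues, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Read a square distance matrix from TSV
#'
#' Expects a header row and a leading label column, symmetric entries, zero
#' diagonal.
#'
#' @param path TSV file.
#' @return a labelled numeric matrix.
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (any(is.na(d))) stop("distance matrix contains NA")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (any(abs(d - t(d)) > 1e-9)) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the new node's height is
#' half the merged distance and distances to other clusters are updated by
#' the size-weighted arithmetic mean. Ties at the minimal distance are
#' broken by the lexicographically smallest (sorted) pair of cluster
#' representative labels (the smallest leaf label in each cluster), making
#' the result invariant under input row permutation.
#'
#' @param d symmetric non-negative matrix with zero diagonal (labelled), or
#'   a `dist` object, or a TSV path for [read_distance_tsv()].
#' @return list of class `upgma_tree`: `root` (nested node list with
#'   `height`, `label`, `children`), `labels`, `newick` (branch lengths are
#'   height differences; leaves at height 0).
#' @export
upgma <- function(d) {
  if (is.character(d) && length(d) == 1L) d <- read_distance_tsv(d)
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two taxa")
  labels <- rownames(d)

  nodes <- lapply(labels, function(l) {
    list(height = 0, label = l, children = NULL, size = 1L, rep = l)
  })
  active <- seq_len(n)
  dm <- d
  while (length(active) > 1L) {
    ## locate the minimal-distance pair among active clusters
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        dij <- dm[i, j]
        reps <- sort(c(nodes[[i]]$rep, nodes[[j]]$rep))
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (reps[1] < best$reps[1] ||
              (reps[1] == best$reps[1] && reps[2] < best$reps[2])))) {
          best <- list(i = i, j = j, d = dij, reps = reps)
        }
      }
    }
    i <- best$i; j <- best$j
    ## canonical child order (by representative label) keeps the Newick
    ## string invariant under input row permutation
    kids <- list(nodes[[i]], nodes[[j]])
    if (nodes[[j]]$rep < nodes[[i]]$rep) kids <- rev(kids)
    new <- list(
      height = best$d / 2,
      label = NA_character_,
      children = kids,
      size = nodes[[i]]$size + nodes[[j]]$size,
      rep = min(nodes[[i]]$rep, nodes[[j]]$rep)
    )
    k <- length(nodes) + 1L
    nodes[[k]] <- new
    ## grow the matrix with size-weighted average distances
    dm <- rbind(cbind(dm, 0), 0)
    for (m in setdiff(active, c(i, j))) {
      dm[k, m] <- dm[m, k] <-
        (nodes[[i]]$size * dm[i, m] + nodes[[j]]$size * dm[j, m]) /
        (nodes[[i]]$size + nodes[[j]]$size)
    }
    active <- c(setdiff(active, c(i, j)), k)
  }
  root <- nodes[[active]]
  structure(list(root = root, labels = sort(labels),
                 newick = paste0(tree_newick(root), ";")),
            class = "upgma_tree")
}

## recursive Newick rendering; branch length = parent height - child height
tree_newick <- function(node) {
  if (is.null(node$children)) return(node$label)
  parts <- vapply(node$children, function(ch) {
    sprintf("%s:%.10g", tree_newick(ch), node$height - ch$height)
  }, character(1))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Cophenetic distances implied by a UPGMA tree
#'
#' The cophenetic distance between two leaves is twice the height of their
#' lowest common ancestor.
#'
#' @param tree a `upgma_tree`.
#' @return a labelled symmetric matrix (rows/columns sorted by label).
#' @export
cophenetic_upgma <- function(tree) {
  labs <- tree$labels
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  walk <- function(node) {
    if (is.null(node$children)) return(node$label)
    leaf_sets <- lapply(node$children, walk)
    for (a in seq_along(leaf_sets)) {
      for (b in seq_along(leaf_sets)) {
        if (b <= a) next
        m[leaf_sets[[a]], leaf_sets[[b]]] <<- 2 * node$height
        m[leaf_sets[[b]], leaf_sets[[a]]] <<- 2 * node$height
      }
    }
    unlist(leaf_sets)
  }
  walk(tree$root)
  m
}

#' Leaf heights and ultrametricity check
#'
#' @param tree a `upgma_tree`.
#' @return named vector of root-to-leaf path lengths (all equal for an
#'   ultrametric tree).
#' @export
leaf_depths <- function(tree) {
  depths <- c()
  walk <- function(node, acc) {
    if (is.null(node$children)) {
      depths[[node$label]] <<- acc
      return(invisible())
    }
    for (ch in node$children) walk(ch, acc + node$height - ch$height)
  }
  walk(tree$root, 0)
  unlist(depths)
}

#' Uncorrected p-distance matrix from an aligned FASTA
#'
#' Pairwise proportion of differing aligned columns, computed over columns
#' where neither sequence has a gap (`-`).
#'
#' @param path aligned FASTA (equal-length sequences).
#' @return labelled symmetric distance matrix.
#' @export
p_distance <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(aln))) != 1L) {
    stop("aligned sequences must have equal length")
  }
  chars <- strsplit(as.character(aln), "")
  n <- length(chars)
  m <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ok <- chars[[i]] != "-" & chars[[j]] != "-"
      m[i, j] <- m[j, i] <- if (any(ok)) {
        mean(chars[[i]][ok] != chars[[j]][ok])
      } else 0
    }
  }
  m
}
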