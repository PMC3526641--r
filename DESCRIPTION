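Package: srnakit
Title: Characterization of Small-RNA Sequencing Libraries from Germline Tissue
Version: 0.1.0
Authors@R: person("srnakit", "maintainers", email = "srnakit@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for characterizing small-RNA sequencing
    libraries such as those obtained from gonadal tissue or from
    immunoprecipitated PIWI-protein complexes. Provides a synthetic-data
    generator emulating ovary-like (22 nt miRNA mode), testis-like (24/27 nt
    bimodal, repeat-rich, 5'-uridine biased) and IP-like libraries with
    ground-truth labels; read cleaning and collapsing into unique families;
    exhaustive exact-match mapping on both strands; a priority-cascade
    annotation of reads into ncRNA, miRNA, repeat, exon and unannotated
    categories; isomiR clustering, seven-group miRNA confidence
    classification and Audic-Claverie differential expression with
    Benjamini-Hochberg correction; rasiRNA candidate selection (23-32 nt,
    unannotated, 1-5 genomic loci) with positional base-composition,
    chromosome-normalized and sliding-window density statistics; and
    cloning-support computations (ORF discovery and translation, protein
    molecular weight and isoelectric point, UPGMA trees with Newick output).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
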