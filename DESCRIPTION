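Package: dinomito
Title: Comparative Mitochondrial Genomics of Dinotoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of the paired mitochondrial
    genomes carried by dinotoms (dinoflagellates with a permanent diatom
    endosymbiont, hence two evolutionarily distinct mitochondria in one
    cell). Reads and writes annotated organellar genomes (GenBank flat
    file, FASTA), computes compact-genome feature statistics (GC content
    by feature class, coding fraction, intergenic spacers, codon surveys),
    extracts signed gene orders and computes exact signed reversal
    (inversion) distances via the Hannenhalli-Pevzner breakpoint-graph
    theory with a breadth-first-search oracle for validation, detects
    conserved synteny blocks, calls gene fission, fusion, in-frame
    insertion, intron interruption and trans-splice junctions, calls
    substitutional RNA-editing sites from paired genomic/cDNA sequences,
    maps pseudogene fragments onto full-length reference genes with
    coverage-uniformity testing, and generates fully seeded synthetic
    data sets with ground truth so that every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
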