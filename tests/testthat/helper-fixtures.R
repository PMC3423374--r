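# Shared fixtures, built in code.

# minimal GenBank record text: one CDS 1..90 on the plus strand
minimal_genbank <- function() {
  cds <- paste0("ATG", paste(rep("GCT", 28), collapse = ""), "TAA")
  c("LOCUS       mini 90 bp    DNA     linear   UNA 01-JAN-2000",
    "DEFINITION  minimal test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..90",
    "     CDS             1..90",
    "                     /gene=\"cox1\"",
    "                     /transl_table=1",
    "ORIGIN",
    paste0("        1 ", paste(substring(tolower(cds),
                                         seq(1, 90, 10), seq(10, 90, 10)),
                               collapse = " ")),
    "//")
}

# circular record with a wrapping join(100..150,1..30) CDS
wrapping_genbank <- function() {
  set.seed(99)
  sq <- paste(sample(c("a", "c", "g", "t"), 150, TRUE), collapse = "")
  lines <- c("LOCUS       wrapper 150 bp    DNA     circular   UNA 01-JAN-2000",
             "FEATURES             Location/Qualifiers",
             "     CDS             join(100..150,1..30)",
             "                     /gene=\"wrapped\"",
             "ORIGIN")
  for (s in seq(1, 150, 60)) {
    chunk <- substr(sq, s, min(s + 59, 150))
    tens <- regmatches(chunk, gregexpr(".{1,10}", chunk))[[1]]
    lines <- c(lines, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  c(lines, "//")
}

# tiny hand-built genome: explicit sequence and features
tiny_genome <- function(seq = "ATGCCCGGGTTT", topology = "linear",
                        feats = NULL) {
  if (is.null(feats))
    feats <- gene_feature("g1", "protein", "+", c(1, 12))
  annotated_genome("tiny", seq, feats, topology = topology)
}

random_dna_fix <- function(n, gc = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_signed_perm <- function(n) sample(1:n) * sample(c(-1L, 1L), n, TRUE)
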