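# Fission, fusion, in-frame insertion, intron interruption, trans-splicing.

test_that("fission of a protein into exact halves is recovered at the cut", {
  set.seed(8)
  prot <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       300, TRUE), collapse = "")
  parts <- c(a = substr(prot, 1, 150), b = substr(prot, 151, 300))
  ev <- detect_fission(prot, parts)
  expect_s3_class(ev, "fission_event")
  expect_equal(ev$part_ids, c("a", "b"))
  expect_equal(ev$breakpoint_aa, c(150, 151))
  # unrelated candidates give nothing
  junk <- c(x = paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                             150, TRUE), collapse = ""),
            y = paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                             150, TRUE), collapse = ""))
  expect_null(detect_fission(prot, junk))
})

test_that("planted fission with mutations is recovered within +-5 aa", {
  sim <- simulate_genome(n_genes = 15, seed = 42)
  for (s in 1:5) {
    ev <- simulate_structural_events(sim$genome, list(fission = TRUE), seed = s)
    parts <- ev$fission$part_proteins
    # ~5% amino-acid level perturbation via nucleotide mutation is emulated
    # by direct residue substitution here
    set.seed(s)
    mutate_aa <- function(p) {
      ch <- strsplit(p, "")[[1]]
      idx <- sample(seq_along(ch), round(0.05 * length(ch)))
      ch[idx] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        length(idx), TRUE)
      paste(ch, collapse = "")
    }
    res <- detect_fission(ev$fission$parent_protein,
                          vapply(parts, mutate_aa, character(1)))
    expect_false(is.null(res))
    expect_lte(abs(res$breakpoint_aa[1] - ev$fission$truth$breakpoint_aa), 5)
  }
})

test_that("a planted in-frame gene fusion is detected, self-comparison is not", {
  sim <- simulate_genome(n_genes = 15, seed = 13)
  ev <- simulate_structural_events(sim$genome, list(fusion = TRUE), seed = 3)
  found <- detect_fusions(ev$fusion$genomeA, ev$fusion$genomeB)
  expect_equal(length(found), 1)
  expect_equal(found[[1]]$upstream, ev$fusion$truth$upstream)
  expect_equal(found[[1]]$downstream, ev$fusion$truth$downstream)
  expect_true(found[[1]]$evidence[["downstream_initiator_met"]])
  expect_length(detect_fusions(ev$fusion$genomeB, ev$fusion$genomeB), 0)
})

test_that("an insert present in the in-group and absent in outgroups is found", {
  sim <- simulate_genome(n_genes = 15, seed = 29)
  ev <- simulate_structural_events(sim$genome,
                                   list(insert = list(len_nt = 150)), seed = 5)
  res <- detect_inframe_insert(ev$insert$ingroup, ev$insert$outgroups)
  expect_s3_class(res, "insertion_event")
  expect_equal(unname(res$bounds_aa[1, ]),
               c(ev$insert$truth$aa_start, ev$insert$truth$aa_end))
  expect_equal(unname(res$insert_len_nt[1]), 150L)
  expect_true(all(res$insert_len_nt %% 3 == 0))
  # identical homologs carry no insert; missing outgroup is an error
  cds <- ev$insert$outgroups[1]
  expect_null(detect_inframe_insert(c(a = unname(cds), b = unname(cds)),
                                    c(o = unname(cds))))
  expect_error(detect_inframe_insert(ev$insert$ingroup, character()),
               class = "no_outgroup")
})

test_that("with 2% divergence the insert is still recovered closely", {
  sim <- simulate_genome(n_genes = 15, seed = 29)
  ev <- simulate_structural_events(sim$genome,
                                   list(insert = list(len_nt = 498,
                                                      divergence = 0.02)),
                                   seed = 8)
  res <- detect_inframe_insert(ev$insert$ingroup, ev$insert$outgroups)
  expect_false(is.null(res))
  expect_lte(abs(res$bounds_aa[1, 1] - ev$insert$truth$aa_start), 5)
  expect_lte(abs(res$bounds_aa[1, 2] - ev$insert$truth$aa_end), 5)
  # flanks align far better than the (unrelated-by-construction) insert
  expect_gt(min(res$flank_identity_pct), 80)
})

test_that("intron interruptions are recovered from locus/cDNA pairs", {
  set.seed(17)
  exons <- replicate(4, random_dna_fix(sample(150:400, 1)))
  introns <- replicate(3, random_dna_fix(sample(80:300, 1), gc = 0.25))
  locus <- paste0(exons[1], introns[1], exons[2], introns[2], exons[3],
                  introns[3], exons[4])
  cdna_exact <- paste(exons, collapse = "")
  found <- detect_intron_interruption(locus, cdna_exact)
  exp_start <- c(nchar(exons[1]) + 1,
                 nchar(exons[1]) + nchar(introns[1]) + nchar(exons[2]) + 1,
                 nchar(exons[1]) + nchar(introns[1]) + nchar(exons[2]) +
                   nchar(introns[2]) + nchar(exons[3]) + 1)
  exp_end <- exp_start + nchar(introns) - 1
  expect_equal(nrow(found), 3)
  expect_true(all(abs(found$intron_start - exp_start) <= 3))
  expect_true(all(abs(found$intron_end - exp_end) <= 3))
  # 2% exon divergence
  cdna_mut <- mutate_seq(cdna_exact, round(0.02 * nchar(cdna_exact)))
  found2 <- detect_intron_interruption(locus, cdna_mut)
  expect_equal(nrow(found2), 3)
  expect_true(all(abs(found2$intron_start - exp_start) <= 3))
  # intronless locus
  expect_equal(nrow(detect_intron_interruption(cdna_exact, cdna_exact)), 0)
  # unrelated cDNA cannot be decomposed
  expect_error(detect_intron_interruption(locus, random_dna_fix(600)),
               class = "decomposition_error")
})

test_that("trans-splice junctions are located with and without inserts", {
  set.seed(23)
  part1 <- paste(dinomito:::random_sense_codons(235, 0.36, 0.75), collapse = "")
  part2 <- paste(dinomito:::random_sense_codons(60, 0.36, 0.75), collapse = "")
  # exact concatenation, no insert
  sj <- locate_trans_splice_junction(part1, part2, paste0(part1, part2))
  expect_equal(sj$junction_aa, c(235, 236))
  expect_equal(sj$insert, "")
  # penta-A at the junction
  sj2 <- locate_trans_splice_junction(part1, part2,
                                      paste0(part1, "AAAAA", part2))
  expect_equal(sj2$insert, "AAAAA")
  expect_equal(sj2$junction_aa, c(235, 236))
  # planted substitution edits upstream do not move the junction
  ed <- simulate_editing_pair(part1, n_sites = 10, seed = 4)
  sj3 <- locate_trans_splice_junction(part1, part2,
                                      paste0(ed$transcript, "AAAAA", part2))
  expect_equal(sj3$junction_aa, c(235, 236))
  expect_equal(sj3$insert, "AAAAA")
  # a partial transcript starting inside part 1 still anchors
  tx <- paste0(substr(part1, 302, nchar(part1)), part2)
  sj4 <- locate_trans_splice_junction(part1, part2, tx)
  expect_equal(sj4$junction_aa, c(235, 236))
})

test_that("detectors return nothing for an empty event spec or self input", {
  sim <- simulate_genome(n_genes = 12, seed = 99)
  expect_length(simulate_structural_events(sim$genome, list(), seed = 1), 0)
  g <- sim$genome
  expect_length(detect_fusions(g, g), 0)
  prot <- sub("\\*$", "", translate_cds(
    spliced_sequence(g, which(g$features$cls == "protein")[1]),
    mode = "open_frame"))
  expect_null(detect_fission(prot, c(self = prot)))
})
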