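# Feature statistics: GC, coverage, spacers, codon surveys, accounting.

test_that("gc_content handles pure AT, pure GC and ambiguity exclusion", {
  g <- tiny_genome("ATAT", feats = gene_feature("g", "tRNA", "+", c(1, 4)))
  expect_equal(gc_content(g, "total"), 0)
  g2 <- tiny_genome("GCGC", feats = gene_feature("g", "tRNA", "+", c(1, 4)))
  expect_equal(gc_content(g2, "total"), 100)
  # N excluded from numerator and denominator
  g3 <- tiny_genome("GCNN", feats = gene_feature("g", "tRNA", "+", c(1, 4)))
  expect_equal(gc_content(g3, "total"), 100)
  expect_error(gc_content(g, "rRNA"), class = "empty_selection")
})

test_that("coding fraction is a position-set union, counted once", {
  sq <- random_dna_fix(100, seed = 3)
  g <- annotated_genome("u", sq,
                        rbind(gene_feature("a", "protein", "+", c(1, 90))),
                        topology = "linear")
  expect_equal(coding_fraction(g), 90)
  g2 <- annotated_genome("u2", sq,
                         rbind(gene_feature("a", "protein", "+", c(1, 50)),
                               gene_feature("b", "protein", "-", c(1, 50))),
                         topology = "linear")
  expect_equal(coding_fraction(g2), 50)
})

test_that("spacers between consecutive genes follow the gap arithmetic", {
  sq <- random_dna_fix(40, seed = 4)
  g <- annotated_genome("s", sq,
                        rbind(gene_feature("a", "tRNA", "+", c(1, 10)),
                              gene_feature("b", "tRNA", "+", c(11, 20))),
                        topology = "linear")
  expect_equal(intergenic_spacers(g)$spacers, 0L)
  g2 <- annotated_genome("s2", sq,
                         rbind(gene_feature("a", "tRNA", "+", c(1, 10)),
                               gene_feature("b", "tRNA", "+", c(16, 20))),
                         topology = "linear")
  expect_equal(intergenic_spacers(g2)$spacers, 5L)
  # overlap reported separately, excluded from spacers
  g3 <- annotated_genome("s3", sq,
                         rbind(gene_feature("a", "tRNA", "+", c(1, 12)),
                               gene_feature("b", "tRNA", "+", c(10, 20)),
                               gene_feature("c", "tRNA", "+", c(26, 30))),
                         topology = "linear")
  sp <- intergenic_spacers(g3)
  expect_equal(sp$spacers, 5L)
  expect_equal(nrow(sp$overlaps), 1)
  expect_equal(sp$overlaps$gene1, "a")
})

test_that("codon survey counts starts, stops and third-position composition", {
  sq <- "ATGAAATAA"
  g <- annotated_genome("c", sq, gene_feature("g1", "protein", "+", c(1, 9)),
                        topology = "linear")
  cs <- codon_stats(g)
  expect_equal(unname(cs$start_codons["g1"]), "ATG")
  expect_equal(unname(cs$stop_codons["g1"]), "TAA")
  # sense codons ATG, AAA -> third positions G, A -> 50% A+T
  expect_equal(cs$third_position_AT_pct, 50)
  expect_length(cs$alt_start_genes, 0)
  # ATA start flagged as alternative
  g2 <- annotated_genome("c2", "ATAAAATAA",
                         gene_feature("rps2", "protein", "+", c(1, 9)),
                         topology = "linear")
  expect_equal(codon_stats(g2)$alt_start_genes, "rps2")
})

test_that("gene length summary averages spliced lengths by class", {
  sq <- random_dna_fix(400, seed = 5)
  g <- annotated_genome("m", sq,
                        rbind(gene_feature("a", "protein", "+", c(1, 100)),
                              gene_feature("b", "protein", "+", c(151, 350)),
                              gene_feature("t", "tRNA", "+", c(351, 400))),
                        topology = "linear")
  gl <- gene_length_summary(g)
  expect_equal(gl$mean_protein_gene_bp, 150)
  expect_equal(gl$mean_all_gene_bp, (100 + 200 + 50) / 3)
})

test_that("simulated genomes reproduce generator parameters within tolerance", {
  sim <- simulate_genome(seed = 101)
  st <- genome_statistics(sim$genome)
  expect_equal(unname(st$gene_counts["total"]), 58)
  expect_equal(unname(st$gene_counts["rRNA"]), 2)
  expect_equal(unname(st$gene_counts["tRNA"]), 23)
  # targets: GC 31%, spacer 58, protein 793, third-position A+T 79%
  expect_lt(abs(st$gc_total_pct - 31.02), 2.5)
  expect_lt(abs(st$mean_spacer_bp - 58) / 58, 0.35)
  expect_lt(abs(st$mean_protein_gene_bp - 793) / 793, 0.15)
  expect_lt(abs(st$third_position_AT_pct - 79), 3)
  expect_equal(st$mean_protein_gene_bp,
               mean(sim$truth$genes$length[sim$truth$genes$cls == "protein"]))
})

test_that("coverage + spacers accounts exactly for the sequenced length", {
  for (s in c(31, 77, 123)) {
    sim <- simulate_genome(n_genes = 30, seed = s)
    st <- genome_statistics(sim$genome)
    cov <- length(dinomito:::coverage_positions(sim$genome))
    expect_identical(cov + sum(st$intergenic_spacer_lengths),
                     nchar(sim$genome$sequence))
    expect_equal(nrow(st$overlap_pairs), nrow(sim$truth$overlap_pairs))
  }
})

test_that("total GC is the coverage-weighted mixture of class GC", {
  sim <- simulate_genome(n_genes = 25, seed = 9, n_overlaps = 0)
  g <- sim$genome
  classes <- c("protein", "rRNA", "tRNA", "orf", "intergenic")
  pos_of <- function(sel) {
    if (sel == "intergenic")
      setdiff(seq_len(nchar(g$sequence)), dinomito:::coverage_positions(g))
    else {
      keep <- which(g$features$cls == sel)
      sort(unique(unlist(lapply(keep, function(i)
        dinomito:::feature_positions(g, g$features[i, ], spliced = TRUE)))))
    }
  }
  w <- vapply(classes, function(s) length(pos_of(s)), numeric(1))
  gcs <- vapply(classes, function(s) gc_content(g, s), numeric(1))
  expect_equal(sum(w * gcs) / sum(w), gc_content(g, "total"), tolerance = 1e-6)
})
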