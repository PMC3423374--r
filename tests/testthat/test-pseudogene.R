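# Pseudogene fragment mapping, classification, coverage profiles.

test_that("an exact gene substring with one random flank maps cleanly", {
  gene <- c(cox1 = random_dna_fix(900, seed = 1))
  core <- substr(gene[[1]], 201, 500)
  # flank constructed not to continue the gene by chance at the junctions
  flank <- random_dna_fix(100, seed = 2)
  while (substr(flank, 1, 1) == substr(gene[[1]], 501, 501))
    flank <- substr(random_dna_fix(101, seed = NULL), 2, 101)
  frag <- c(f1 = paste0(core, flank))
  m <- map_fragments(frag, gene)
  expect_equal(nrow(m), 1)
  expect_equal(m$gene_start, 201)
  expect_equal(m$gene_end, 500)
  expect_equal(m$identity_pct, 100)
  expect_equal(m$flank_left, 0)
  expect_equal(m$flank_right, 100)
  expect_equal(m$aa_first, 67)   # ceiling(201/3)
  expect_equal(m$aa_last, 167)   # ceiling(500/3)
  expect_equal(m$orientation, "+")
  expect_equal(m$conservation, "conserved")
  # reverse complement maps to the same interval on the minus strand
  rc <- c(f1rc = dinomito:::revcomp(frag[[1]]))
  m2 <- map_fragments(rc, gene)
  expect_equal(m2$gene_start, 201)
  expect_equal(m2$gene_end, 500)
  expect_equal(m2$orientation, "-")
  expect_equal(m2$identity_pct, 100)
  expect_equal(m2$flank_left, 100)
})

test_that("one contig can carry pseudogenes of two different genes", {
  genes <- c(cob = random_dna_fix(1100, seed = 3),
             cox1 = random_dna_fix(1500, seed = 4))
  frag <- c(mixed = paste0(random_dna_fix(60, seed = 5),
                           substr(genes[["cob"]], 1, 327),
                           random_dna_fix(40, seed = 6),
                           substr(genes[["cox1"]], 400, 780),
                           random_dna_fix(80, seed = 7)))
  m <- map_fragments(frag, genes)
  expect_setequal(m$gene, c("cob", "cox1"))
  mb <- m[m$gene == "cob", ]
  expect_lte(abs(mb$gene_start - 1), 3)
  expect_lte(abs(mb$gene_end - 327), 3)
})

test_that("generator truth is recovered: spans, orientation, identity", {
  gene <- c(rnl = random_dna_fix(2400, seed = 8))
  ps <- simulate_pseudogene_set(gene, n_fragments = 25, seed = 21)
  m <- map_fragments(ps$fragments, gene)
  expect_equal(nrow(m), 25)
  mm <- merge(m, ps$truth, by = "fragment")
  expect_true(all(mm$orientation.x == mm$orientation.y))
  errs <- c(abs(mm$gene_start.x - mm$gene_start.y),
            abs(mm$gene_end.x - mm$gene_end.y))
  # boundary vs random flank is a changepoint estimate: median exact, the
  # overwhelming majority of ends within +-3 nt
  expect_equal(median(errs), 0)
  expect_gte(mean(errs <= 3), 0.9)
  iderr <- abs(mm$identity_pct - 100 * mm$identity)
  expect_lte(median(iderr), 0.5)
  expect_gte(mean(iderr <= 1), 0.9)
})

test_that("classification thresholds are monotone with published anchors", {
  expect_equal(classify_match(99), "conserved")
  expect_equal(classify_match(44), "degenerate")
  expect_equal(classify_match(75), "intermediate")
  ids <- seq(100, 40, by = -1)
  cls <- factor(classify_match(ids),
                levels = c("degenerate", "intermediate", "conserved"),
                ordered = TRUE)
  expect_true(all(diff(as.integer(cls)) <= 0))
})

test_that("coverage depth conserves mass and flags the empty case", {
  gene <- c(g = random_dna_fix(1000, seed = 9))
  m <- data.frame(fragment = c("a", "b"), gene = "g",
                  frag_start = 1, frag_end = 10,
                  gene_start = c(1, 401), gene_end = c(500, 900),
                  aa_first = 1, aa_last = 1, orientation = "+",
                  identity_pct = 99, flank_left = 0, flank_right = 0,
                  conservation = "conserved")
  pr <- coverage_profile(m, gene)
  expect_equal(sum(pr$depth), 1000)
  expect_equal(max(pr$depth), 2)   # 401..500 doubly covered
  empty <- coverage_profile(m[0, ], gene)
  expect_equal(sum(empty$depth), 0)
  expect_true(is.na(empty$p_value))
  expect_match(empty$flag, "undefined")
})

test_that("a single full-length match does not reject uniformity", {
  gene <- c(g = random_dna_fix(600, seed = 10))
  m <- data.frame(fragment = "a", gene = "g", frag_start = 1, frag_end = 600,
                  gene_start = 1, gene_end = 600, aa_first = 1, aa_last = 200,
                  orientation = "+", identity_pct = 100, flank_left = 0,
                  flank_right = 0, conservation = "conserved")
  pr <- coverage_profile(m, gene)
  expect_true(all(pr$depth == 1))
  expect_gte(pr$p_value, 0.01)
})

test_that("matches stacked on one half reject uniformity at alpha 0.01", {
  gene <- c(g = random_dna_fix(1000, seed = 11))
  n <- 30
  m <- data.frame(fragment = sprintf("f%02d", 1:n), gene = "g",
                  frag_start = 1, frag_end = 50,
                  gene_start = round(seq(1, 450, length.out = n)),
                  gene_end = round(seq(1, 450, length.out = n)) + 49,
                  aa_first = 1, aa_last = 17, orientation = "+",
                  identity_pct = 100, flank_left = 0, flank_right = 0,
                  conservation = "conserved")
  pr <- coverage_profile(m, gene)
  expect_lt(pr$p_value, 0.01)
})

test_that("uniformly placed fragments rarely reject uniformity", {
  # placement test operates on truth spans directly (no alignment needed)
  gene <- c(g = random_dna_fix(2000, seed = 12))
  rejections <- 0
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    ps <- simulate_pseudogene_set(gene, n_fragments = 100, seed = 1000 + s)
    m <- data.frame(fragment = ps$truth$fragment, gene = "g",
                    frag_start = 1, frag_end = 1,
                    gene_start = ps$truth$gene_start,
                    gene_end = ps$truth$gene_end,
                    aa_first = 1, aa_last = 1, orientation = "+",
                    identity_pct = 100, flank_left = 0, flank_right = 0,
                    conservation = "conserved")
    pr <- coverage_profile(m, gene)
    if (pr$p_value < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections / n_rep, 0.05)
})
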