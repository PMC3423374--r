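# Signed gene orders, reversal distance, synteny blocks.

test_that("joint permutation numbering follows the reference", {
  ref <- as_signed_gene_order(letters[1:6], rep("+", 6), "ref")
  expect_equal(build_joint_permutation(ref, ref)$values, 1:6)
  # query = reference with genes 2..4 reversed and sign-flipped
  qry <- apply_reversal(ref, 2, 4)
  qry$genome_id <- "qry"
  expect_equal(build_joint_permutation(ref, qry)$values,
               c(1L, -4L, -3L, -2L, 5L, 6L))
  # reference on mixed strands defines + orientation
  ref2 <- as_signed_gene_order(letters[1:4], c("+", "-", "+", "-"), "ref2")
  expect_equal(build_joint_permutation(ref2, ref2)$values, 1:4)
})

test_that("joint permutation drops duplicates and requires overlap", {
  ref <- as_signed_gene_order(c("a", "b", "c", "b"), rep("+", 4), "ref")
  qry <- as_signed_gene_order(c("a", "c", "d"), rep("+", 3), "qry")
  expect_error(suppressWarnings(build_joint_permutation(ref, qry)),
               class = "insufficient_overlap")
  qry2 <- as_signed_gene_order(c("c", "a", "e", "d"), rep("+", 4), "qry")
  ref2 <- as_signed_gene_order(c("a", "b", "c", "b", "e", "d"), rep("+", 6), "r")
  expect_warning(p <- build_joint_permutation(ref2, qry2), "duplicated")
  expect_equal(sort(abs(p$values)), 1:4)
})

test_that("reversal distance matches hand-checkable cases", {
  expect_equal(reversal_distance(signed_permutation(1:7)), 0L)
  expect_equal(reversal_distance(signed_permutation(c(-3, -2, -1))), 1L)
  # frozen from the exhaustive BFS oracle at n = 2
  expect_equal(bfs_reversal_distance(signed_permutation(c(2L, 1L))), 3L)
  expect_equal(reversal_distance(signed_permutation(c(2L, 1L))), 3L)
  # one applied reversal from identity is distance 1
  set.seed(2)
  for (r in 1:10) {
    n <- sample(3:9, 1)
    p <- apply_reversal(signed_permutation(1:n), sample(n, 1), n)
    expect_equal(bfs_reversal_distance(p), 1L)
  }
})

test_that("breakpoint-graph distance equals the BFS oracle on random permutations", {
  set.seed(1234)
  for (r in 1:150) {
    n <- sample(2:8, 1)
    p <- signed_permutation(random_signed_perm(n))
    expect_identical(reversal_distance(p), bfs_reversal_distance(p),
                     label = paste(p$values, collapse = ","))
  }
})

test_that("distance is symmetric and changes by at most 1 per reversal", {
  set.seed(77)
  inv_perm <- function(v) {
    out <- integer(length(v))
    out[abs(v)] <- sign(v) * seq_along(v)
    out
  }
  for (r in 1:40) {
    n <- sample(3:8, 1)
    v <- random_signed_perm(n)
    d <- reversal_distance(signed_permutation(v))
    expect_equal(reversal_distance(signed_permutation(inv_perm(v))), d)
    i <- sample(n, 1); j <- i + sample.int(n - i + 1, 1) - 1
    d2 <- reversal_distance(apply_reversal(signed_permutation(v), i, j))
    expect_lte(abs(d2 - d), 1L)
  }
})

test_that("k planted reversals give distance <= k, circular and linear", {
  set.seed(31)
  for (r in 1:25) {
    n <- sample(6:20, 1)
    k <- sample(0:5, 1)
    topo <- sample(c("linear", "circular"), 1)
    ord <- as_signed_gene_order(paste0("g", 1:n), rep("+", n), "A",
                                topology = topo)
    mv <- apply_random_reversals(ord, k, seed = r)
    p <- build_joint_permutation(ord, mv$order)
    expect_lte(reversal_distance(p), k)
    if (k == 0) expect_equal(reversal_distance(p), 0L)
    if (k == 1) expect_equal(reversal_distance(p), 1L)
  }
})

test_that("the BFS oracle guards its state space", {
  expect_error(bfs_reversal_distance(signed_permutation(1:10)),
               class = "oracle_guard")
  circ <- signed_permutation(1:4, topology = "circular")
  expect_error(bfs_reversal_distance(circ), class = "topology_error")
})

test_that("circular distance is invariant under rotation and reflection", {
  set.seed(55)
  for (r in 1:15) {
    n <- sample(4:9, 1)
    v <- random_signed_perm(n)
    d0 <- reversal_distance(signed_permutation(v, topology = "circular"))
    k <- sample(n, 1)
    rot <- c(v[k:n], v[seq_len(k - 1)])[seq_len(n)]
    expect_equal(reversal_distance(signed_permutation(rot, topology = "circular")), d0)
    refl <- rev(-v)
    expect_equal(reversal_distance(signed_permutation(refl, topology = "circular")), d0)
  }
})

test_that("identical orders give one block covering all shared genes", {
  a <- as_signed_gene_order(paste0("g", 1:12),
                            rep(c("+", "-"), 6), "A", topology = "circular")
  b <- a; b$genome_id <- "B"
  blocks <- find_conserved_blocks(list(a, b))
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$length, 12)
  expect_setequal(blocks[[1]]$genes, paste0("g", 1:12))
})

test_that("an internal inversion splits the run at its boundaries", {
  a <- as_signed_gene_order(paste0("g", 1:10), rep("+", 10), "A")
  b <- apply_reversal(a, 4, 7)
  b$genome_id <- "B"
  blocks <- find_conserved_blocks(list(a, b), min_len = 2)
  genes <- lapply(blocks, `[[`, "genes")
  expect_setequal(vapply(genes, paste, character(1), collapse = ","),
                  c("g1,g2,g3", "g4,g5,g6,g7", "g8,g9,g10"))
})

test_that("a whole-block strand flip still counts as conserved", {
  a <- as_signed_gene_order(c("x", "y", "z", "w"), c("+", "-", "+", "+"), "A")
  # B carries y-z as a flipped unit elsewhere: (z-, y+) with signs negated
  b <- as_signed_gene_order(c("x", "w", "z", "y"), c("+", "+", "-", "+"), "B")
  blocks <- find_conserved_blocks(list(a, b), min_len = 2)
  expect_true(any(vapply(blocks, function(bl)
    identical(bl$genes, c("y", "z")), logical(1))))
  # per-gene sign flips without reordering are NOT conserved adjacencies
  c_ <- as_signed_gene_order(c("x", "y", "z", "w"), c("+", "+", "-", "+"), "C")
  blocks2 <- find_conserved_blocks(list(a, c_), min_len = 2)
  expect_false(any(vapply(blocks2, function(bl)
    all(c("y", "z") %in% bl$genes), logical(1))))
})

test_that("shuffled orientation-randomized orders yield no long blocks", {
  set.seed(404)
  a <- as_signed_gene_order(paste0("g", 1:40), rep("+", 40), "A")
  pairs <- 0; longer <- 0
  for (r in 1:10) {
    b <- as_signed_gene_order(sample(paste0("g", 1:40)),
                              sample(c("+", "-"), 40, TRUE), "B")
    bl <- find_conserved_blocks(list(a, b), min_len = 2)
    lens <- vapply(bl, `[[`, integer(1), "length")
    pairs <- pairs + sum(lens == 2)
    longer <- longer + sum(lens >= 3)
  }
  # a chance conserved adjacency has probability ~1/80 per gene pair, so a
  # couple of 2-gene blocks can appear over 10 shuffles; runs of 3+ cannot
  expect_equal(longer, 0)
  expect_lte(pairs, 8)
})

test_that("distance matrix over genomes is symmetric with zero diagonal", {
  simA <- simulate_genome(n_genes = 20, seed = 61)
  ordA <- signed_gene_order(simA$genome)
  mvB <- apply_random_reversals(ordA, 3, seed = 62)
  ordB <- mvB$order; ordB$genome_id <- "B"
  D <- genome_distance_matrix(list(ordA, ordB))
  expect_equal(diag(D), c(0L, 0L), ignore_attr = TRUE)
  expect_equal(D[1, 2], D[2, 1])
  expect_lte(D[1, 2], 3)
})
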