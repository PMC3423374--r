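# Signed gene orders, breakpoint-graph reversal distance, synteny blocks.
#
# The reversal (inversion) distance between two genomes is the minimum number
# of segment reversals -- each flipping both gene order and strand -- needed
# to transform one signed gene order into the other.  It is computed exactly
# with the Hannenhalli-Pevzner theory:
#
#   d = (n + 1) - c + h + f        (linear permutations)
#
# where c counts cycles of the breakpoint graph, h counts hurdles
# (unoriented components that do not separate other unoriented components)
# and f is 1 for a fortress (an odd number of hurdles, all of them
# superhurdles).  Circular gene orders are reduced to the linear problem by
# anchoring one marker.  An O(n^2) implementation is ample at organellar
# scale (n ~ 60).

#' Extract the signed gene order of a genome
#'
#' Genes are listed by locus start position along the genome; orientation is
#' the annotated strand.  Which feature classes enter the order is a flag:
#' the default includes all gene-like classes (protein, rRNA, tRNA, orf).
#'
#' @param genome an [annotated_genome()].
#' @param classes feature classes to include.
#' @return object of class `signed_gene_order`: list with `genome_id`,
#'   `entries` (data.frame name, sign with sign in +1/-1) and `topology`.
#' @export
signed_gene_order <- function(genome,
                              classes = c("protein", "rRNA", "tRNA", "orf")) {
  keep <- genome$features$cls %in% classes
  feats <- genome$features[keep, , drop = FALSE]
  start <- vapply(feats$segments, function(s) s[1, 1], integer(1))
  ord <- order(start)
  structure(list(
    genome_id = genome$id,
    entries = data.frame(name = feats$name[ord],
                         sign = ifelse(feats$strand[ord] == "+", 1L, -1L),
                         stringsAsFactors = FALSE),
    topology = if (genome$topology == "circular") "circular" else "linear"),
    class = "signed_gene_order")
}

#' Build a signed gene order directly from names and signs
#' @param names gene names in genomic order.
#' @param signs +1/-1 (or "+"/"-") orientations.
#' @param genome_id identifier.
#' @param topology "circular" or "linear".
#' @return `signed_gene_order`.
#' @export
as_signed_gene_order <- function(names, signs, genome_id = "order",
                                 topology = "linear") {
  if (is.character(signs)) signs <- ifelse(signs == "+", 1L, -1L)
  structure(list(genome_id = genome_id,
                 entries = data.frame(name = names, sign = as.integer(signs),
                                      stringsAsFactors = FALSE),
                 topology = topology),
            class = "signed_gene_order")
}

#' Express a query gene order as a signed permutation of a reference
#'
#' Restricts both orders to their shared, uniquely-named genes; the reference
#' defines the identity numbering `+1..+n` (and the + orientation); the query
#' is re-expressed in that numbering.  Genes with duplicated names in either
#' genome are dropped with a warning, since minimum-distance rearrangement
#' with duplicated markers is a different (much harder) problem.
#'
#' @param reference,query `signed_gene_order` objects.
#' @return object of class `signed_permutation`: list with `values` (signed
#'   integer vector, each of 1..n once), `topology`, and `genes` (the shared
#'   gene names in reference order).
#' @export
build_joint_permutation <- function(reference, query) {
  dup_r <- reference$entries$name[duplicated(reference$entries$name)]
  dup_q <- query$entries$name[duplicated(query$entries$name)]
  dropped <- union(dup_r, dup_q)
  if (length(dropped))
    warning(sprintf("dropping duplicated gene names from permutation: %s",
                    paste(dropped, collapse = ", ")))
  shared <- setdiff(intersect(reference$entries$name, query$entries$name),
                    dropped)
  if (length(shared) < 3)
    stop_dinomito("only %d shared genes after normalization (need >= 3)",
                  length(shared), class = "insufficient_overlap")
  re <- reference$entries[reference$entries$name %in% shared, ]
  qe <- query$entries[query$entries$name %in% shared, ]
  num <- setNames(seq_len(nrow(re)), re$name)
  sgn <- setNames(re$sign, re$name)
  values <- as.integer(num[qe$name] * qe$sign * sgn[qe$name])
  topo <- if (reference$topology == "circular" && query$topology == "circular")
    "circular" else "linear"
  structure(list(values = values, topology = topo, genes = re$name),
            class = "signed_permutation")
}

#' Construct a signed permutation from a vector
#' @param values signed integers, each magnitude 1..n exactly once.
#' @param topology "linear" or "circular".
#' @return `signed_permutation`.
#' @export
signed_permutation <- function(values, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  values <- as.integer(values)
  if (length(values) && !identical(sort(abs(values)), seq_along(values)))
    stop_dinomito("not a signed permutation of 1..n", class = "bad_permutation")
  structure(list(values = values, topology = topology, genes = NULL),
            class = "signed_permutation")
}

# rotate/reflect a circular signed permutation so that +1 leads, then drop it
# and renumber: reversal distance on a circle of n markers equals the linear
# distance of this (n-1)-marker reduction.
canonicalize_circular <- function(values) {
  i <- which(abs(values) == 1L)
  if (values[i] < 0) {                       # reflect the circle
    values <- rev(-values)
    i <- which(abs(values) == 1L)
  }
  if (i > 1) values <- c(values[i:length(values)], values[seq_len(i - 1)])
  v <- values[-1]
  as.integer(sign(v) * (abs(v) - 1L))
}

#' Minimum signed reversal distance to the identity
#'
#' Exact Hannenhalli-Pevzner distance via the breakpoint graph with cycle,
#' hurdle and fortress accounting.  Circular permutations are reduced to the
#' linear problem by anchoring marker 1 (rotating, and reflecting if needed).
#'
#' @param perm a `signed_permutation` (or a plain signed integer vector,
#'   treated as linear).
#' @return non-negative integer distance.
#' @export
reversal_distance <- function(perm) {
  if (!inherits(perm, "signed_permutation")) perm <- signed_permutation(perm)
  values <- perm$values
  if (perm$topology == "circular") {
    if (length(values) <= 1) return(0L)
    values <- canonicalize_circular(values)
  }
  hp_linear_distance(values)
}

hp_linear_distance <- function(values) {
  n <- length(values)
  if (n == 0L) return(0L)
  # unsigned doubling: +x -> (2x-1, 2x), -x -> (2x, 2x-1); extend with 0 and
  # 2n+1.  u has length 2n+2; positions are 0-based below.
  u <- integer(2 * n + 2)
  u[1] <- 0L
  for (i in seq_len(n)) {
    x <- values[i]
    u[2 * i] <- if (x > 0) 2L * x - 1L else -2L * x
    u[2 * i + 1] <- if (x > 0) 2L * x else -2L * x - 1L
  }
  u[2 * n + 2] <- 2L * n + 1L
  pos <- integer(2 * n + 2)          # pos[v+1] = 0-based position of value v
  pos[u + 1L] <- 0:(2 * n + 1)

  # black edge i (i = 0..n) joins positions 2i and 2i+1; contracting black
  # edges, gray edges (2j <-> 2j+1) connect black-edge nodes: connected
  # components of that multigraph are the cycles of the breakpoint graph.
  parent <- 0:n
  find <- function(a) { while (parent[a + 1L] != a) { parent[a + 1L] <<- parent[parent[a + 1L] + 1L]; a <- parent[a + 1L] }; a }
  gray_pos <- matrix(0L, n + 1, 2)   # position endpoints of gray edge j
  oriented_edge <- logical(n + 1)
  for (j in 0:n) {
    p <- pos[2L * j + 1L]            # position of value 2j
    q <- pos[2L * j + 2L]            # position of value 2j+1
    gray_pos[j + 1, ] <- c(min(p, q), max(p, q))
    oriented_edge[j + 1] <- (p %% 2L) == (q %% 2L)
    r1 <- find(p %/% 2L); r2 <- find(q %/% 2L)
    if (r1 != r2) parent[r1 + 1L] <- r2
  }
  cyc <- vapply(0:n, find, integer(1))           # cycle id per black edge
  c_cycles <- length(unique(cyc))

  # components of the interleaving graph: cycles whose gray edges cross are
  # merged (crossing = intervals overlap without nesting)
  cyc_of_gray <- cyc[gray_pos[, 1] %/% 2L + 1L]
  cparent <- 0:n
  cfind <- function(a) { while (cparent[a + 1L] != a) { cparent[a + 1L] <<- cparent[cparent[a + 1L] + 1L]; a <- cparent[a + 1L] }; a }
  cunion <- function(a, b) { ra <- cfind(a); rb <- cfind(b)
    if (ra != rb) cparent[ra + 1L] <<- rb }
  for (a in seq_len(n + 1)) {
    for (b in seq_len(n + 1)) {
      if (b <= a) next
      s1 <- gray_pos[a, 1]; e1 <- gray_pos[a, 2]
      s2 <- gray_pos[b, 1]; e2 <- gray_pos[b, 2]
      crosses <- (s1 < s2 && s2 < e1 && e1 < e2) ||
                 (s2 < s1 && s1 < e2 && e2 < e1)
      if (crosses) cunion(cyc_of_gray[a], cyc_of_gray[b])
    }
  }
  comp <- vapply(cyc, cfind, integer(1))         # component id per black edge
  comp_ids <- unique(comp)
  comp_sizes <- vapply(comp_ids, function(k) sum(comp == k), integer(1))
  comp_oriented <- vapply(comp_ids, function(k)
    any(oriented_edge[comp[gray_pos[, 1] %/% 2L + 1L] == k]), logical(1))
  unoriented <- comp_ids[comp_sizes > 1 & !comp_oriented]

  h <- 0L; f <- 0L
  if (length(unoriented)) {
    # a component is a hurdle iff its black-edge indices are cyclically
    # consecutive within the merged index list of all unoriented components
    # (i.e. it does not separate two other unoriented components)
    seq_ids <- comp[comp %in% unoriented]
    hurdle_ids <- hurdles_of(seq_ids)
    h <- length(hurdle_ids)
    if (h > 0 && h %% 2L == 1L) {
      super <- vapply(hurdle_ids, function(hid) {
        rest <- seq_ids[seq_ids != hid]
        newly <- setdiff(hurdles_of(rest), hurdles_of(seq_ids))
        length(newly) > 0
      }, logical(1))
      if (length(super) && all(super)) f <- 1L
    }
  }
  as.integer((n + 1L) - c_cycles + h + f)
}

# which component ids occur as one cyclically-consecutive run
hurdles_of <- function(seq_ids) {
  ids <- unique(seq_ids)
  if (length(ids) <= 1) return(ids)
  vapply(ids, function(k) {
    m <- seq_ids == k
    # runs of k, treating the sequence as a cycle
    r <- rle(m)$values
    nruns <- sum(r)
    if (nruns > 1 && m[1] && m[length(m)]) nruns <- nruns - 1L
    nruns == 1L
  }, logical(1)) |> (\(ok) ids[ok])()
}

#' Exact reversal distance by breadth-first search (test oracle)
#'
#' Independent exact distance computed by bidirectional breadth-first search
#' over all reversal moves (implemented in C++ over packed 64-bit states).
#' Only linear permutations of n <= 9 are accepted; this is the validation
#' oracle for [reversal_distance()], sharing none of its theory.
#'
#' @param perm a linear `signed_permutation` (or plain signed vector), n <= 9.
#' @return non-negative integer distance.
#' @export
bfs_reversal_distance <- function(perm) {
  if (!inherits(perm, "signed_permutation")) perm <- signed_permutation(perm)
  if (perm$topology != "linear")
    stop_dinomito("BFS oracle handles linear permutations only",
                  class = "topology_error")
  n <- length(perm$values)
  if (n > 9)
    stop_dinomito("BFS oracle limited to n <= 9 (state-space guard), got %d",
                  n, class = "oracle_guard")
  if (n == 0) return(0L)
  bfs_reversal_distance_cpp(perm$values)
}

#' Apply one reversal to a signed permutation or gene order
#' @param x `signed_permutation` or `signed_gene_order`.
#' @param i,j 1-based inclusive interval to reverse (order and signs flip).
#' @return object of the same class.
#' @export
apply_reversal <- function(x, i, j) {
  stopifnot(i >= 1, j >= i)
  if (inherits(x, "signed_permutation")) {
    stopifnot(j <= length(x$values))
    x$values[i:j] <- -rev(x$values[i:j])
  } else if (inherits(x, "signed_gene_order")) {
    stopifnot(j <= nrow(x$entries))
    x$entries[i:j, ] <- x$entries[j:i, ]
    x$entries$sign[i:j] <- -x$entries$sign[i:j]
  } else stop("unsupported class")
  x
}

#' Pairwise reversal-distance matrix for a set of genomes
#'
#' @param genomes list of [annotated_genome()] objects (or
#'   `signed_gene_order`s).
#' @param classes feature classes entering the permutation (flag, since
#'   published distance tables rarely state their marker set).
#' @param topology "auto" (circular when both genomes are circular),
#'   "circular" or "linear".
#' @return symmetric integer matrix with genome ids as dimnames.
#' @export
genome_distance_matrix <- function(genomes,
                                   classes = c("protein", "rRNA", "tRNA", "orf"),
                                   topology = "auto") {
  orders <- lapply(genomes, function(g)
    if (inherits(g, "signed_gene_order")) g else signed_gene_order(g, classes))
  m <- length(orders)
  ids <- vapply(orders, `[[`, character(1), "genome_id")
  D <- matrix(0L, m, m, dimnames = list(ids, ids))
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    perm <- build_joint_permutation(orders[[a]], orders[[b]])
    if (topology != "auto") perm$topology <- topology
    D[a, b] <- D[b, a] <- reversal_distance(perm)
  }
  D
}

#' Find conserved synteny blocks across gene orders
#'
#' A block is a maximal run of genes, consecutive in every member genome
#' (after restriction to the genes shared by all orders), with adjacency and
#' relative orientation preserved -- a whole-block strand flip is allowed,
#' per-gene flips are not.
#'
#' @param orders list of >= 2 `signed_gene_order` objects.
#' @param min_len minimum block length in genes.
#' @return list of blocks; each is a list with `genes`, `pattern`
#'   (orientations in the first order, "+"/"-"), `genomes`, `length`.
#' @export
find_conserved_blocks <- function(orders, min_len = 2L) {
  stopifnot(length(orders) >= 2)
  shared <- Reduce(intersect, lapply(orders, function(o) {
    nm <- o$entries$name
    nm[!nm %in% nm[duplicated(nm)]]
  }))
  if (!length(shared)) return(list())
  restr <- lapply(orders, function(o) {
    e <- o$entries[o$entries$name %in% shared, ]
    list(name = e$name, sign = e$sign, circular = o$topology == "circular",
         idx = setNames(seq_len(nrow(e)), e$name),
         sgn = setNames(e$sign, e$name))
  })
  ref <- restr[[1]]
  n <- length(ref$name)
  if (n < min_len) return(list())
  adj_ok <- function(g, a, sa, b, sb) {
    ia <- g$idx[[a]]; ib <- g$idx[[b]]
    ga <- g$sgn[[a]]; gb <- g$sgn[[b]]
    m <- length(g$idx)
    nxt <- function(i) if (g$circular) (i %% m) + 1L else i + 1L
    (nxt(ia) == ib && ga == sa && gb == sb) ||
      (nxt(ib) == ia && ga == -sa && gb == -sb)
  }
  n_adj <- if (ref$circular) n else n - 1L
  preserved <- vapply(seq_len(n_adj), function(i) {
    j <- (i %% n) + 1L
    all(vapply(restr[-1], adj_ok, logical(1),
               a = ref$name[i], sa = ref$sign[i],
               b = ref$name[j], sb = ref$sign[j]))
  }, logical(1))
  ids <- vapply(orders, `[[`, character(1), "genome_id")
  if (all(preserved) && ref$circular) {
    return(list(list(genes = ref$name,
                     pattern = ifelse(ref$sign > 0, "+", "-"),
                     genomes = ids, length = n)))
  }
  # maximal runs of preserved adjacencies (cyclic for circular references)
  blocks <- list()
  brk <- which(!preserved)
  if (ref$circular) {
    starts <- (brk %% n) + 1L
    for (s in starts) {
      genes <- s
      i <- s
      while (preserved[((i - 1L) %% n) + 1L] %||% FALSE) {
        i <- (i %% n) + 1L
        genes <- c(genes, i)
        if (length(genes) == n) break
      }
      if (length(genes) >= min_len)
        blocks[[length(blocks) + 1]] <-
          list(genes = ref$name[genes],
               pattern = ifelse(ref$sign[genes] > 0, "+", "-"),
               genomes = ids, length = length(genes))
    }
  } else {
    r <- rle(preserved)
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      genes <- pos[k]:(pos[k] + r$lengths[k])   # run of adjacencies -> +1 gene
      if (length(genes) >= min_len)
        blocks[[length(blocks) + 1]] <-
          list(genes = ref$name[genes],
               pattern = ifelse(ref$sign[genes] > 0, "+", "-"),
               genomes = ids, length = length(genes))
    }
  }
  blocks
}

#' Render synteny blocks as a data.frame
#' @param blocks result of [find_conserved_blocks()].
#' @return data.frame with columns block, length, genes, pattern, genomes.
#' @export
blocks_table <- function(blocks) {
  if (!length(blocks))
    return(data.frame(block = integer(), length = integer(), genes = character(),
                      pattern = character(), genomes = character()))
  data.frame(
    block = seq_along(blocks),
    length = vapply(blocks, `[[`, integer(1), "length"),
    genes = vapply(blocks, function(b) paste(b$genes, collapse = "-"), character(1)),
    pattern = vapply(blocks, function(b) paste(b$pattern, collapse = ""), character(1)),
    genomes = vapply(blocks, function(b) paste(b$genomes, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
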