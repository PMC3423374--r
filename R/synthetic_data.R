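# Seeded synthetic data with full ground truth.
#
# The generators emulate the statistical structure of a compact diatom-type
# mitochondrial genome (~58 genes in three classes plus a couple of ORFs,
# mean protein gene ~793 bp, mean spacer ~58 bp, GC ~31%, strong A/T bias at
# third codon positions) and of the dinoflagellate-type host data
# (substitutional editing pairs, split genes rejoined in transcripts,
# pseudogene contigs: high-identity gene fragments in unrelated flanks).
# Every generator takes a single integer seed; each stage draws from its own
# named stream, so adding a stage never perturbs another stage's draws, and
# a fixed seed reproduces byte-identical output.

MITO_PROTEIN_NAMES <- c(
  "cox1", "cox2", "cox3", "cob", "atp6", "atp8", "atp9",
  "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6", "nad7", "nad9",
  "nad11a", "nad11b", "tatC",
  "rps2", "rps3", "rps4", "rps7", "rps8", "rps10", "rps11", "rps12", "rps13",
  "rps14", "rps19", "rpl2", "rpl5", "rpl6", "rpl14", "rpl16", "rpl31")
MITO_TRNA_NAMES <- paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I",
                                   "K", "L", "M", "N", "P", "Q", "R", "S",
                                   "V", "W", "Y", "Mf", "L2", "S2", "G2",
                                   "R2", "S3"))
MITO_RRNA_NAMES <- c("rns", "rnl")

random_dna <- function(n, gc = 0.31) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# sense codons with independent per-position base frequencies; stops rejected
random_sense_codons <- function(ncod, gc12, at3) {
  p12 <- c(A = (1 - gc12) / 2, C = gc12 / 2, G = gc12 / 2, T = (1 - gc12) / 2)
  p3 <- c(A = at3 / 2, C = (1 - at3) / 2, G = (1 - at3) / 2, T = at3 / 2)
  draw <- function(k) paste0(sample(names(p12), k, TRUE, p12),
                             sample(names(p12), k, TRUE, p12),
                             sample(names(p3), k, TRUE, p3))
  cods <- draw(ncod)
  repeat {
    bad <- cods %in% c("TAA", "TAG", "TGA")
    if (!any(bad)) break
    cods[bad] <- draw(sum(bad))
  }
  cods
}

random_protein_gene <- function(len_nt, gc12, at3) {
  ncod <- max(40L, round(len_nt / 3))
  paste0("ATG",
         paste(random_sense_codons(ncod - 2L, gc12, at3), collapse = ""),
         sample(c("TAA", "TAG"), 1, prob = c(0.7, 0.3)))
}

#' Substitute random point mutations into a sequence
#' @param seq DNA string.
#' @param n_mut number of substitution positions (distinct).
#' @return mutated string.
#' @export
mutate_seq <- function(seq, n_mut) {
  if (n_mut <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), min(n_mut, length(chars)))
  for (p in pos)
    chars[p] <- sample_int(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# assemble a genome from an ordered parts table; overlap_with > 0 makes a
# part start inside the previous part's tail (the genomic sequence of the
# overlap belongs to the upstream gene)
assemble_genome <- function(id, parts, spacers, topology = "circular",
                            gc = 0.31, translation_table = 1L) {
  n <- nrow(parts)
  stopifnot(length(spacers) >= n)
  chunks <- character(0)
  feats <- empty_features()
  cursor <- 0L
  for (i in seq_len(n)) {
    sp <- spacers[i]
    gseq <- if (parts$strand[i] == "-") revcomp(parts$seq[i]) else parts$seq[i]
    len <- nchar(gseq)
    if (sp >= 0) {
      if (sp > 0) { chunks <- c(chunks, random_dna(sp, gc)); cursor <- cursor + sp }
      start <- cursor + 1L
      chunks <- c(chunks, gseq)
      cursor <- cursor + len
    } else {
      d <- min(-sp, cursor - 1L, len - 1L)
      start <- cursor - d + 1L
      chunks <- c(chunks, substr(gseq, d + 1L, len))
      cursor <- cursor + len - d
    }
    feats <- rbind(feats, gene_feature(parts$name[i], parts$cls[i],
                                       parts$strand[i], c(start, cursor),
                                       complete = TRUE))
  }
  if (topology == "circular" && length(spacers) > n && spacers[n + 1] > 0)
    chunks <- c(chunks, random_dna(spacers[n + 1], gc))
  annotated_genome(id, paste(chunks, collapse = ""), feats,
                   topology = topology, translation_table = translation_table)
}

#' Simulate a compact annotated organellar genome
#'
#' Defaults are sized to a dinotom-endosymbiont-style genome: 58 genes (33
#' protein-coding, 2 rRNA, 23 tRNA), mean protein gene 793 nt, mean spacer
#' 58 nt, GC 31%, third-codon-position A+T 79%, circular topology, a few
#' small gene overlaps (downstream tRNA starting inside the upstream gene's
#' tail), universal genetic code.
#'
#' @param n_genes total gene count.
#' @param class_mix proportions for protein/rRNA/tRNA (orf genes come out of
#'   the protein share via `n_orfs`).
#' @param protein_len_mean,protein_len_sd protein gene length distribution
#'   (nt, including stop codon).
#' @param rrna_lengths lengths of the rRNA genes (recycled to the rRNA
#'   count).
#' @param trna_len_mean tRNA gene length (nt, sd 4).
#' @param spacer_mean mean intergenic spacer (nt; exponential).
#' @param gc overall genomic GC fraction.
#' @param third_pos_at A+T fraction at third codon positions of protein
#'   genes; first/second-position composition is derived so total GC comes
#'   out at `gc`.
#' @param n_orfs how many genes are spurious ORFs (class `orf`).
#' @param n_overlaps how many adjacent gene pairs overlap.
#' @param topology genome topology.
#' @param translation_table genetic code.
#' @param seed integer seed.
#' @return list with `genome` (an [annotated_genome()]) and `truth`
#'   (generator bookkeeping: per-gene table, spacer lengths, overlap pairs,
#'   parameters, seed).
#' @export
simulate_genome <- function(n_genes = 58L,
                            class_mix = c(protein = 33, rRNA = 2, tRNA = 23) / 58,
                            protein_len_mean = 793, protein_len_sd = 220,
                            rrna_lengths = c(1600L, 2700L),
                            trna_len_mean = 72, spacer_mean = 58,
                            gc = 0.3102, third_pos_at = 0.79,
                            n_orfs = 2L, n_overlaps = 4L,
                            topology = "circular", translation_table = 1L,
                            seed = 1L) {
  stopifnot(n_genes >= 1, all(class_mix >= 0))
  class_mix <- class_mix / sum(class_mix)
  n_trna <- round(n_genes * class_mix[["tRNA"]])
  n_rrna <- min(round(n_genes * class_mix[["rRNA"]]), length(MITO_RRNA_NAMES))
  n_prot <- n_genes - n_trna - n_rrna
  if (n_prot < 0) stop_dinomito("class mix infeasible for n_genes=%d", n_genes,
                                class = "bad_parameters")
  n_orfs <- min(n_orfs, n_prot)
  gc12 <- min(0.95, max(0.05, (3 * gc - (1 - third_pos_at)) / 2))

  parts <- with_stage_seed(seed, "genome-layout", {
    prot_names <- c(head(MITO_PROTEIN_NAMES, n_prot - n_orfs),
                    if (n_prot - n_orfs > length(MITO_PROTEIN_NAMES))
                      sprintf("yej%d", seq_len(n_prot - n_orfs -
                                                 length(MITO_PROTEIN_NAMES))))
    orf_names <- if (n_orfs) sprintf("orf%d", 100 + seq_len(n_orfs)) else character()
    trna_names <- c(head(MITO_TRNA_NAMES, n_trna),
                    if (n_trna > length(MITO_TRNA_NAMES))
                      sprintf("trnX%d", seq_len(n_trna - length(MITO_TRNA_NAMES))))
    df <- data.frame(
      name = c(prot_names, orf_names, head(MITO_RRNA_NAMES, n_rrna), trna_names),
      cls = c(rep("protein", n_prot - n_orfs), rep("orf", n_orfs),
              rep("rRNA", n_rrna), rep("tRNA", n_trna)),
      stringsAsFactors = FALSE)
    df <- df[sample.int(nrow(df)), ]
    df$strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
    df
  })

  parts$seq <- with_stage_seed(seed, "genome-sequences", {
    vapply(seq_len(nrow(parts)), function(i) {
      switch(parts$cls[i],
             protein = ,
             orf = random_protein_gene(
               rnorm(1, protein_len_mean, protein_len_sd), gc12, third_pos_at),
             rRNA = random_dna(rep_len(rrna_lengths,
                                       sum(parts$cls == "rRNA"))[
                                         cumsum(parts$cls == "rRNA")[i]], gc),
             tRNA = random_dna(max(60L, round(rnorm(1, trna_len_mean, 4))), gc))
    }, character(1))
  })

  layout <- with_stage_seed(seed, "genome-spacers", {
    nsp <- nrow(parts) + as.integer(topology == "circular")
    spacers <- pmax(0L, round(rexp(nsp, 1 / spacer_mean)))
    ov_idx <- integer(0)
    if (n_overlaps > 0) {
      # overlap candidates: adjacencies whose downstream gene is a tRNA
      # (tRNA sequences have no codon structure to corrupt)
      cand <- which(parts$cls == "tRNA" & seq_len(nrow(parts)) > 1)
      ov_idx <- sample_int(cand, min(n_overlaps, length(cand)))
      spacers[ov_idx] <- -sample(1:15, length(ov_idx), replace = TRUE)
    }
    list(spacers = spacers, ov_idx = ov_idx)
  })

  genome <- with_stage_seed(seed, "genome-assembly",
    assemble_genome(sprintf("sim%06d", abs(seed) %% 1000000), parts,
                    layout$spacers, topology = topology, gc = gc,
                    translation_table = translation_table))

  truth <- list(seed = seed,
                genes = data.frame(name = parts$name, cls = parts$cls,
                                   strand = parts$strand,
                                   length = nchar(parts$seq),
                                   stringsAsFactors = FALSE),
                spacers = layout$spacers[layout$spacers >= 0],
                overlap_pairs = if (length(layout$ov_idx))
                  data.frame(gene1 = parts$name[layout$ov_idx - 1],
                             gene2 = parts$name[layout$ov_idx])
                else data.frame(gene1 = character(), gene2 = character()),
                params = list(n_genes = n_genes, gc = gc,
                              third_pos_at = third_pos_at,
                              protein_len_mean = protein_len_mean,
                              spacer_mean = spacer_mean, topology = topology))
  list(genome = genome, truth = truth)
}

#' Apply k random reversals to a signed gene order
#'
#' Intervals are chosen uniformly among all (i <= j) index pairs; each
#' reversal flips order and orientation.  The truth records the intervals,
#' so downstream distance estimates can be checked against the planted k
#' (the true minimum distance is <= k).
#'
#' @param order a `signed_gene_order` (or `signed_permutation`).
#' @param k number of reversals.
#' @param seed integer seed.
#' @return list with `order` (same class as input) and `truth` (matrix of
#'   intervals).
#' @export
apply_random_reversals <- function(order, k, seed = 1L) {
  n <- if (inherits(order, "signed_permutation")) length(order$values)
  else nrow(order$entries)
  ivals <- with_stage_seed(seed, "reversals", {
    if (k == 0) matrix(integer(), 0, 2) else
      t(vapply(seq_len(k), function(r) sort(sample.int(n, 2, replace = TRUE)),
               integer(2)))
  })
  for (r in seq_len(nrow(ivals)))
    order <- apply_reversal(order, ivals[r, 1], ivals[r, 2])
  list(order = order, truth = list(intervals = ivals, k = k, seed = seed))
}

#' Simulate a DNA/cDNA editing pair
#'
#' Plants exactly `n_sites` distinct substitution positions in a transcript
#' copy of the CDS; no indels.  Default weights mirror dinoflagellate host
#' editing: mostly A->G, some T->C and C->T, rarely G->C, at codon positions
#' 1-2.
#'
#' @param cds coding sequence (DNA).
#' @param n_sites number of planted sites.
#' @param type_weights named weights over substitution types ("A>G", ...).
#' @param codon_pos_weights length-3 weights over codon positions.
#' @param seed integer seed.
#' @return list with `transcript` and `truth` (data.frame position, from,
#'   to, codon_position).
#' @export
simulate_editing_pair <- function(cds, n_sites = 11L,
                                  type_weights = c("A>G" = 0.60, "T>C" = 0.20,
                                                   "C>T" = 0.12, "G>C" = 0.08),
                                  codon_pos_weights = c(0.5, 0.5, 0),
                                  seed = 1L) {
  cds <- toupper(cds)
  chars <- strsplit(cds, "")[[1]]
  codon_pos <- (seq_along(chars) - 1) %% 3 + 1
  truth <- with_stage_seed(seed, "editing-sites", {
    used <- logical(length(chars))
    rows <- list()
    tries <- 0
    while (length(rows) < n_sites && tries < 1000 * max(1, n_sites)) {
      tries <- tries + 1
      ty <- sample_int(names(type_weights), 1, prob = type_weights)
      cp <- sample_int(1:3, 1, prob = codon_pos_weights)
      from <- substr(ty, 1, 1); to <- substr(ty, 3, 3)
      cand <- which(chars == from & codon_pos == cp & !used)
      if (!length(cand)) next
      p <- sample_int(cand, 1)
      used[p] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(position = p, from = from,
                                             to = to, codon_position = cp,
                                             stringsAsFactors = FALSE)
    }
    if (length(rows) < n_sites)
      stop_dinomito("could not place %d sites with the given weights", n_sites,
                    class = "bad_parameters")
    if (length(rows)) do.call(rbind, rows)[order(vapply(rows, `[[`, integer(1),
                                                        "position")), ]
    else data.frame(position = integer(), from = character(), to = character(),
                    codon_position = integer())
  })
  tx <- chars
  tx[truth$position] <- truth$to
  list(transcript = paste(tx, collapse = ""), truth = truth)
}

#' Simulate a pseudogene fragment set from one reference gene
#'
#' Each fragment carries one gene-derived span (length uniform in
#' `span_len`, start uniform over feasible placements, mutated down to a
#' sampled identity level) embedded between random unrelated flanks, on a
#' random strand.  Default identity levels follow the observed regime
#' (99-100% identity).
#'
#' @param gene named character vector of length 1 (the reference gene).
#' @param n_fragments number of contigs.
#' @param span_len length-2 range of gene-derived span lengths (nt).
#' @param identity_levels identity fractions sampled per fragment.
#' @param flank_len length-2 range of each flank's length (nt).
#' @param gc GC fraction of the flanks.
#' @param seed integer seed.
#' @return list with `fragments` (named character vector) and `truth`
#'   (data.frame fragment, gene_start, gene_end, orientation, identity,
#'   flank_left, flank_right).
#' @export
simulate_pseudogene_set <- function(gene, n_fragments = 20L,
                                    span_len = c(100L, 500L),
                                    identity_levels = c(0.99, 1.0),
                                    flank_len = c(30L, 300L),
                                    gc = 0.35, seed = 1L) {
  stopifnot(length(gene) == 1, !is.null(names(gene)))
  gname <- names(gene)[1]
  gseq <- toupper(gene[[1]])
  G <- nchar(gseq)
  with_stage_seed(seed, "pseudogenes", {
    rows <- list(); frags <- character(0)
    for (i in seq_len(n_fragments)) {
      L <- sample(span_len[1]:min(span_len[2], G), 1)
      s <- sample.int(G - L + 1, 1)
      lvl <- sample_int(identity_levels, 1)
      core <- mutate_seq(substr(gseq, s, s + L - 1), round((1 - lvl) * L))
      fl <- sample(flank_len[1]:flank_len[2], 2, replace = TRUE)
      ori <- sample(c("+", "-"), 1)
      body <- paste0(random_dna(fl[1], gc), core, random_dna(fl[2], gc))
      if (ori == "-") body <- revcomp(body)
      id <- sprintf("contig%03d", i)
      frags[id] <- body
      rows[[i]] <- data.frame(
        fragment = id, gene = gname, gene_start = s, gene_end = s + L - 1,
        orientation = ori, identity = lvl,
        flank_left = if (ori == "+") fl[1] else fl[2],
        flank_right = if (ori == "+") fl[2] else fl[1],
        stringsAsFactors = FALSE)
    }
    list(fragments = frags,
         truth = if (length(rows)) do.call(rbind, rows) else
           data.frame(fragment = character(), gene = character(),
                      gene_start = integer(), gene_end = integer(),
                      orientation = character(), identity = numeric(),
                      flank_left = integer(), flank_right = integer()))
  })
}

#' Simulate structural events on an annotated genome
#'
#' Produces modified genomes and sequence sets carrying planted events, with
#' full truth, for exercising the detectors:
#' \describe{
#'   \item{fission}{one protein gene split into `a`/`b` parts (new stop for
#'     part a, new start for part b, part b relocated to the opposite strand
#'     elsewhere in the genome).}
#'   \item{fusion}{two adjacent same-strand protein genes concatenated in
#'     frame (upstream stop lost, downstream initiator retained); the pair
#'     is made adjacent in the companion genome.}
#'   \item{insert}{an in-frame insertion planted into one gene; returns
#'     in-group homolog copies carrying it and outgroup copies without.}
#'   \item{splice}{one gene split in two trans-spliced pieces; the
#'     transcript rejoins them with a junction insert and upstream edits.}
#' }
#'
#' @param genome an [annotated_genome()] (typically from
#'   [simulate_genome()]).
#' @param event_spec list with any of `fission`, `fusion`, `insert`,
#'   `splice`; each either `TRUE` (defaults) or a list of options:
#'   fission `gene`, `at_frac`; fusion none; insert `gene`, `len_nt`,
#'   `divergence`; splice `gene`, `at_frac`, `junction_insert`, `n_edits`.
#' @param seed integer seed.
#' @return named list, one element per requested event, each with the
#'   materials the corresponding detector consumes plus a `truth` entry.
#'   An empty spec yields an empty list.
#' @export
simulate_structural_events <- function(genome, event_spec = list(), seed = 1L) {
  out <- list()
  prot_idx <- which(genome$features$cls == "protein")
  get_cds <- function(i) spliced_sequence(genome, genome$features[i, ])
  opt <- function(spec, key, default) {
    if (is.list(spec) && !is.null(spec[[key]])) spec[[key]] else default
  }

  if (!is.null(event_spec$fission)) {
    out$fission <- with_stage_seed(seed, "event-fission", {
      gname <- opt(event_spec$fission, "gene",
                   sample_int(genome$features$name[prot_idx], 1))
      i <- match(gname, genome$features$name)
      cds <- get_cds(i)
      naa <- nchar(cds) %/% 3 - 1
      frac <- opt(event_spec$fission, "at_frac", runif(1, 0.3, 0.7))
      b <- max(10L, min(naa - 10L, round(naa * frac)))
      part_a <- paste0(substr(cds, 1, 3 * b), "TAA")
      part_b <- paste0("ATG", substr(cds, 3 * b + 1, nchar(cds)))
      parent_protein <- sub("\\*$", "", translate_cds(cds, mode = "open_frame"))
      list(parent_gene = gname,
           parent_protein = parent_protein,
           part_proteins = setNames(
             c(sub("\\*$", "", translate_cds(part_a, mode = "open_frame")),
               sub("\\*$", "", translate_cds(part_b, mode = "open_frame"))),
             paste0(gname, c("a", "b"))),
           truth = list(gene = gname, breakpoint_aa = b))
    })
  }

  if (!is.null(event_spec$fusion)) {
    out$fusion <- with_stage_seed(seed, "event-fusion", {
      base <- feature_table(genome)
      parts <- data.frame(name = genome$features$name,
                          cls = genome$features$cls,
                          strand = genome$features$strand,
                          stringsAsFactors = FALSE)
      parts$seq <- vapply(seq_len(nrow(parts)), get_cds, character(1))
      pp <- which(parts$cls == "protein")
      g1 <- sample_int(pp, 1)
      g2 <- sample_int(setdiff(pp, g1), 1)
      # companion genome B: the two genes adjacent, separate, same strand
      ordB <- c(setdiff(seq_len(nrow(parts)), c(g1, g2)))
      at <- sample.int(length(ordB) + 1, 1) - 1
      ordB <- append(ordB, c(g1, g2), after = at)
      partsB <- parts[ordB, ]
      partsB$strand[partsB$name %in% parts$name[c(g1, g2)]] <- "+"
      spB <- pmax(0L, round(rexp(nrow(partsB) + 1, 1 / 40)))
      genomeB <- assemble_genome(paste0(genome$id, "_sep"), partsB, spB,
                                 topology = genome$topology, gc = 0.31,
                                 translation_table = genome$translation_table)
      # genome A: same layout but the pair fused in frame
      fused_seq <- paste0(substr(parts$seq[g1], 1, nchar(parts$seq[g1]) - 3),
                          parts$seq[g2])
      partsA <- partsB[!partsB$name %in% parts$name[g2], ]
      fi <- match(parts$name[g1], partsA$name)
      partsA$name[fi] <- paste0(parts$name[g1], "-", parts$name[g2])
      partsA$seq[fi] <- fused_seq
      genomeA <- assemble_genome(paste0(genome$id, "_fused"), partsA, spB,
                                 topology = genome$topology, gc = 0.31,
                                 translation_table = genome$translation_table)
      list(genomeA = genomeA, genomeB = genomeB,
           truth = list(upstream = parts$name[g1], downstream = parts$name[g2],
                        fused_gene = partsA$name[fi]))
    })
  }

  if (!is.null(event_spec$insert)) {
    out$insert <- with_stage_seed(seed, "event-insert", {
      gname <- opt(event_spec$insert, "gene",
                   sample_int(genome$features$name[prot_idx], 1))
      len_nt <- opt(event_spec$insert, "len_nt", 150L)
      div <- opt(event_spec$insert, "divergence", 0)
      stopifnot(len_nt %% 3 == 0)
      i <- match(gname, genome$features$name)
      cds <- get_cds(i)
      naa <- nchar(cds) %/% 3 - 1
      at <- sample(seq(10L, naa - 10L), 1)
      ins <- paste(random_sense_codons(len_nt %/% 3, 0.36, 0.79), collapse = "")
      with_ins <- paste0(substr(cds, 1, 3 * at), ins,
                         substr(cds, 3 * at + 1, nchar(cds)))
      mut <- function(s) mutate_seq(s, round(div * nchar(s)))
      list(ingroup = setNames(c(mut(with_ins), mut(with_ins)),
                              paste0(gname, c("_db", "_kf"))),
           outgroups = setNames(c(mut(cds), mut(cds)),
                                paste0(gname, c("_pt", "_tp"))),
           truth = list(gene = gname, aa_start = at + 1L,
                        aa_end = at + len_nt %/% 3, len_nt = len_nt))
    })
  }

  if (!is.null(event_spec$splice)) {
    out$splice <- with_stage_seed(seed, "event-splice", {
      gname <- opt(event_spec$splice, "gene",
                   sample_int(genome$features$name[prot_idx], 1))
      jins <- opt(event_spec$splice, "junction_insert", "AAAAA")
      n_edits <- opt(event_spec$splice, "n_edits", 10L)
      i <- match(gname, genome$features$name)
      cds <- sub("(TAA|TAG|TGA)$", "", get_cds(i))
      naa <- nchar(cds) %/% 3
      frac <- opt(event_spec$splice, "at_frac", runif(1, 0.4, 0.7))
      b <- max(10L, min(naa - 10L, round(naa * frac)))
      part1 <- substr(cds, 1, 3 * b)
      part2 <- substr(cds, 3 * b + 1, nchar(cds))
      ed <- simulate_editing_pair(part1, n_sites = n_edits,
                                  seed = stage_seed(seed, "splice-edits"))
      transcript <- paste0(ed$transcript, jins, part2)
      list(part1 = part1, part2 = part2, transcript = transcript,
           truth = list(gene = gname, junction_aa = c(b, b + 1L),
                        insert = jins, edits = ed$truth))
    })
  }
  out
}
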