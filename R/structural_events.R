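# Gene-level structural events: fission, fusion, in-frame insertion, intron
# interruption, trans-splice junctions.
#
# Shared alignment configuration (recorded in CLI output headers): protein
# local alignments use Smith-Waterman with BLOSUM62, gap open 11 / extend 1;
# nucleotide alignments use match +2 / mismatch -3, gap open 5 / extend 2.
# Identity everywhere is matches / aligned columns with terminal gaps
# excluded.

#' Default alignment configuration
#' @return named list of scoring parameters used by all detectors.
#' @export
alignment_config <- function() {
  list(protein_matrix = "BLOSUM62", protein_gap_open = 11, protein_gap_ext = 1,
       nt_match = 2, nt_mismatch = -3, nt_gap_open = 5, nt_gap_ext = 2)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

nt_submat <- function() {
  cfg <- alignment_config()
  Biostrings::nucleotideSubstitutionMatrix(match = cfg$nt_match,
                                           mismatch = cfg$nt_mismatch,
                                           baseOnly = FALSE)
}

# local protein alignment; returns NULL below min score
aa_local <- function(query, target, min_score = 0) {
  cfg <- alignment_config()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    substitutionMatrix = blosum62(), type = "local",
    gapOpening = cfg$protein_gap_open, gapExtension = cfg$protein_gap_ext)
  if (Biostrings::score(pa) < min_score) return(NULL)
  list(score = Biostrings::score(pa),
       query_range = c(Biostrings::start(Biostrings::pattern(pa)),
                       Biostrings::end(Biostrings::pattern(pa))),
       target_range = c(Biostrings::start(Biostrings::subject(pa)),
                        Biostrings::end(Biostrings::subject(pa))),
       pid = Biostrings::pid(pa, type = "PID1"))
}

# does x look like DNA rather than protein
is_dna <- function(x) grepl("^[ACGTRYSWKMBDHVN]+$", toupper(x))

#' Detect gene fission against a parent protein
#'
#' Reports a fission when exactly two candidate proteins align (locally) to
#' essentially disjoint spans of the parent, each covering at least
#' `min_part_cov` of it and jointly at least `min_joint_cov`.  The archetype
#' is nad11 of diatom-type mitochondria, split between its FeS-binding and
#' molybdopterin-binding domains into independently expressed nad11a/nad11b.
#'
#' @param parent_protein parent amino-acid sequence.
#' @param candidate_proteins named character vector of candidate part
#'   proteins.
#' @param min_part_cov minimum fraction of the parent covered by each part.
#' @param min_joint_cov minimum joint coverage.
#' @param max_overlap_aa maximum allowed overlap of the two part spans.
#' @return a `fission_event` list (part ids, parent spans, breakpoint aa
#'   interval) or `NULL` when no compatible pair exists.
#' @export
detect_fission <- function(parent_protein, candidate_proteins,
                           min_part_cov = 0.25, min_joint_cov = 0.80,
                           max_overlap_aa = 10L) {
  np <- nchar(parent_protein)
  if (np == 0 || !length(candidate_proteins)) return(NULL)
  if (is.null(names(candidate_proteins)))
    names(candidate_proteins) <- paste0("part", seq_along(candidate_proteins))
  hits <- lapply(candidate_proteins, function(p) {
    h <- aa_local(p, parent_protein, min_score = 30)
    if (is.null(h)) return(NULL)
    h$cov <- (h$target_range[2] - h$target_range[1] + 1) / np
    h
  })
  ok <- !vapply(hits, is.null, logical(1))
  hits <- hits[ok]
  hits <- hits[vapply(hits, function(h) h$cov >= min_part_cov, logical(1))]
  if (length(hits) < 2) return(NULL)
  best <- NULL
  nm <- names(hits)
  for (a in seq_along(hits)) for (b in seq_along(hits)) {
    if (a == b) next
    ha <- hits[[a]]; hb <- hits[[b]]
    if (ha$target_range[1] > hb$target_range[1]) next
    overlap <- ha$target_range[2] - hb$target_range[1] + 1
    joint <- ha$cov + hb$cov - max(0, overlap) / np
    if (overlap > max_overlap_aa || joint < min_joint_cov) next
    if (is.null(best) || joint > best$joint)
      best <- list(a = a, b = b, joint = joint)
  }
  if (is.null(best)) return(NULL)
  ha <- hits[[best$a]]; hb <- hits[[best$b]]
  structure(list(
    part_ids = c(nm[best$a], nm[best$b]),
    parent_spans = rbind(ha$target_range, hb$target_range),
    breakpoint_aa = c(ha$target_range[2], hb$target_range[1]),
    joint_coverage = best$joint,
    identities = c(ha$pid, hb$pid)),
    class = "fission_event")
}

#' Detect gene fusions between two annotated genomes
#'
#' Scans gene pairs adjacent in genome B (separate genes, same strand,
#' consecutive along the genome) and reports those that correspond to one
#' continuous reading frame in genome A: a single protein feature of A whose
#' translation carries both parts in order, with no stop codon between the
#' gene-derived regions, and with the downstream part's initiator-position
#' methionine retained.
#'
#' @param genomeA genome carrying the candidate fused genes.
#' @param genomeB genome carrying the separate genes.
#' @param min_part_cov minimum fraction of each separate protein covered in
#'   the fused frame.
#' @param max_overlap_aa maximum overlap of the two spans in the fused frame.
#' @return list of `fusion_event`s (possibly empty).
#' @export
detect_fusions <- function(genomeA, genomeB, min_part_cov = 0.5,
                           max_overlap_aa = 10L) {
  protB <- which(genomeB$features$cls == "protein")
  extB <- feature_extents(genomeB)
  extB <- extB[extB$idx %in% protB, ]
  extB <- extB[order(extB$start), ]
  protA <- which(genomeA$features$cls == "protein")
  events <- list()
  if (nrow(extB) < 2 || !length(protA)) return(events)
  transA <- lapply(protA, function(i)
    sub("\\*$", "", translate_cds(spliced_sequence(genomeA, genomeA$features[i, ]),
                                  table = genomeA$translation_table,
                                  mode = "open_frame")))
  names(transA) <- genomeA$features$name[protA]
  pairs <- cbind(seq_len(nrow(extB) - 1), seq_len(nrow(extB) - 1) + 1)
  if (genomeB$topology == "circular")
    pairs <- rbind(pairs, c(nrow(extB), 1))
  for (r in seq_len(nrow(pairs))) {
    i1 <- extB$idx[pairs[r, 1]]; i2 <- extB$idx[pairs[r, 2]]
    f1 <- genomeB$features[i1, ]; f2 <- genomeB$features[i2, ]
    if (f1$strand != f2$strand) next
    # reading order along the strand: on '-', the downstream gene of the
    # transcriptional unit is the genomically-earlier one
    if (f1$strand == "-") { tmp <- f1; f1 <- f2; f2 <- tmp }
    p1 <- sub("\\*$", "", translate_cds(spliced_sequence(genomeB, f1),
                                        table = genomeB$translation_table,
                                        mode = "open_frame"))
    p2 <- sub("\\*$", "", translate_cds(spliced_sequence(genomeB, f2),
                                        table = genomeB$translation_table,
                                        mode = "open_frame"))
    if (grepl("\\*", p1) || grepl("\\*", p2)) next
    for (k in seq_along(transA)) {
      pf <- transA[[k]]
      if (grepl("\\*", pf)) next                 # internal stop: not one frame
      if (names(transA)[k] %in% c(f1$name, f2$name) &&
          nchar(pf) <= max(nchar(p1), nchar(p2)) + 10) next  # same lone gene
      h1 <- aa_local(p1, pf, min_score = 30)
      h2 <- aa_local(p2, pf, min_score = 30)
      if (is.null(h1) || is.null(h2)) next
      cov1 <- (h1$query_range[2] - h1$query_range[1] + 1) / nchar(p1)
      cov2 <- (h2$query_range[2] - h2$query_range[1] + 1) / nchar(p2)
      if (cov1 < min_part_cov || cov2 < min_part_cov) next
      if (h1$target_range[1] >= h2$target_range[1]) next
      if (h1$target_range[2] - h2$target_range[1] + 1 > max_overlap_aa) next
      init_pos <- h2$target_range[1] - (h2$query_range[1] - 1)
      init_met <- init_pos >= 1 && substr(pf, init_pos, init_pos) == "M" &&
        substr(p2, 1, 1) == "M"
      events[[length(events) + 1]] <- structure(list(
        upstream = f1$name, downstream = f2$name,
        fused_gene = names(transA)[k],
        genomeA = genomeA$id, genomeB = genomeB$id,
        spans_in_fused = rbind(h1$target_range, h2$target_range),
        evidence = c(no_internal_stop = TRUE, downstream_initiator_met = init_met)),
        class = "fusion_event")
      break
    }
  }
  events
}

#' Detect an in-frame insertion shared by in-group homologs
#'
#' Looks for a contiguous region present in every in-group sequence but
#' absent (gapped) in all outgroup homologs, with nucleotide length divisible
#' by 3.  Sequences may be proteins or CDS DNA (DNA is translated in open
#' frame).  The archetype is the ~500 bp in-frame, unspliced insertion in the
#' dinotom nad2 relative to free-living diatoms.
#'
#' @param ingroup named character vector (>= 2) of homologs carrying the
#'   insert.
#' @param outgroups named character vector (>= 1) of homologs lacking it.
#' @param min_insert_aa minimum insert length (aa) to report.
#' @return an `insertion_event` or `NULL`; errors without an outgroup
#'   (insert polarity is undecidable).
#' @export
detect_inframe_insert <- function(ingroup, outgroups, min_insert_aa = 20L) {
  if (length(outgroups) < 1)
    stop_dinomito("no outgroup homolog: insert polarity undecidable",
                  class = "no_outgroup")
  if (length(ingroup) < 2)
    stop_dinomito("need >= 2 in-group homologs", class = "bad_input")
  to_aa <- function(x) if (is_dna(x)) sub("\\*$", "",
                                          translate_cds(x, mode = "open_frame")) else x
  ing <- vapply(ingroup, to_aa, character(1))
  out <- vapply(outgroups, to_aa, character(1))
  cfg <- alignment_config()
  runs_per <- lapply(ing, function(p) {
    per_out <- lapply(out, function(o) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(p), Biostrings::AAString(o),
        substitutionMatrix = blosum62(), type = "global",
        gapOpening = cfg$protein_gap_open, gapExtension = cfg$protein_gap_ext)
      ins <- Biostrings::insertion(pa)[[1]]   # gaps in the outgroup subject
      keep <- IRanges::width(ins) >= min_insert_aa
      cbind(start = IRanges::start(ins)[keep] -
              (Biostrings::start(Biostrings::pattern(pa)) - 1),
            width = IRanges::width(ins)[keep])
    })
    per_out
  })
  # an insert must appear against every outgroup, at overlapping in-group
  # coordinates; take the consensus bounds per in-group sequence
  bounds <- matrix(NA_integer_, nrow = length(ing), ncol = 2,
                   dimnames = list(names(ing), c("aa_start", "aa_end")))
  for (i in seq_along(ing)) {
    cand <- runs_per[[i]][[1]]
    if (!nrow(cand)) return(NULL)
    found <- FALSE
    for (r in seq_len(nrow(cand))) {
      s <- cand[r, "start"]; e <- s + cand[r, "width"] - 1
      ok <- all(vapply(runs_per[[i]], function(m) {
        if (!nrow(m)) return(FALSE)
        any(pmax(m[, "start"], s) <= pmin(m[, "start"] + m[, "width"] - 1, e))
      }, logical(1)))
      if (ok) {
        ss <- ee <- numeric(0)
        for (m in runs_per[[i]]) {
          j <- which(pmax(m[, "start"], s) <= pmin(m[, "start"] + m[, "width"] - 1, e))[1]
          ss <- c(ss, m[j, "start"]); ee <- c(ee, m[j, "start"] + m[j, "width"] - 1)
        }
        bounds[i, ] <- c(round(median(ss)), round(median(ee)))
        found <- TRUE
        break
      }
    }
    if (!found) return(NULL)
  }
  # identities between the first two in-group members, inside vs outside
  pa12 <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ing[[1]]), Biostrings::AAString(ing[[2]]),
    substitutionMatrix = blosum62(), type = "global",
    gapOpening = cfg$protein_gap_open, gapExtension = cfg$protein_gap_ext)
  al1 <- strsplit(as.character(Biostrings::alignedPattern(pa12)), "")[[1]]
  al2 <- strsplit(as.character(Biostrings::alignedSubject(pa12)), "")[[1]]
  pos1 <- cumsum(al1 != "-")
  region <- pos1 >= bounds[1, 1] & pos1 <= bounds[1, 2] & al1 != "-"
  idy <- function(sel) {
    cols <- sel & !(al1 == "-" & al2 == "-")
    if (!sum(cols)) return(NA_real_)
    100 * sum(al1[cols] == al2[cols] & al1[cols] != "-") / sum(cols)
  }
  structure(list(
    bounds_aa = bounds,
    insert_len_nt = 3L * (bounds[, 2] - bounds[, 1] + 1L),
    insert_identity_pct = idy(region),
    flank_identity_pct = c(before = idy(pos1 < bounds[1, 1]),
                           after = idy(pos1 > bounds[1, 2])),
    outgroups = names(out)),
    class = "insertion_event")
}

#' Detect intron interruptions from a gene locus and its spliced cDNA
#'
#' Aligns the spliced cDNA to the genomic locus (the cDNA must be fully
#' decomposable into ordered locus substrings); gaps in the cDNA of at least
#' `min_intron` nt are reported as introns in locus coordinates.
#'
#' @param gene_locus_dna genomic sequence of the locus.
#' @param spliced_cdna spliced transcript sequence.
#' @param min_intron minimum reported intron length (nt).
#' @param min_exon_identity minimum percent identity of the exonic alignment;
#'   below it the decomposition is rejected with an error.
#' @return data.frame with columns intron_start, intron_end (locus
#'   coordinates, 1-based); zero rows for an intronless locus.
#' @export
detect_intron_interruption <- function(gene_locus_dna, spliced_cdna,
                                       min_intron = 20L,
                                       min_exon_identity = 80) {
  if (nchar(spliced_cdna) > nchar(gene_locus_dna))
    stop_dinomito("cDNA longer than locus", class = "bad_input")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(spliced_cdna), Biostrings::DNAString(gene_locus_dna),
    substitutionMatrix = nt_submat(), type = "global-local",
    gapOpening = 8, gapExtension = 0.1)
  al_p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  exonic <- al_p != "-" & al_s != "-"
  exon_idy <- 100 * sum(al_p[exonic] == al_s[exonic]) / max(1, sum(exonic))
  # nearly all cDNA residues must take part in the exon chain: unaligned
  # cDNA (gaps opened in the locus) means the decomposition failed
  exon_cov <- 100 * sum(exonic) / nchar(spliced_cdna)
  if (exon_idy < min_exon_identity || exon_cov < 90)
    stop_dinomito("cDNA does not decompose into ordered locus substrings (exon identity %.1f%%, exon coverage %.1f%%)",
                  exon_idy, exon_cov, class = "decomposition_error")
  if (!any(al_p == "-"))
    return(data.frame(intron_start = integer(), intron_end = integer()))
  sub_start <- Biostrings::start(Biostrings::subject(pa))
  sub_pos <- sub_start - 1 + cumsum(al_s != "-")
  runs <- rle(al_p == "-")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_intron
  data.frame(intron_start = sub_pos[starts[keep]],
             intron_end = sub_pos[ends[keep]])
}

#' Locate a trans-splice junction in a transcript spanning two gene pieces
#'
#' Finds the maximal transcript prefix matching the 5' gene piece and the
#' maximal suffix matching the 3' piece, allowing substitutions (the host
#' transcripts are heavily edited, especially upstream of the junction) but
#' no indels; the residues left between them are the junction insert (e.g.
#' the penta-A carried over from the polyadenylated 5' piece).
#'
#' @param part1_dna coding sequence of the 5' gene piece, in frame from
#'   codon 1 of the full protein.
#' @param part2_dna coding sequence of the 3' piece.
#' @param transcript transcript sequence spanning the junction.
#' @param max_mismatch_rate maximum substitution rate tolerated when
#'   anchoring each side.
#' @param max_insert maximum junction-insert length searched.
#' @return a `splice_junction` list: `junction_aa` (last aa encoded by part 1,
#'   first encoded by part 2), `insert` (possibly empty string),
#'   `transcript_cut` (last transcript position matched to part 1), and
#'   `ambiguous` (TRUE when the insert boundary is an interval, reported via
#'   `cut_interval`).
#' @export
locate_trans_splice_junction <- function(part1_dna, part2_dna, transcript,
                                         max_mismatch_rate = 0.25,
                                         max_insert = 50L) {
  t_chars <- strsplit(toupper(transcript), "")[[1]]
  p1 <- strsplit(toupper(part1_dna), "")[[1]]
  p2 <- strsplit(toupper(part2_dna), "")[[1]]
  L1 <- length(p1); Lt <- length(t_chars)
  # anchor the transcript start inside part 1 (ungapped)
  best <- NULL
  for (o in seq_len(L1)) {
    span <- min(L1 - o + 1, Lt)
    if (span < 15) break
    mm <- sum(t_chars[seq_len(span)] != p1[o:(o + span - 1)]) / span
    if (is.null(best) || mm < best$mm) best <- list(o = o, mm = mm, span = span)
  }
  if (is.null(best) || best$mm > max_mismatch_rate)
    stop_dinomito("transcript does not anchor in part 1 (best mismatch rate %.2f)",
                  best$mm %||% 1, class = "anchor_error")
  prefix_len <- L1 - best$o + 1              # transcript covers part 1 through its end
  if (prefix_len >= Lt)
    stop_dinomito("transcript does not extend past part 1", class = "bad_input")
  # anchor part 2's start in the transcript tail (ungapped)
  cand <- (prefix_len - 5):(prefix_len + max_insert)
  cand <- cand[cand >= 1 & cand + 14 <= Lt]
  mm2 <- vapply(cand, function(s) {
    span <- min(Lt - s, length(p2))
    sum(t_chars[(s + 1):(s + span)] != p2[seq_len(span)]) / span
  }, numeric(1))
  if (!length(cand) || min(mm2) > max_mismatch_rate)
    stop_dinomito("part 2 does not anchor in the transcript tail",
                  class = "anchor_error")
  cut2 <- cand[which.min(mm2)]               # last transcript pos before part2
  ambiguous <- cut2 < prefix_len
  insert <- if (cut2 > prefix_len)
    paste(t_chars[(prefix_len + 1):cut2], collapse = "") else ""
  n1 <- L1
  junction_aa <- c(floor(n1 / 3), floor(n1 / 3) + 1L)
  structure(list(junction_aa = junction_aa, insert = insert,
                 transcript_cut = prefix_len,
                 ambiguous = ambiguous,
                 cut_interval = if (ambiguous) c(cut2, prefix_len)
                 else c(prefix_len, prefix_len)),
            class = "splice_junction")
}
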