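# Substitutional RNA-editing calling from paired genomic/cDNA sequences.
#
# Dinoflagellate mitochondrial mRNAs differ from their encoding DNA by
# single-base substitutions (mostly A->G, at codon positions 1-2, almost
# always non-synonymous).  Editing here is substitutional only: the caller
# anchors the transcript on the gene without internal indels and reports
# every mismatch.  RNA bases are mapped to the DNA alphabet (U -> T) so edit
# types are uniformly reported genomic-base -> transcript-base in DNA letters
# ("substitute a G for an A" = A in DNA, G in mRNA).

EDIT_TYPES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Call substitutional editing sites from a gene/transcript pair
#'
#' The (possibly partial) transcript is anchored on the gene CDS by a best
#' ungapped placement; every mismatch over the compared span becomes a site
#' with its codon index, codon position and amino-acid consequence under
#' open-frame translation.  An indel within the compared span is an error --
#' substitutional editing cannot shift frame.
#'
#' @param gene_cds genomic coding sequence (DNA).
#' @param transcript_cds transcript sequence (RNA or DNA alphabet; may be a
#'   partial RT-PCR fragment).
#' @param frame_offset number of coding nucleotides upstream of
#'   `gene_cds[1]` in the full CDS (0 when the gene starts at codon 1).
#' @param table genetic code used for the amino-acid consequence.
#' @param min_anchor_identity minimum percent identity of the anchored span.
#' @return data.frame of class `editing_sites`: cds_position (1-based, in the
#'   full-CDS frame), codon_index, codon_position, genomic_base,
#'   transcript_base, aa_before, aa_after, synonymous.
#' @export
call_editing_sites <- function(gene_cds, transcript_cds, frame_offset = 0L,
                               table = 1L, min_anchor_identity = 70) {
  gene <- toupper(gene_cds)
  tx <- chartr("Uu", "Tt", toupper(transcript_cds))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(tx), Biostrings::DNAString(gene),
    substitutionMatrix = nt_submat(), type = "global-local",
    gapOpening = alignment_config()$nt_gap_open,
    gapExtension = alignment_config()$nt_gap_ext)
  if (Biostrings::nindel(pa)@insertion[1, "Length"] > 0 ||
      Biostrings::nindel(pa)@deletion[1, "Length"] > 0) {
    al_s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    al_p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    first <- which(al_s == "-" | al_p == "-")[1]
    gpos <- Biostrings::start(Biostrings::subject(pa)) - 1 +
      sum(al_s[seq_len(first)] != "-")
    stop_dinomito("indel at gene position %d: editing is substitutional only",
                  gpos, class = "alignment_error")
  }
  if (Biostrings::pid(pa, type = "PID1") < min_anchor_identity)
    stop_dinomito("transcript does not anchor on gene (identity %.1f%%)",
                  Biostrings::pid(pa, type = "PID1"), class = "anchor_error")
  al_p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  offset <- Biostrings::start(Biostrings::subject(pa)) - 1
  mm <- which(al_p != al_s)
  sites <- lapply(mm, function(col) {
    local_pos <- offset + col
    eff <- local_pos + frame_offset          # position in the full-CDS frame
    codon_index <- (eff - 1) %/% 3 + 1
    codon_pos <- (eff - 1) %% 3 + 1
    cstart <- local_pos - codon_pos + 1
    codon_before <- if (cstart >= 1 && cstart + 2 <= nchar(gene))
      substr(gene, cstart, cstart + 2) else NA_character_
    aa_b <- aa_a <- NA_character_
    if (!is.na(codon_before) && grepl("^[ACGT]{3}$", codon_before)) {
      codon_after <- codon_before
      substr(codon_after, codon_pos, codon_pos) <- al_p[col]
      aa_b <- translate_cds(codon_before, table = table, mode = "open_frame")
      aa_a <- translate_cds(codon_after, table = table, mode = "open_frame")
    }
    data.frame(cds_position = eff, codon_index = codon_index,
               codon_position = codon_pos,
               genomic_base = al_s[col], transcript_base = al_p[col],
               aa_before = aa_b, aa_after = aa_a,
               synonymous = !is.na(aa_b) && !is.na(aa_a) && aa_b == aa_a,
               stringsAsFactors = FALSE)
  })
  out <- if (length(sites)) do.call(rbind, sites) else
    data.frame(cds_position = integer(), codon_index = integer(),
               codon_position = integer(), genomic_base = character(),
               transcript_base = character(), aa_before = character(),
               aa_after = character(), synonymous = logical(),
               stringsAsFactors = FALSE)
  class(out) <- c("editing_sites", class(out))
  attr(out, "compared_span") <- c(offset + 1, offset + length(al_p))
  out
}

#' Editing spectrum: substitution types by codon position
#'
#' Full 12 x 3 contingency of substitution type (genomic -> transcript base)
#' by codon position; totals are conserved.
#'
#' @param sites an `editing_sites` data.frame.
#' @return integer matrix, rows the 12 substitution types, columns codon
#'   positions 1-3.
#' @export
edit_spectrum <- function(sites) {
  type <- factor(if (nrow(sites)) paste0(sites$genomic_base, ">",
                                         sites$transcript_base)
                 else character(), levels = EDIT_TYPES)
  pos <- factor(sites$codon_position, levels = 1:3)
  as.matrix(table(type, pos))
}

#' Build a codon-level homolog map between two CDS
#'
#' Global nucleotide alignment projected to per-position correspondence;
#' the map feeds [conserved_editing_sites()].
#'
#' @param cdsA,cdsB homologous coding sequences.
#' @return data.frame with columns posA, posB (NA where one sequence gaps).
#' @export
build_homolog_map <- function(cdsA, cdsB) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(cdsA)), Biostrings::DNAString(toupper(cdsB)),
    substitutionMatrix = nt_submat(), type = "global",
    gapOpening = alignment_config()$nt_gap_open,
    gapExtension = alignment_config()$nt_gap_ext)
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  data.frame(posA = ifelse(a == "-", NA_integer_, cumsum(a != "-")),
             posB = ifelse(b == "-", NA_integer_, cumsum(b != "-")))
}

#' Match editing sites conserved between two homologous genes
#'
#' Sites are matched when the homolog map sends them to the same aligned
#' position and they carry the same substitution type.  Sites outside the
#' map are excluded with a warning.  The matching is symmetric.
#'
#' @param sitesA,sitesB `editing_sites` for the two genes.
#' @param homolog_map output of [build_homolog_map()] for (geneA, geneB).
#' @return data.frame with columns posA, posB, type.
#' @export
conserved_editing_sites <- function(sitesA, sitesB, homolog_map) {
  mapAB <- setNames(homolog_map$posB, homolog_map$posA)
  inmap <- sitesA$cds_position %in% homolog_map$posA
  if (any(!inmap))
    warning(sprintf("%d site(s) of A outside the homolog map; excluded",
                    sum(!inmap)))
  a <- sitesA[inmap, , drop = FALSE]
  empty <- data.frame(posA = integer(), posB = integer(), type = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(sitesB)) return(empty)
  keyB <- paste(sitesB$cds_position, sitesB$genomic_base, sitesB$transcript_base)
  posB <- mapAB[as.character(a$cds_position)]
  keyA <- paste(posB, a$genomic_base, a$transcript_base)
  hit <- which(keyA %in% keyB & !is.na(posB))
  if (!length(hit)) return(empty)
  data.frame(posA = a$cds_position[hit], posB = unname(posB[hit]),
             type = paste0(a$genomic_base[hit], ">", a$transcript_base[hit]),
             stringsAsFactors = FALSE)
}
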