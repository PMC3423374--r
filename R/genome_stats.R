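# Feature statistics for compact organellar genomes: GC content by feature
# class, coding fraction, intergenic spacers and overlaps, codon surveys,
# gene length summaries.
#
# All denominators refer to the sequenced region only.  For genomes deposited
# with one unclosed gap (topology "linear_gapped") the sequence slot holds
# the sequenced coding-plus-intergenic region, and statistics are computed
# over it without wrapping across the gap.

gene_like <- function(cls) cls %in% c("protein", "rRNA", "tRNA", "orf")

# position set covered by >= 1 gene-like feature; intronic nucleotides count
# as part of the gene locus (segment gaps are filled)
coverage_positions <- function(genome, include = gene_like) {
  keep <- which(include(genome$features$cls))
  if (!length(keep)) return(integer())
  sort(unique(unlist(lapply(keep, function(i)
    feature_positions(genome, genome$features[i, ], spliced = FALSE)))))
}

#' GC content of a genome region selection
#'
#' Percent G+C among unambiguous bases (A/C/G/T) in the selected positions;
#' ambiguity codes are excluded from both numerator and denominator, and
#' positions covered by several copies are counted once.
#'
#' @param genome an [annotated_genome()].
#' @param selector `"total"`, `"intergenic"`, or a feature class
#'   (`"protein"`, `"rRNA"`, `"tRNA"`, `"orf"`, `"intron"`).
#' @return percent in `[0, 100]`.
#' @export
gc_content <- function(genome, selector = "total") {
  chars <- strsplit(genome$sequence, "")[[1]]
  pos <- if (identical(selector, "total")) {
    seq_along(chars)
  } else if (identical(selector, "intergenic")) {
    setdiff(seq_along(chars), coverage_positions(genome))
  } else if (selector %in% GENE_CLASSES) {
    keep <- which(genome$features$cls == selector)
    sort(unique(unlist(lapply(keep, function(i)
      feature_positions(genome, genome$features[i, ], spliced = TRUE)))))
  } else stop_dinomito("unknown selector '%s'", selector, class = "bad_selector")
  sel <- chars[pos]
  denom <- sum(sel %in% c("A", "C", "G", "T"))
  if (denom == 0)
    stop_dinomito("selector '%s': empty selection, GC undefined", selector,
                  class = "empty_selection")
  100 * sum(sel %in% c("G", "C")) / denom
}

#' Fraction of the sequenced region covered by genes
#'
#' Coverage is a position-set union over protein, rRNA, tRNA and annotated
#' ORF loci (introns counted as part of their gene locus), so overlapping
#' genes are counted once.
#'
#' @param genome an [annotated_genome()].
#' @return percent.
#' @export
coding_fraction <- function(genome) {
  if (!nrow(genome$features))
    stop_dinomito("genome has no features", class = "empty_selection")
  100 * length(coverage_positions(genome)) / nchar(genome$sequence)
}

# gene extent along the genome for adjacency analysis: (start, end) possibly
# wrapping; multi-segment features use first segment start / last segment end
feature_extents <- function(genome) {
  keep <- which(gene_like(genome$features$cls))
  ext <- t(vapply(keep, function(i) {
    segs <- genome$features$segments[[i]]
    c(segs[1, 1], segs[nrow(segs), 2])
  }, integer(2)))
  data.frame(idx = keep, name = genome$features$name[keep],
             start = ext[, 1], end = ext[, 2], stringsAsFactors = FALSE)
}

#' Intergenic spacers and gene overlaps
#'
#' Walks consecutive gene loci along the genome (cyclically for circular
#' genomes; open across the gap for linear/linear_gapped ones) with a running
#' furthest-end sweep.  Non-negative gaps are spacers; a gene starting before
#' the previous furthest end yields an overlap pair, reported separately and
#' excluded from the spacer mean.  By construction
#' `union coverage + sum(spacers) = sequenced length` when loci have no
#' internal unannotated gaps.
#'
#' @param genome an [annotated_genome()] with >= 2 gene features.
#' @return list with `spacers` (integer vector), `mean` (mean spacer bp),
#'   `overlaps` (data.frame of adjacent overlapping gene-name pairs).
#' @export
intergenic_spacers <- function(genome) {
  ext <- feature_extents(genome)
  if (nrow(ext) < 2)
    stop_dinomito("need >= 2 gene features", class = "empty_selection")
  L <- nchar(genome$sequence)
  circ <- genome$topology == "circular"
  # unwrap: a wrapping extent (start > end) extends past L
  ext$uend <- ifelse(ext$end >= ext$start, ext$end, ext$end + L)
  ext <- ext[order(ext$start, -ext$uend), ]
  spacers <- integer()
  overlaps <- list()
  cur_end <- ext$uend[1]
  cur_name <- ext$name[1]
  for (i in seq_len(nrow(ext))[-1]) {
    gap <- ext$start[i] - cur_end - 1
    if (gap >= 0) spacers <- c(spacers, gap)
    else overlaps[[length(overlaps) + 1]] <- c(cur_name, ext$name[i])
    if (ext$uend[i] > cur_end) { cur_end <- ext$uend[i]; cur_name <- ext$name[i] }
  }
  if (circ) {
    gap <- ext$start[1] + L - cur_end - 1
    if (gap >= 0) spacers <- c(spacers, gap)
    else overlaps[[length(overlaps) + 1]] <- c(cur_name, ext$name[1])
  }
  ov <- if (length(overlaps))
    as.data.frame(do.call(rbind, overlaps), stringsAsFactors = FALSE)
  else data.frame(V1 = character(), V2 = character())
  names(ov) <- c("gene1", "gene2")
  spacers <- as.integer(spacers)
  list(spacers = spacers,
       mean = if (length(spacers)) mean(spacers) else NA_real_,
       overlaps = ov)
}

#' Codon usage, third-position composition and start/stop survey
#'
#' Computed over all complete protein-coding CDS (class `protein`; fused
#' genes are single features and therefore counted once).  The third-position
#' A+T statistic is `(#A + #T at codon position 3) / #codons`, taken over
#' sense codons (the terminal stop is excluded).  Genes whose spliced length
#' is not a multiple of 3 are excluded with a per-gene warning.
#'
#' @param genome an [annotated_genome()].
#' @param alt_start_codons codons other than ATG flagged as alternative
#'   starts.
#' @return list: `codon_counts` (named 64-vector), `third_position_AT_pct`,
#'   `start_codons`, `stop_codons` (gene-named vectors), `alt_start_genes`.
#' @export
codon_stats <- function(genome,
                        alt_start_codons = c("ATA", "ATT", "GTG", "TTG")) {
  idx <- which(genome$features$cls == "protein" & genome$features$complete)
  if (!length(idx))
    stop_dinomito("no complete protein-coding features", class = "empty_selection")
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste,
                      collapse = "")
  counts <- setNames(integer(64), sort(all_codons))
  starts <- stops <- character()
  third <- character()
  for (i in idx) {
    cds <- spliced_sequence(genome, genome$features[i, ])
    if (nchar(cds) %% 3 != 0) {
      warning(sprintf("gene '%s': CDS length %d not divisible by 3; excluded",
                      genome$features$name[i], nchar(cds)))
      next
    }
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    starts[genome$features$name[i]] <- cods[1]
    stops[genome$features$name[i]] <- cods[length(cods)]
    sense <- cods[-length(cods)]
    ok <- grepl("^[ACGT]{3}$", sense)
    tb <- table(sense[ok])
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    third <- c(third, substr(sense[ok], 3, 3))
  }
  list(codon_counts = counts,
       third_position_AT_pct = 100 * mean(third %in% c("A", "T")),
       start_codons = starts,
       stop_codons = stops,
       alt_start_genes = names(starts)[starts %in% alt_start_codons])
}

#' Mean gene lengths
#'
#' Arithmetic means over spliced gene lengths (introns excluded): separately
#' for protein-coding genes and for all gene-like features (protein, rRNA,
#' tRNA, ORF).
#'
#' @param genome an [annotated_genome()].
#' @return list `mean_protein_gene_bp`, `mean_all_gene_bp`.
#' @export
gene_length_summary <- function(genome) {
  tab <- feature_table(genome)
  list(mean_protein_gene_bp = mean(tab$length[tab$cls == "protein"]),
       mean_all_gene_bp = mean(tab$length[gene_like(tab$cls)]))
}

#' Full genome statistics summary
#'
#' Assembles the standard comparative table for a compact organellar genome:
#' size, GC content (total, per feature class, intergenic), gene counts by
#' class, coding fraction, spacer lengths and overlaps, mean gene lengths,
#' third-position A+T and start/stop codon survey.
#'
#' @param genome an [annotated_genome()].
#' @return object of class `genome_statistics` (a named list).
#' @export
genome_statistics <- function(genome) {
  cls <- genome$features$cls
  gc_cls <- function(sel) tryCatch(gc_content(genome, sel), error = function(e) NA_real_)
  sp <- intergenic_spacers(genome)
  cs <- tryCatch(codon_stats(genome), error = function(e) NULL)
  gl <- gene_length_summary(genome)
  out <- list(
    genome_id = genome$id,
    topology = genome$topology,
    total_bp = nchar(genome$sequence),
    coding_intergenic_bp = nchar(genome$sequence),
    gc_total_pct = gc_content(genome, "total"),
    gc_by_class = c(rRNA = gc_cls("rRNA"), tRNA = gc_cls("tRNA"),
                    protein = gc_cls("protein"), intergenic = gc_cls("intergenic")),
    gene_counts = c(total = sum(gene_like(cls)),
                    protein = sum(cls == "protein"),
                    rRNA = sum(cls == "rRNA"),
                    tRNA = sum(cls == "tRNA"),
                    orf = sum(cls == "orf"),
                    intron = sum(cls == "intron")),
    coding_fraction_pct = coding_fraction(genome),
    intergenic_spacer_lengths = sp$spacers,
    mean_spacer_bp = sp$mean,
    overlap_pairs = sp$overlaps,
    mean_protein_gene_bp = gl$mean_protein_gene_bp,
    mean_all_gene_bp = gl$mean_all_gene_bp,
    third_position_AT_pct = if (is.null(cs)) NA_real_ else cs$third_position_AT_pct,
    start_codon_table = if (is.null(cs)) character() else cs$start_codons,
    stop_codon_table = if (is.null(cs)) character() else cs$stop_codons,
    alt_start_genes = if (is.null(cs)) character() else cs$alt_start_genes)
  class(out) <- "genome_statistics"
  out
}

#' @export
print.genome_statistics <- function(x, ...) {
  cat(sprintf("Genome statistics for '%s' (%s)\n", x$genome_id, x$topology))
  cat(sprintf("  sequenced length      %d bp\n", x$total_bp))
  cat(sprintf("  GC total              %.2f %%\n", x$gc_total_pct))
  cat(sprintf("  GC by class           rRNA %.2f  tRNA %.2f  protein %.2f  intergenic %.2f\n",
              x$gc_by_class["rRNA"], x$gc_by_class["tRNA"],
              x$gc_by_class["protein"], x$gc_by_class["intergenic"]))
  cat(sprintf("  genes                 %d (protein %d, rRNA %d, tRNA %d, orf %d)\n",
              x$gene_counts["total"], x$gene_counts["protein"],
              x$gene_counts["rRNA"], x$gene_counts["tRNA"], x$gene_counts["orf"]))
  cat(sprintf("  coding fraction       %.2f %%\n", x$coding_fraction_pct))
  cat(sprintf("  mean spacer           %.1f bp (n=%d; %d overlap pairs)\n",
              x$mean_spacer_bp, length(x$intergenic_spacer_lengths),
              nrow(x$overlap_pairs)))
  cat(sprintf("  mean gene length      %.0f bp protein (%.0f all genes)\n",
              x$mean_protein_gene_bp, x$mean_all_gene_bp))
  cat(sprintf("  3rd-position A+T      %.1f %%\n", x$third_position_AT_pct))
  if (length(x$alt_start_genes))
    cat("  alternative starts    ", paste(x$alt_start_genes, collapse = ", "), "\n")
  invisible(x)
}

#' One-row-per-statistic data.frame rendering of genome statistics
#' @param x a `genome_statistics` object.
#' @param ... unused.
#' @return data.frame with columns statistic, value.
#' @export
as.data.frame.genome_statistics <- function(x, ...) {
  num <- function(v) sprintf("%.4g", v)
  data.frame(
    statistic = c("genome_id", "topology", "coding_intergenic_bp",
                  "gc_total_pct", "gc_rRNA_pct", "gc_tRNA_pct",
                  "gc_protein_pct", "gc_intergenic_pct",
                  "genes_total", "genes_protein", "genes_rRNA", "genes_tRNA",
                  "genes_orf", "introns", "coding_fraction_pct",
                  "mean_spacer_bp", "overlap_pairs",
                  "mean_protein_gene_bp", "mean_all_gene_bp",
                  "third_position_AT_pct", "alt_start_genes"),
    value = c(x$genome_id, x$topology, x$coding_intergenic_bp,
              num(x$gc_total_pct), num(x$gc_by_class["rRNA"]),
              num(x$gc_by_class["tRNA"]), num(x$gc_by_class["protein"]),
              num(x$gc_by_class["intergenic"]),
              x$gene_counts["total"], x$gene_counts["protein"],
              x$gene_counts["rRNA"], x$gene_counts["tRNA"],
              x$gene_counts["orf"], x$gene_counts["intron"],
              num(x$coding_fraction_pct), num(x$mean_spacer_bp),
              paste(sprintf("%s-%s", x$overlap_pairs$gene1,
                            x$overlap_pairs$gene2), collapse = ";"),
              num(x$mean_protein_gene_bp), num(x$mean_all_gene_bp),
              num(x$third_position_AT_pct),
              paste(x$alt_start_genes, collapse = ";")),
    stringsAsFactors = FALSE)
}
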