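# Annotated-genome containers and GenBank/FASTA IO.
#
# Coordinates are 1-based inclusive throughout (GenBank convention).  A
# feature's segments are stored in reading order along the plus strand; a
# minus-strand feature is the reverse complement of the concatenated
# segments, which matches GenBank complement(join(...)) semantics.  On a
# circular genome a single segment may wrap the origin (start > end).

GENE_CLASSES <- c("protein", "rRNA", "tRNA", "orf", "intron", "pseudogene")

#' Construct an annotated genome
#'
#' @param id genome identifier.
#' @param sequence IUPAC DNA string (the sequenced portion only; for genomes
#'   with an unclosed gap use `topology = "linear_gapped"` and store just the
#'   sequenced region).
#' @param features data.frame of features, usually built by rbinding
#'   [gene_feature()] rows.
#' @param topology one of `"circular"`, `"linear"`, `"linear_gapped"`.
#' @param translation_table integer genetic code: 1 (universal) or 4
#'   (TGA decoded as tryptophan, as in some centric diatom mitochondria).
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence, features = empty_features(),
                             topology = c("circular", "linear", "linear_gapped"),
                             translation_table = 1L) {
  topology <- match.arg(topology)
  sequence <- toupper(gsub("[ \r\n0-9]", "", sequence))
  g <- structure(list(id = id, topology = topology, sequence = sequence,
                      features = features,
                      translation_table = as.integer(translation_table)),
                 class = "annotated_genome")
  validate_genome(g)
  g
}

#' Construct one gene feature (a one-row feature table)
#'
#' @param name normalized gene symbol (e.g. `cox1`, `nad11a`, `trnM`).
#' @param cls feature class: protein, rRNA, tRNA, orf, intron or pseudogene.
#' @param strand `"+"` or `"-"`.
#' @param segments integer matrix with columns start, end (1-based inclusive),
#'   one row per segment in reading order; or a length-2 vector for a single
#'   segment.
#' @param complete logical; FALSE for features truncated by a contig end.
#' @return one-row data.frame with a `segments` list column.
#' @export
gene_feature <- function(name, cls, strand, segments, complete = TRUE) {
  stopifnot(cls %in% GENE_CLASSES, strand %in% c("+", "-"))
  if (!is.matrix(segments))
    segments <- matrix(as.integer(segments), ncol = 2, byrow = TRUE)
  storage.mode(segments) <- "integer"
  dimnames(segments) <- list(NULL, c("start", "end"))
  data.frame(name = name, cls = cls, strand = strand,
             complete = complete, segments = I(list(segments)),
             stringsAsFactors = FALSE)
}

empty_features <- function() {
  data.frame(name = character(), cls = character(), strand = character(),
             complete = logical(), segments = I(list()),
             stringsAsFactors = FALSE)
}

validate_genome <- function(g) {
  if (!nzchar(g$sequence))
    stop_dinomito("genome '%s': empty sequence", g$id, class = "genome_invalid")
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", g$sequence)
  if (bad)
    stop_dinomito("genome '%s': unknown residue characters in sequence",
                  g$id, class = "genome_invalid")
  if (anyDuplicated(g$features$name))
    warning(sprintf("genome '%s': duplicated feature names: %s", g$id,
                    paste(unique(g$features$name[duplicated(g$features$name)]),
                          collapse = ", ")))
  L <- nchar(g$sequence)
  for (i in seq_len(nrow(g$features))) {
    seg <- g$features$segments[[i]]
    if (nrow(seg) == 0)
      stop_dinomito("feature '%s': no segments", g$features$name[i],
                    class = "genome_invalid")
    wraps <- seg[, 1] > seg[, 2]
    if (any(wraps) && g$topology != "circular")
      stop_dinomito("feature '%s': wrapping segment on non-circular genome",
                    g$features$name[i], class = "coordinate_error")
    if (any(seg < 1) || any(seg > L))
      stop_dinomito("feature '%s': segment outside sequence [1, %d]",
                    g$features$name[i], L, class = "coordinate_error")
  }
  invisible(g)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome '%s': %d bp, %s, code %d, %d features\n",
              x$id, nchar(x$sequence), x$topology, x$translation_table,
              nrow(x$features)))
  if (nrow(x$features))
    print(table(factor(x$features$cls, levels = GENE_CLASSES)))
  invisible(x)
}

# Genomic positions of one segment, honouring circular wrap.
segment_positions <- function(seg, glen, circular) {
  s <- seg[1]; e <- seg[2]
  if (s <= e) return(s:e)
  if (!circular)
    stop_dinomito("segment %d..%d wraps on a non-circular genome", s, e,
                  class = "coordinate_error")
  c(s:glen, 1:e)
}

# Positions of a feature: spliced (segments only) or locus (segments plus the
# gaps between consecutive segments, i.e. introns of a join feature).
feature_positions <- function(genome, feature_row, spliced = TRUE) {
  segs <- feature_row$segments[[1]]
  glen <- nchar(genome$sequence)
  circ <- genome$topology == "circular"
  pos <- unlist(lapply(seq_len(nrow(segs)), function(i)
    segment_positions(segs[i, ], glen, circ)))
  if (!spliced && nrow(segs) > 1) {
    for (i in seq_len(nrow(segs) - 1)) {
      from <- segs[i, 2]; to <- segs[i + 1, 1]
      gap <- if (from + 1 <= to - 1) (from + 1):(to - 1)
      else if (circ && to < from) segment_positions(c(from + 1, to - 1), glen, circ)
      else integer()
      pos <- c(pos, gap)
    }
  }
  unique(pos)
}

#' Extract the spliced sequence of a feature
#'
#' Segments are concatenated in reading order; a minus-strand feature returns
#' the reverse complement of the concatenation; segments wrapping the origin
#' of a circular genome are handled.
#'
#' @param genome an [annotated_genome()].
#' @param feature one row of `genome$features` (by index or name).
#' @return DNA character string.
#' @export
spliced_sequence <- function(genome, feature) {
  fr <- resolve_feature(genome, feature)
  glen <- nchar(genome$sequence)
  circ <- genome$topology == "circular"
  segs <- fr$segments[[1]]
  parts <- vapply(seq_len(nrow(segs)), function(i) {
    pos <- segment_positions(segs[i, ], glen, circ)
    paste(strsplit(genome$sequence, "")[[1]][pos], collapse = "")
  }, character(1))
  s <- paste(parts, collapse = "")
  if (fr$strand == "-") s <- revcomp(s)
  s
}

resolve_feature <- function(genome, feature) {
  if (is.data.frame(feature)) return(feature)
  if (is.character(feature)) {
    i <- match(feature, genome$features$name)
    if (is.na(i)) stop_dinomito("no feature named '%s'", feature,
                                class = "feature_not_found")
    return(genome$features[i, ])
  }
  genome$features[feature, ]
}

#' Translate a coding sequence
#'
#' @param cds DNA string.
#' @param table genetic code: 1 (universal; TGA = stop) or 4 (TGA = Trp).
#' @param mode `"standard"` requires a length divisible by 3; `"open_frame"`
#'   translates without requiring an initiator or terminator and trims a
#'   trailing partial codon (used for dinoflagellate host genes, which lack
#'   canonical start and stop codons).
#' @return protein string; stops as `*`.  In standard mode an internal stop
#'   raises a warning of class `internal_stop` (flagged, never dropped).
#' @export
translate_cds <- function(cds, table = 1L, mode = c("standard", "open_frame")) {
  mode <- match.arg(mode)
  cds <- toupper(cds)
  if (mode == "standard" && nchar(cds) %% 3 != 0)
    stop_dinomito("CDS length %d not divisible by 3", nchar(cds),
                  class = "frame_error")
  if (mode == "open_frame") cds <- substr(cds, 1, nchar(cds) %/% 3 * 3)
  if (!nzchar(cds)) return("")
  code <- Biostrings::getGeneticCode(as.character(table))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), genetic.code = code,
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
  if (mode == "standard") {
    internal <- grepl("\\*", substr(aa, 1, nchar(aa) - 1))
    if (internal)
      warning(warningCondition(
        sprintf("internal stop codon in CDS (length %d)", nchar(cds)),
        class = "internal_stop"))
  }
  aa
}

#' Normalize a gene symbol
#'
#' Lowercases (tRNAs keep their amino-acid letter case), strips locus-tag
#' prefixes, and maps synonyms (e.g. `rnl`/`LSU` for the large-subunit rRNA)
#' through a user-extensible table, so that genes can be matched across
#' genomes annotated by different groups.
#'
#' @param name raw gene name(s).
#' @param synonyms named character vector mapping alternate symbols to
#'   canonical ones, merged over the built-in table.
#' @return canonical symbol(s).
#' @export
normalize_gene_name <- function(name, synonyms = character()) {
  builtin <- c(lsu = "rnl", "rrnl" = "rnl", "23s" = "rnl", "26s" = "rnl",
               ssu = "rns", "rrns" = "rns", "16s" = "rns", "18s" = "rns",
               cytb = "cob", cox3a = "cox3-1", cox3b = "cox3-2",
               atpase6 = "atp6", atpase8 = "atp8", atpase9 = "atp9",
               nad4l = "nad4L", tatc = "tatC", ymf16 = "tatC")
  map <- c(synonyms, builtin)
  out <- sub("^[A-Za-z0-9]+_", "", name)          # locus-tag prefixes
  trna <- grepl("^trn", out, ignore.case = TRUE)
  out[!trna] <- tolower(out[!trna])
  out[trna] <- paste0("trn", sub("^trn", "", out[trna], ignore.case = TRUE))
  hit <- match(tolower(out), tolower(names(map)))
  out[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  out
}

# ---------------------------------------------------------------------------
# GenBank flat-file reading

#' Read an annotated genome from a GenBank flat file
#'
#' A minimal reader for the GenBank flat-file dialect used by organellar
#' genome deposits: LOCUS topology, ORIGIN sequence, and CDS/rRNA/tRNA/intron
#' features with `complement()`/`join()` locations and the usual qualifiers.
#' Features whose key is not one of those four are ignored (source, gene,
#' misc_feature, ...).
#'
#' @param path file path (or a character vector of lines via `text`).
#' @param text optional character vector of record lines, instead of `path`.
#' @param topology override the LOCUS topology (e.g. `"linear_gapped"` for a
#'   circular-mapping genome with one unsequenced gap).
#' @param synonyms passed to [normalize_gene_name()].
#' @return [annotated_genome()].
#' @export
read_genbank <- function(path, text = NULL, topology = NULL,
                         synonyms = character()) {
  lines <- text %||% readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus))
    stop_dinomito("no LOCUS line", class = "parse_error")
  toks <- strsplit(trimws(locus[1]), "[ \t]+")[[1]]
  id <- toks[2]
  topo <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  tt <- 1L

  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart))
    stop_dinomito("no ORIGIN section", class = "parse_error")
  oend <- grep("^//", lines)
  oend <- if (length(oend)) oend[oend > ostart][1] else length(lines) + 1
  seqtxt <- paste(lines[(ostart + 1):(oend - 1)], collapse = "")
  sequence <- toupper(gsub("[^A-Za-z]", "", seqtxt))
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
    stop_dinomito("unknown residue characters in ORIGIN", class = "parse_error")

  fstart <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(fstart)) {
    flines <- lines[(fstart[1] + 1):(ostart - 1)]
    # a new feature starts with a key in column 6; continuation lines are
    # indented to column 22
    keyed <- grepl("^ {5}\\S", flines)
    idx <- cumsum(keyed)
    for (k in seq_len(max(idx, 0))) {
      block <- flines[idx == k]
      key <- sub("^ {5}(\\S+).*", "\\1", block[1])
      rest <- sub("^ {5}\\S+\\s*", "", block[1])
      cont <- trimws(block[-1])
      qstart <- grep("^/", cont)
      loc <- paste(c(rest, if (length(qstart)) head(cont, qstart[1] - 1) else cont),
                   collapse = "")
      quals <- parse_qualifiers(if (length(qstart)) cont[qstart[1]:length(cont)]
                                else character())
      if (!is.null(quals$transl_table)) tt <- as.integer(quals$transl_table)
      if (!key %in% c("CDS", "rRNA", "tRNA", "intron")) next
      pl <- parse_location(loc, key)
      name <- quals$gene %||% quals$standard_name %||% quals$product %||%
        quals$locus_tag %||% paste0(tolower(key), k)
      name <- normalize_gene_name(name, synonyms)
      cls <- switch(key, rRNA = "rRNA", tRNA = "tRNA", intron = "intron",
                    CDS = if (!is.null(quals$pseudo)) "pseudogene"
                    else if (grepl("^orf", name)) "orf" else "protein")
      features <- rbind(features,
                        gene_feature(name, cls, pl$strand, pl$segments,
                                     complete = pl$complete))
    }
  }
  if (anyDuplicated(features$name)) {
    # keep duplicate copies distinguishable (e.g. two trnM genes)
    occ <- stats::ave(seq_len(nrow(features)), features$name, FUN = seq_along)
    dup <- features$name %in% features$name[duplicated(features$name)]
    features$name[dup] <- paste0(features$name[dup], ".", occ[dup])
  }
  annotated_genome(id, sequence, features,
                   topology = topology %||% topo, translation_table = tt)
}

parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  txt <- paste(lines, collapse = "\n")
  pieces <- strsplit(txt, "\n/")[[1]]
  pieces[1] <- sub("^/", "", pieces[1])
  out <- list()
  for (p in pieces) {
    p <- gsub("\n", " ", p)
    if (grepl("=", p)) {
      k <- sub("=.*", "", p)
      v <- sub('^[^=]+=', "", p)
      v <- gsub('^"|"$', "", trimws(v))
      out[[k]] <- v
    } else out[[trimws(p)]] <- TRUE
  }
  out
}

parse_location <- function(loc, key = "feature") {
  loc <- gsub("[ \t]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  elems <- strsplit(loc, ",")[[1]]
  complete <- !grepl("[<>]", loc)
  segs <- t(vapply(elems, function(e) {
    e <- gsub("[<>]", "", e)
    if (grepl("^[0-9]+$", e)) return(c(as.integer(e), as.integer(e)))
    m <- regmatches(e, regexec("^([0-9]+)\\.\\.([0-9]+)$", e))[[1]]
    if (length(m) != 3)
      stop_dinomito("malformed coordinates '%s' in %s", e, key,
                    class = "parse_error")
    as.integer(m[2:3])
  }, integer(2)))
  # GenBank lists complement(join(...)) segments in plus-strand order; our
  # convention stores plus-strand reading order, so nothing to flip.
  list(strand = strand, segments = segs, complete = complete)
}

# ---------------------------------------------------------------------------
# GenBank flat-file writing (round-trips through read_genbank)

#' Write an annotated genome as a GenBank flat file
#'
#' Emits the subset of the flat-file dialect that [read_genbank()] consumes,
#' so that read -> write -> read round-trips the feature table exactly.
#'
#' @param genome an [annotated_genome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- nchar(genome$sequence)
  topo <- if (genome$topology == "circular") "circular" else "linear"
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   UNA 01-JAN-2000",
                   genome$id, L, topo),
           sprintf("DEFINITION  %s mitochondrial genome.", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    key <- switch(f$cls, protein = "CDS", orf = "CDS", pseudogene = "CDS",
                  rRNA = "rRNA", tRNA = "tRNA", intron = "intron")
    segs <- f$segments[[1]]
    locs <- sprintf("%d..%d", segs[, 1], segs[, 2])
    loc <- if (length(locs) > 1) sprintf("join(%s)", paste(locs, collapse = ","))
    else locs
    if (!f$complete) loc <- sub("^(join\\()?", "\\1<", loc)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     %-15s %s", key, loc),
             sprintf("                     /gene=\"%s\"", f$name))
    if (!is.null(f$cls) && f$cls == "pseudogene")
      out <- c(out, "                     /pseudo")
    if (key == "CDS" && f$cls != "pseudogene")
      out <- c(out, sprintf("                     /transl_table=%d",
                            genome$translation_table))
  }
  out <- c(out, "ORIGIN")
  sq <- tolower(genome$sequence)
  starts <- seq(1, L, by = 60)
  for (s in starts) {
    chunk <- substr(sq, s, min(s + 59, L))
    tens <- regmatches(chunk, gregexpr(".{1,10}", chunk))[[1]]
    out <- c(out, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA and feature-table IO

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of DNA sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*", "", names(x)))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  out <- unlist(lapply(names(seqs), function(n) {
    s <- seqs[[n]]
    c(paste0(">", n),
      substring(s, seq(1, nchar(s), width),
                pmin(seq(1, nchar(s), width) + width - 1, nchar(s))))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Flat feature table of a genome
#'
#' One row per feature: genome_id, name, cls, strand, segments (as
#' `start..end` joined by `;`), spliced length.  This is the TSV interchange
#' format of the `stats` and `simulate` subcommands.
#'
#' @param genome an [annotated_genome()].
#' @return data.frame.
#' @export
feature_table <- function(genome) {
  n <- nrow(genome$features)
  data.frame(
    genome_id = rep(genome$id, n),
    name = genome$features$name,
    cls = genome$features$cls,
    strand = genome$features$strand,
    segments = vapply(genome$features$segments, function(s)
      paste(sprintf("%d..%d", s[, 1], s[, 2]), collapse = ";"), character(1)),
    length = vapply(seq_len(n), function(i)
      length(feature_positions(genome, genome$features[i, ], spliced = TRUE)),
      integer(1)),
    stringsAsFactors = FALSE)
}

#' Rotate a circular genome to a new origin
#'
#' Shifts the sequence so that position `new_origin` becomes position 1 and
#' remaps all feature coordinates (segments may newly wrap or stop wrapping).
#' Statistics are invariant under rotation; this is also used to canonicalize
#' circular gene orders.
#'
#' @param genome a circular [annotated_genome()].
#' @param new_origin 1-based position that becomes position 1.
#' @return rotated [annotated_genome()].
#' @export
rotate_genome <- function(genome, new_origin) {
  if (genome$topology != "circular")
    stop_dinomito("rotation requires a circular genome", class = "topology_error")
  L <- nchar(genome$sequence)
  k <- ((new_origin - 1) %% L)
  if (k == 0) return(genome)
  sq <- paste0(substr(genome$sequence, k + 1, L), substr(genome$sequence, 1, k))
  shift <- function(p) as.integer(((p - k - 1) %% L) + 1)
  feats <- genome$features
  feats$segments <- I(lapply(feats$segments, function(s) {
    s[, 1] <- shift(s[, 1]); s[, 2] <- shift(s[, 2]); s
  }))
  g <- genome
  g$sequence <- sq
  g$features <- feats
  validate_genome(g)
  g
}
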