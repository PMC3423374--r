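# Shared small helpers: seeded streams, sequence utilities, TSV reports.

#' Run code under a named deterministic random stream
#'
#' Derives a sub-seed from `seed` and a stage label, runs `expr` under it and
#' restores the caller's RNG state afterwards.  Each generator stage draws
#' from its own stream, so adding a stage never perturbs another stage's
#' draws.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_stage_seed <- function(seed, stage, expr) {
  sub <- stage_seed(seed, stage)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub)
  expr
}

# FNV-1a style string hash folded into [1, 2^31 - 2]; keeps derived seeds
# well inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  h <- 216613626
  for (cc in utf8ToInt(stage)) {
    h <- bitwXor(as.integer(h %% 2147483647), cc)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((abs(seed) * 48271 + h) %% 2147483562 %% 2147483646 + 1)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# sample() without the length-1 surprise
sample_int <- function(x, n, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a TSV report with provenance header
#'
#' Reports carry `#`-prefixed provenance lines (tool version, config hash,
#' seed) above a standard tab-separated table, and are written atomically
#' (tempfile in the same directory, then rename).
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list recorded in the header (seed, parameters, ...).
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("dinomito ",
                               as.character(utils::packageVersion("dinomito")))),
            meta)
  meta$config_hash <- config_hash(meta)
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = ","),
                        character(1)))
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wt")
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read back a TSV report written by [write_tsv_report()]
#' @param path file path.
#' @return data.frame; header lines are attached as attribute `"meta"`.
#' @export
read_tsv_report <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  df <- read.table(text = lines[setdiff(seq_along(lines), hdr)],
                   sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  attr(df, "meta") <- sub("^# ", "", lines[hdr])
  df
}

config_hash <- function(x) {
  s <- paste(deparse(x[sort(names(x))]), collapse = "")
  h <- 216613626
  for (cc in utf8ToInt(s))
    h <- (bitwXor(as.integer(h), cc) * 16777) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_dinomito <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "dinomito_error")))
}
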