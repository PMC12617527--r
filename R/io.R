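# Readers and writers for the package's plain-text formats. All TSVs carry
# a single "#"-prefixed header comment with the schema name and config
# hash; coordinate-bearing files use 0-based, half-open coordinates.

#' Read a CDS multi-FASTA
#'
#' Headers follow the `gene_id<delim>transcript_id` convention (a header
#' without the delimiter uses the whole id for both fields). Sequences are
#' uppercased; every record is validated (non-empty, in frame, A/C/G/T
#' alphabet) and all failures are reported together.
#'
#' @param path FASTA file.
#' @param delim Header delimiter between gene and transcript id.
#' @return CDS set `data.frame` with `gene_id`, `transcript_id`,
#'   `sequence`.
#' @export
read_cds_fasta <- function(path, delim = "|") {
  if (!file.exists(path)) {
    stop("cannot read FASTA: ", path, call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(ids, delim, fixed = TRUE)
  gene_id <- vapply(parts, `[`, character(1), 1L)
  transcript_id <- vapply(parts, function(p) if (length(p) >= 2L) p[2] else p[1],
                          character(1))
  key <- paste(gene_id, transcript_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate gene_id+transcript_id in FASTA: ",
         paste(unique(ids[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  sequence <- toupper(as.character(seqs))
  errors <- character(0)
  for (i in seq_along(sequence)) {
    msg <- tryCatch({
      invisible(enumerate_codons(sequence[i]))
      NA_character_
    }, error = function(e) conditionMessage(e))
    if (!is.na(msg)) {
      errors <- c(errors, paste0(ids[i], ": ", msg))
    }
  }
  if (length(errors) > 0L) {
    stop("invalid CDS record(s):\n  ", paste(errors, collapse = "\n  "), call. = FALSE)
  }
  data.frame(gene_id = gene_id, transcript_id = transcript_id,
             sequence = unname(sequence), stringsAsFactors = FALSE)
}

#' Write a CDS set as multi-FASTA
#'
#' @param cds CDS set `data.frame`.
#' @param path Output file.
#' @param delim Header delimiter.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path, delim = "|") {
  stopifnot(all(c("gene_id", "transcript_id", "sequence") %in% names(cds)))
  x <- Biostrings::DNAStringSet(cds$sequence)
  names(x) <- paste(cds$gene_id, cds$transcript_id, sep = delim)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Stable hash of a configuration object
#'
#' 32-bit FNV-1a over the deparsed object, printed as 8 hex digits. Used to
#' stamp output files so a run's inputs can be matched to its config.
#'
#' @param x Any R object.
#' @return Character scalar, e.g. `"a1b2c3d4"`.
#' @export
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte, keeping h a double in [0, 2^32)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619; the 16-bit split
    # keeps every intermediate inside the exact-integer range of doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536 * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a TSV with a schema comment header
#'
#' @param df Data frame.
#' @param path Output file.
#' @param schema Short schema name recorded in the header comment.
#' @param hash Config hash recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, schema = "table", hash = "") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# sercodon schema=%s version=1 coords=0-based-half-open hash=%s",
                     schema, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (or any headered TSV)
#'
#' `#` comment lines are skipped; the presence of `required_cols` is
#' checked and rows with the wrong field count are reported with their line
#' numbers.
#'
#' @param path Input file.
#' @param required_cols Character vector of columns that must be present.
#' @return Data frame.
#' @export
read_tsv <- function(path, required_cols = character(0)) {
  if (!file.exists(path)) {
    stop("cannot read TSV: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  content_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(content_idx) == 0L) {
    stop(path, ": no content rows", call. = FALSE)
  }
  nfields <- vapply(strsplit(lines[content_idx], "\t", fixed = TRUE), length, integer(1))
  if (length(unique(nfields)) > 1L) {
    bad <- content_idx[nfields != nfields[1]]
    stop(path, ": malformed row(s) at line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (expected ", nfields[1], " tab-separated fields)", call. = FALSE)
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop(path, ": missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a footprint alignment TSV
#'
#' Columns `transcript_id`, `start`, `end` in 0-based, half-open transcript
#' CDS coordinates.
#'
#' @param path Input file.
#' @return Alignment `data.frame`.
#' @export
read_alignments_tsv <- function(path) {
  df <- read_tsv(path, required_cols = c("transcript_id", "start", "end"))
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$start < 0 | df$end <= df$start)
  if (length(bad) > 0L) {
    stop(path, ": invalid alignment row(s) (data row ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "): need 0 <= start < end", call. = FALSE)
  }
  df
}

#' Read a tRNA isodecoder count TSV
#'
#' Columns `isodecoder_id`, `condition`, `n_cca`, `n_cc`, `n_pre`, and
#' optionally `library_size`.
#'
#' @param path Input file.
#' @return Count `data.frame`.
#' @export
read_trna_counts_tsv <- function(path) {
  df <- read_tsv(path, required_cols = c("isodecoder_id", "condition",
                                         "n_cca", "n_cc", "n_pre"))
  num <- intersect(c("n_cca", "n_cc", "n_pre", "library_size"), names(df))
  for (col in num) {
    if (any(!is.finite(df[[col]]) | df[[col]] < 0)) {
      stop(path, ": negative or non-numeric values in ", col, call. = FALSE)
    }
  }
  df
}
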