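# Downstream charged DM-tRNA-seq arithmetic: 3'-end read classification,
# charging fractions, isodecoder -> isoacceptor aggregation, charged pools,
# isoacceptor ratio tables.

#' tRNA reference record
#'
#' Describes one tRNA isodecoder for read-end classification. The read
#' coordinate system is the transcript laid out as
#' `[leader][mature body][CCA][trailer]`; the mature 3' end (after the
#' post-transcriptionally added CCA) sits at `leader_len + mature_len + 3`.
#'
#' @param isodecoder_id Identifier, `AminoAcid-Anticodon-Copy`
#'   (e.g. `"Ser-AGA-1"`).
#' @param mature_len Length of the mature body up to and including the
#'   discriminator base (CCA not included). Must be 50-150 nt, the
#'   gel-purified tRNA size range.
#' @param leader_len,trailer_len 5' leader / 3' trailer lengths (>= 0).
#' @return Object of class `trna_reference`.
#' @export
trna_reference <- function(isodecoder_id, mature_len, leader_len = 0L, trailer_len = 0L) {
  mature_len <- as.integer(mature_len)
  if (mature_len < 50L || mature_len > 150L) {
    stop("mature tRNA length must be in 50-150 nt, got ", mature_len, call. = FALSE)
  }
  if (leader_len < 0L || trailer_len < 0L) {
    stop("leader/trailer lengths must be >= 0", call. = FALSE)
  }
  structure(
    list(
      isodecoder_id = isodecoder_id,
      mature_len = mature_len,
      leader_len = as.integer(leader_len),
      trailer_len = as.integer(trailer_len)
    ),
    class = "trna_reference"
  )
}

#' Classify a tRNA-seq read by its 3' end
#'
#' Periodate oxidation destroys the 3'-terminal ribose of uncharged tRNAs
#' while the esterified amino acid protects charged ones, so after repair
#' and ligation a charged mature tRNA reads through the full ...CCA end and
#' an uncharged one ends one base short at ...CC. Reads extending into the
#' leader or trailer are pre-tRNA; anything else is ambiguous (a counted
#' category, not an error).
#'
#' @param read_end 0-based exclusive 3' alignment end on the reference
#'   layout of `ref` (see [trna_reference()]).
#' @param terminal_bases Last bases of the read sequence (at least 2-3).
#' @param ref A [trna_reference()].
#' @param read_start Optional 0-based alignment start; a start inside the
#'   leader also classifies the read as `pre`.
#' @return One of `"charged_mature"`, `"uncharged_mature"`, `"pre"`,
#'   `"ambiguous"`.
#' @export
classify_read_end <- function(read_end, terminal_bases, ref, read_start = NULL) {
  stopifnot(inherits(ref, "trna_reference"))
  mature_cca_end <- ref$leader_len + ref$mature_len + 3L
  total_len <- mature_cca_end + ref$trailer_len
  if (read_end < 0L || read_end > total_len) {
    stop("read end ", read_end, " outside reference bounds [0, ", total_len, "]",
         call. = FALSE)
  }
  terminal_bases <- toupper(terminal_bases)
  if (read_end > mature_cca_end ||
      (!is.null(read_start) && read_start < ref$leader_len)) {
    return("pre")
  }
  if (read_end == mature_cca_end && endsWith(terminal_bases, "CCA")) {
    return("charged_mature")
  }
  if (read_end == mature_cca_end - 1L && endsWith(terminal_bases, "CC")) {
    return("uncharged_mature")
  }
  "ambiguous"
}

#' Percentage of charged tRNA
#'
#' `100 * n_cca / (n_cca + n_cc)`; `NA` (undefined) when no mature reads
#' were observed. Ambiguous reads are excluded from the denominator.
#'
#' @param n_cca,n_cc Counts of reads ending ...CCA (charged) and ...CC
#'   (uncharged), vectorized.
#' @return Percent charged, or `NA_real_` where undefined.
#' @export
charging_fraction <- function(n_cca, n_cc) {
  if (any(n_cca < 0) || any(n_cc < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  denom <- n_cca + n_cc
  ifelse(denom > 0, 100 * n_cca / denom, NA_real_)
}

parse_isodecoder <- function(isodecoder_id) {
  parts <- strsplit(isodecoder_id, "-", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2L || any(p[1:2] == ""), logical(1))
  if (any(bad)) {
    stop("unparseable isodecoder id(s): ",
         paste(unique(isodecoder_id[bad]), collapse = ", "),
         " (expected 'AminoAcid-Anticodon[-copy]')", call. = FALSE)
  }
  data.frame(
    amino_acid = vapply(parts, `[`, character(1), 1L),
    anticodon = vapply(parts, `[`, character(1), 2L),
    isoacceptor_id = vapply(parts, function(p) paste(p[1:2], collapse = "-"), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Aggregate isodecoder counts into isoacceptors
#'
#' Sums the read counts of all isodecoders sharing an anticodon, per
#' condition, preserving grand totals. Mature reads are `n_cca + n_cc`.
#'
#' @param counts `data.frame` with columns `isodecoder_id`, `condition`,
#'   `n_cca`, `n_cc`, `n_pre` (and optionally `library_size`, carried
#'   through; it must agree within a condition).
#' @return `data.frame` with `isoacceptor_id`, `amino_acid`, `anticodon`,
#'   `condition`, summed `n_cca`, `n_cc`, `n_pre`, and `n_mature`.
#' @export
sum_isoacceptors <- function(counts) {
  need <- c("isodecoder_id", "condition", "n_cca", "n_cc", "n_pre")
  stopifnot(is.data.frame(counts), all(need %in% names(counts)))
  if (nrow(counts) == 0L) {
    out <- data.frame(
      isoacceptor_id = character(0), amino_acid = character(0),
      anticodon = character(0), condition = character(0),
      n_cca = numeric(0), n_cc = numeric(0), n_pre = numeric(0),
      n_mature = numeric(0), stringsAsFactors = FALSE
    )
    return(out)
  }
  parsed <- parse_isodecoder(counts$isodecoder_id)
  key <- list(isoacceptor_id = parsed$isoacceptor_id, condition = counts$condition)
  agg <- stats::aggregate(counts[, c("n_cca", "n_cc", "n_pre")], by = key, FUN = sum)
  meta <- unique(data.frame(isoacceptor_id = parsed$isoacceptor_id,
                            amino_acid = parsed$amino_acid,
                            anticodon = parsed$anticodon,
                            stringsAsFactors = FALSE))
  out <- merge(agg, meta, by = "isoacceptor_id", sort = TRUE)
  if ("library_size" %in% names(counts)) {
    lib <- unique(counts[, c("condition", "library_size")])
    if (anyDuplicated(lib$condition)) {
      stop("library_size differs between rows of the same condition", call. = FALSE)
    }
    out <- merge(out, lib, by = "condition", sort = FALSE)
  }
  out$n_mature <- out$n_cca + out$n_cc
  ord <- order(out$isoacceptor_id, out$condition)
  out <- out[ord, c("isoacceptor_id", "amino_acid", "anticodon", "condition",
                    "n_cca", "n_cc", "n_pre", "n_mature",
                    intersect("library_size", names(out)))]
  rownames(out) <- NULL
  out
}

#' Charged tRNA level
#'
#' The charged pool is the charging percentage applied to the mature tRNA
#' level: `(pct_charged / 100) * mature_level`. Undefined charging (`NA`)
#' propagates.
#'
#' @param pct_charged Percent charged (0-100 or `NA`), vectorized.
#' @param mature_level Mature tRNA level (normalized counts).
#' @return Charged tRNA level on the same scale as `mature_level`.
#' @export
charged_level <- function(pct_charged, mature_level) {
  (pct_charged / 100) * mature_level
}

#' Counts per million
#'
#' @param count Read count(s).
#' @param library_size Total reads in the library (> 0).
#' @return `count * 1e6 / library_size`.
#' @export
cpm_normalize <- function(count, library_size) {
  if (any(library_size <= 0)) {
    stop("library_size must be > 0", call. = FALSE)
  }
  count * 1e6 / library_size
}

#' Isoacceptor pool ratios for one amino acid
#'
#' Normalizes charged (or mature) isoacceptor levels to their within-amino-
#' acid pool (`ratio_in_pool = level / sum(levels)`) and reports one named
#' pairwise ratio, e.g. tRNA-Ser(AGA) : tRNA-Ser(GCU).
#'
#' @param levels Named numeric vector of isoacceptor levels (>= 0), one
#'   amino acid's isoacceptors.
#' @param pair Length-2 character vector naming the numerator and
#'   denominator isoacceptors of the pairwise ratio, or `NULL` to skip.
#' @return List with `table` (`data.frame`: `isoacceptor_id`, `level`,
#'   `ratio_in_pool`) and `pairwise` (numeric or `NA` when the denominator
#'   level is 0). An all-zero pool yields `NA` ratios and an attribute
#'   `flag = "all_zero_pool"` on the result.
#' @export
isoacceptor_ratio_table <- function(levels, pair = NULL) {
  if (length(levels) < 1L || is.null(names(levels))) {
    stop("levels must be a named vector with >= 1 isoacceptor", call. = FALSE)
  }
  if (any(levels < 0, na.rm = TRUE)) {
    stop("levels must be >= 0", call. = FALSE)
  }
  total <- sum(levels)
  all_zero <- !is.na(total) && total == 0
  ratio <- if (all_zero) rep(NA_real_, length(levels)) else as.numeric(levels) / total
  tab <- data.frame(
    isoacceptor_id = names(levels),
    level = as.numeric(levels),
    ratio_in_pool = ratio,
    stringsAsFactors = FALSE
  )
  pairwise <- NA_real_
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2L)
    missing <- setdiff(pair, names(levels))
    if (length(missing) > 0L) {
      stop("pair member(s) absent from levels: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    denom <- levels[[pair[2]]]
    pairwise <- if (is.na(denom) || denom == 0) NA_real_ else levels[[pair[1]]] / denom
  }
  out <- list(table = tab, pairwise = pairwise)
  if (all_zero) attr(out, "flag") <- "all_zero_pool"
  out
}

#' Full charging table from isodecoder counts
#'
#' End-to-end tRNA quantification: aggregates isodecoders into
#' isoacceptors, computes the charging percentage, CPM-normalized mature
#' and pre levels (when `library_size` is present; raw counts otherwise),
#' the charged pool, and each isoacceptor's share of its amino acid's
#' charged pool.
#'
#' @param counts Isodecoder count table, see [sum_isoacceptors()].
#' @return `data.frame` with one row per isoacceptor and condition:
#'   `pct_charged`, `mature_level`, `pre_level`, `charged_level`,
#'   `ratio_in_pool`.
#' @export
charging_table <- function(counts) {
  iso <- sum_isoacceptors(counts)
  iso$pct_charged <- charging_fraction(iso$n_cca, iso$n_cc)
  if ("library_size" %in% names(iso)) {
    iso$mature_level <- cpm_normalize(iso$n_mature, iso$library_size)
    iso$pre_level <- cpm_normalize(iso$n_pre, iso$library_size)
  } else {
    iso$mature_level <- iso$n_mature
    iso$pre_level <- iso$n_pre
  }
  iso$charged_level <- charged_level(iso$pct_charged, iso$mature_level)
  iso$ratio_in_pool <- NA_real_
  for (grp in split(seq_len(nrow(iso)), list(iso$amino_acid, iso$condition), drop = TRUE)) {
    lv <- iso$charged_level[grp]
    tot <- sum(lv, na.rm = TRUE)
    if (tot > 0) {
      iso$ratio_in_pool[grp] <- ifelse(is.na(lv), NA_real_, lv / tot)
    }
  }
  iso
}
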