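# Per-gene serine codon composition: enumeration, class counts, percentages,
# codon-balance z-scores, percentage bins, longest-CDS selection.

#' Serine codon classes
#'
#' The three serine codon classes whose decoding responds differently to
#' serine limitation, keyed by their RNA-style class labels. Internally the
#' package works on the DNA alphabet (`TCC`/`TCT` etc.); outputs use the
#' RNA-style labels `UC[C/U]`, `AG[U/C]`, `UC[G/A]`.
#'
#' @return Named list of character vectors of DNA codons.
#' @export
ser_codon_classes <- function() {
  list(
    "UC[C/U]" = c("TCC", "TCT"),
    "AG[U/C]" = c("AGT", "AGC"),
    "UC[G/A]" = c("TCG", "TCA")
  )
}

#' All sense codons (DNA alphabet)
#'
#' The 61 codons that encode amino acids, i.e. all triplets over A/C/G/T
#' except the three stop codons.
#'
#' @return Character vector of 61 codons.
#' @export
sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}

normalize_cds_sequence <- function(sequence) {
  seq <- toupper(as.character(sequence))
  # U is accepted on input and mapped onto the DNA alphabet
  seq <- chartr("U", "T", seq)
  if (nchar(seq) == 0L) {
    stop("empty coding sequence", call. = FALSE)
  }
  bad <- gsub("[ACGT]", "", seq)
  if (nchar(bad) > 0L) {
    stop(
      "non-ACGT character(s) in coding sequence after normalization: ",
      paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
      call. = FALSE
    )
  }
  seq
}

#' Split an in-frame CDS into codons
#'
#' Partitions a coding sequence into consecutive triplets in reading frame 0.
#' Lowercase and RNA-alphabet (`U`) input is normalized to uppercase DNA.
#'
#' @param sequence Nucleotide string; length must be a multiple of 3.
#' @return Character vector of codons, in order.
#' @examples
#' enumerate_codons("ATGTCCTAA")
#' @export
enumerate_codons <- function(sequence) {
  seq <- normalize_cds_sequence(sequence)
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " is not divisible by 3 (out of frame)", call. = FALSE)
  }
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Count serine codon classes in a codon list
#'
#' Tallies the three serine codon classes (UC\[C/U\] = TCC/TCT,
#' AG\[U/C\] = AGT/AGC, UC\[G/A\] = TCG/TCA) over a codon vector from
#' [enumerate_codons()]. All codons are counted, including the first and
#' last of the CDS.
#'
#' @param codons Character vector of codons.
#' @param gene_id Optional gene identifier carried into the result.
#' @return One-row `data.frame` with columns `gene_id`, `n_ucc_ucu`,
#'   `n_agu_agc`, `n_ucg_uca`, `n_ser_total`, `n_codons_total`.
#' @export
count_ser_classes <- function(codons, gene_id = NA_character_) {
  classes <- ser_codon_classes()
  n_ucc_ucu <- sum(codons %in% classes[["UC[C/U]"]])
  n_agu_agc <- sum(codons %in% classes[["AG[U/C]"]])
  n_ucg_uca <- sum(codons %in% classes[["UC[G/A]"]])
  data.frame(
    gene_id = gene_id,
    n_ucc_ucu = n_ucc_ucu,
    n_agu_agc = n_agu_agc,
    n_ucg_uca = n_ucg_uca,
    n_ser_total = n_ucc_ucu + n_agu_agc + n_ucg_uca,
    n_codons_total = length(codons),
    stringsAsFactors = FALSE
  )
}

#' Serine codon class percentages and balance z-score
#'
#' Converts class counts into percentages of the total number of serine
#' codons, and attaches the AG\[U/C\]-vs-UC\[C/U\] codon-balance z-score.
#' Genes without any serine codon are flagged `defined = FALSE` (percentages
#' `NA`), not treated as 0%.
#'
#' @param counts One-row data frame (or row-bound frame) from
#'   [count_ser_classes()].
#' @return `data.frame` with `pct_ucc_ucu`, `pct_agu_agc`, `pct_ucg_uca`,
#'   `z_agu_vs_ucc`, `defined` appended.
#' @export
ser_percentages <- function(counts) {
  stopifnot(all(c("n_ucc_ucu", "n_agu_agc", "n_ucg_uca", "n_ser_total") %in% names(counts)))
  defined <- counts$n_ser_total > 0L
  pct <- function(n) ifelse(defined, 100 * n / counts$n_ser_total, NA_real_)
  out <- counts
  out$pct_ucc_ucu <- pct(counts$n_ucc_ucu)
  out$pct_agu_agc <- pct(counts$n_agu_agc)
  out$pct_ucg_uca <- pct(counts$n_ucg_uca)
  out$z_agu_vs_ucc <- codon_balance_zscore(counts$n_agu_agc, counts$n_ucc_ucu)
  out$defined <- defined
  out
}

#' Codon-balance z-score
#'
#' Standardized imbalance between two codon-class counts under a symmetric
#' (p = 0.5) binomial null: `z = (n_a - n_b) / sqrt(n_a + n_b)`, with z = 0
#' when both counts are zero. The package uses it with `n_a` = AG\[U/C\] and
#' `n_b` = UC\[C/U\] counts, so positive values mark AG\[U/C\]-skewed genes.
#'
#' @param n_a,n_b Non-negative counts (vectorized).
#' @return Numeric z-score(s).
#' @export
codon_balance_zscore <- function(n_a, n_b) {
  if (any(n_a < 0) || any(n_b < 0)) {
    stop("codon counts must be non-negative", call. = FALSE)
  }
  tot <- n_a + n_b
  ifelse(tot == 0, 0, (n_a - n_b) / sqrt(tot))
}

#' Percentage bin schemes
#'
#' Constructs a bin scheme over the percentage scale \[0, 100\] with
#' half-open intervals `[lo, hi)` (the last interval closed at 100).
#' `ser_bin_scheme()` returns the two schemes used throughout: `"fine"`,
#' ten 10-point bins labelled `0-10`, `11-20`, ..., `91-100`; and
#' `"coarse"`, the grouping `0-60`, `61-90`, `91-100` used to call
#' likely-sensitive genes.
#'
#' @param edges Strictly increasing numeric breakpoints from 0 to 100.
#' @param labels One label per interval (`length(edges) - 1`).
#' @return Object of class `bin_scheme`.
#' @export
bin_scheme <- function(edges, labels) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    stop("edges must be strictly increasing", call. = FALSE)
  }
  if (edges[1] != 0 || edges[length(edges)] != 100) {
    stop("edges must cover [0, 100]", call. = FALSE)
  }
  if (length(labels) != length(edges) - 1L) {
    stop("need one label per interval", call. = FALSE)
  }
  structure(list(edges = edges, labels = as.character(labels)),
            class = "bin_scheme")
}

#' @rdname bin_scheme
#' @param which `"fine"` or `"coarse"`.
#' @export
ser_bin_scheme <- function(which = c("fine", "coarse")) {
  which <- match.arg(which)
  if (which == "fine") {
    bin_scheme(
      edges = c(0, seq(11, 91, by = 10), 100),
      labels = c("0-10", paste(seq(11, 81, by = 10), seq(20, 90, by = 10), sep = "-"), "91-100")
    )
  } else {
    bin_scheme(edges = c(0, 61, 91, 100), labels = c("0-60", "61-90", "91-100"))
  }
}

#' Bin midpoints of a scheme
#'
#' @param scheme A [bin_scheme()].
#' @return Named numeric vector of interval midpoints.
#' @export
bin_midpoints <- function(scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  mids <- (scheme$edges[-length(scheme$edges)] + scheme$edges[-1]) / 2
  names(mids) <- scheme$labels
  mids
}

#' Assign percentages to bins
#'
#' Maps each percentage to the unique label of the interval containing it
#' under the half-open convention `[lo, hi)`, last interval closed at 100.
#'
#' @param pct Numeric vector in \[0, 100\] (`NA` passes through).
#' @param scheme A [bin_scheme()].
#' @return Character vector of bin labels.
#' @export
assign_bin <- function(pct, scheme = ser_bin_scheme("fine")) {
  stopifnot(inherits(scheme, "bin_scheme"))
  ok <- is.na(pct) | (pct >= 0 & pct <= 100)
  if (!all(ok)) {
    stop("percentage outside [0, 100]: ", paste(pct[!ok], collapse = ", "), call. = FALSE)
  }
  idx <- findInterval(pct, scheme$edges, rightmost.closed = TRUE)
  out <- scheme$labels[idx]
  out[is.na(pct)] <- NA_character_
  out
}

#' Select the longest CDS per gene
#'
#' Keeps, for each gene, the transcript with the longest CDS; exact length
#' ties are broken by the lexicographically smallest `transcript_id`.
#'
#' @param cds A CDS set: `data.frame` with columns `gene_id`,
#'   `transcript_id`, `sequence` (one row per transcript), e.g. from
#'   [read_cds_fasta()].
#' @return CDS set with one row per gene.
#' @export
select_longest_cds <- function(cds) {
  stopifnot(is.data.frame(cds), all(c("gene_id", "transcript_id", "sequence") %in% names(cds)))
  if (nrow(cds) == 0L) {
    stop("empty CDS set", call. = FALSE)
  }
  len <- nchar(cds$sequence)
  ord <- order(cds$gene_id, -len, cds$transcript_id)
  cds <- cds[ord, , drop = FALSE]
  out <- cds[!duplicated(cds$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene serine codon profile table
#'
#' End-to-end composition table over a CDS set: longest CDS per gene, codon
#' counts, class percentages, codon-balance z-score, and fine/coarse bin
#' assignments of the requested class percentage.
#'
#' @param cds CDS set `data.frame` (`gene_id`, `transcript_id`, `sequence`).
#' @param longest_only Reduce to one (longest) transcript per gene first.
#' @param bin_on Which class percentage drives the bin columns; one of
#'   `"pct_ucc_ucu"`, `"pct_agu_agc"`, `"pct_ucg_uca"`.
#' @return `data.frame` with columns `gene_id`, `transcript_id`, `cds_len`,
#'   `n_codons_total`, class counts, `n_ser_total`, class percentages,
#'   `z_agu_vs_ucc`, `defined`, `bin_fine`, `bin_coarse`.
#' @export
ser_codon_profile <- function(cds, longest_only = TRUE, bin_on = "pct_ucc_ucu") {
  bin_on <- match.arg(bin_on, c("pct_ucc_ucu", "pct_agu_agc", "pct_ucg_uca"))
  if (longest_only) {
    cds <- select_longest_cds(cds)
  }
  rows <- lapply(seq_len(nrow(cds)), function(i) {
    codons <- enumerate_codons(cds$sequence[i])
    count_ser_classes(codons, gene_id = cds$gene_id[i])
  })
  prof <- ser_percentages(do.call(rbind, rows))
  prof <- cbind(
    prof[, "gene_id", drop = FALSE],
    transcript_id = cds$transcript_id,
    cds_len = nchar(cds$sequence),
    prof[, setdiff(names(prof), "gene_id"), drop = FALSE]
  )
  prof$bin_fine <- assign_bin(prof[[bin_on]], ser_bin_scheme("fine"))
  prof$bin_coarse <- assign_bin(prof[[bin_on]], ser_bin_scheme("coarse"))
  rownames(prof) <- NULL
  prof
}
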