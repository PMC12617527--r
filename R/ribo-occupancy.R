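# Codon-centric ribosome density: coverage tracks, per-transcript
# normalization, +/-150-nt codon metagenes, condition deltas, pause scores,
# and a labelled naive differential-TE ratio.

#' Build a coverage track from footprint alignments
#'
#' Per-position footprint coverage over a CDS: `values[p]` is the number of
#' footprints overlapping position `p` (0-based, half-open read intervals).
#'
#' @param alignments `data.frame` with columns `start`, `end` (0-based,
#'   half-open, transcript CDS coordinates); optionally `transcript_id`.
#' @param cds_length CDS length in nucleotides.
#' @param transcript_id Identifier stored in the track (taken from
#'   `alignments` if present and unique).
#' @return Object of class `coverage_track`: list with `transcript_id`,
#'   `values` (length `cds_length`), `n_reads`, `normalized`, `status`.
#' @export
coverage_from_alignments <- function(alignments, cds_length, transcript_id = NA_character_) {
  stopifnot(is.data.frame(alignments), all(c("start", "end") %in% names(alignments)) || nrow(alignments) == 0L)
  cds_length <- as.integer(cds_length)
  if (nrow(alignments) > 0L) {
    bad <- which(!(alignments$start >= 0L & alignments$start < alignments$end &
                     alignments$end <= cds_length))
    if (length(bad) > 0L) {
      stop(
        "out-of-bounds footprint alignment(s) at row(s): ",
        paste(utils::head(bad, 5L), collapse = ", "),
        " (CDS length ", cds_length, ")",
        call. = FALSE
      )
    }
    if ("transcript_id" %in% names(alignments) && is.na(transcript_id)) {
      ids <- unique(alignments$transcript_id)
      if (length(ids) == 1L) transcript_id <- ids
    }
    # difference-array accumulation: +1 at start, -1 at end, then cumsum
    delta <- numeric(cds_length + 1L)
    tab_s <- tabulate(alignments$start + 1L, nbins = cds_length + 1L)
    tab_e <- tabulate(alignments$end + 1L, nbins = cds_length + 1L)
    values <- cumsum(tab_s - tab_e)[seq_len(cds_length)]
  } else {
    values <- numeric(cds_length)
  }
  structure(
    list(
      transcript_id = transcript_id,
      values = as.numeric(values),
      n_reads = nrow(alignments),
      normalized = FALSE,
      status = "raw"
    ),
    class = "coverage_track"
  )
}

#' Normalize a coverage track to its mean
#'
#' Divides the track by its per-position mean coverage so that the
#' normalized mean is 1. Tracks whose raw mean coverage is below `min_mean`
#' (including all-zero tracks) are returned with `status = "filtered"` and
#' untouched values rather than normalized or erroring; normalizing an
#' already-normalized track is an error.
#'
#' @param track A `coverage_track`.
#' @param min_mean Minimum mean raw coverage (reads/nt) to retain a track.
#' @return The track, normalized (`status = "normalized"`) or filtered.
#' @export
normalize_track <- function(track, min_mean = 0) {
  stopifnot(inherits(track, "coverage_track"))
  if (isTRUE(track$normalized)) {
    stop("track is already normalized", call. = FALSE)
  }
  m <- mean(track$values)
  if (m <= 0 || m < min_mean) {
    track$status <- "filtered"
    return(track)
  }
  track$values <- track$values / m
  track$normalized <- TRUE
  track$status <- "normalized"
  track
}

#' Coverage tracks for a set of transcripts
#'
#' Convenience wrapper: splits an alignment table by transcript, builds one
#' coverage track per CDS, applies footprint-count and mean-coverage
#' filters, and normalizes the survivors. Filter counts are attached as an
#' attribute so runs can log them.
#'
#' @param alignments `data.frame` with `transcript_id`, `start`, `end`.
#' @param cds CDS set `data.frame` (`gene_id`, `transcript_id`, `sequence`).
#' @param min_footprints Minimum total footprints per transcript (default 100).
#' @param min_mean Minimum mean coverage in reads/nt (default 0.5).
#' @return Named list of normalized `coverage_track`s keyed by
#'   `transcript_id`; attribute `filtered` holds the per-reason counts.
#' @export
coverage_tracks <- function(alignments, cds, min_footprints = 100, min_mean = 0.5) {
  stopifnot(all(c("transcript_id", "start", "end") %in% names(alignments)))
  lens <- stats::setNames(nchar(cds$sequence), cds$transcript_id)
  unknown <- setdiff(unique(alignments$transcript_id), names(lens))
  if (length(unknown) > 0L) {
    stop("alignments reference transcript(s) absent from the CDS set: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  by_tx <- split(alignments[, c("start", "end")], alignments$transcript_id)
  n_low_reads <- 0L
  n_low_mean <- 0L
  tracks <- list()
  for (tx in names(by_tx)) {
    aln <- by_tx[[tx]]
    if (nrow(aln) < min_footprints) {
      n_low_reads <- n_low_reads + 1L
      next
    }
    tr <- coverage_from_alignments(aln, lens[[tx]], transcript_id = tx)
    tr <- normalize_track(tr, min_mean = min_mean)
    if (tr$status == "filtered") {
      n_low_mean <- n_low_mean + 1L
      next
    }
    tracks[[tx]] <- tr
  }
  attr(tracks, "filtered") <- c(low_footprints = n_low_reads, low_mean_coverage = n_low_mean)
  tracks
}

#' Codon-anchored ribosome-density metagene
#'
#' Mean normalized ribosome density at each position of a window around all
#' occurrences of one codon, pooled over transcripts with equal weight per
#' occurrence. Relative position 0 is the first nucleotide of the codon;
#' positions run from `-half_window` to `half_window + 2`. Window positions
#' falling outside a CDS contribute nothing (edge truncation), and
#' occurrences within `edge_exclude` codons of the CDS ends are skipped to
#' keep initiation/termination signal out of the average.
#'
#' @param tracks Named list of normalized `coverage_track`s (see
#'   [coverage_tracks()]).
#' @param cds CDS set `data.frame`; only transcripts present in both
#'   `tracks` and `cds` contribute.
#' @param codon Codon of interest (DNA or RNA alphabet, e.g. `"TCC"`).
#' @param half_window Window half-width in nucleotides (default 150).
#' @param edge_exclude Number of codons at each CDS end whose occurrences
#'   are skipped (default 20).
#' @return Object of class `metagene_result`: list with `codon`,
#'   `positions` (length `2 * half_window + 3`), `density` (NA where no
#'   occurrence covers a position), `n_occurrences` per position, and
#'   `n_occurrences_total`.
#' @export
metagene_around_codon <- function(tracks, cds, codon, half_window = 150, edge_exclude = 20) {
  codon <- chartr("u", "t", chartr("U", "T", toupper(codon)))
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop("codon must be a triplet over A/C/G/T(/U): got '", codon, "'", call. = FALSE)
  }
  half_window <- as.integer(half_window)
  if (half_window < 1L) {
    stop("half_window must be >= 1", call. = FALSE)
  }
  positions <- seq.int(-half_window, half_window + 2L)
  wlen <- length(positions)
  dsum <- numeric(wlen)
  cnt <- integer(wlen)
  seq_by_tx <- stats::setNames(cds$sequence, cds$transcript_id)
  n_occ <- 0L
  for (tx in intersect(names(tracks), names(seq_by_tx))) {
    track <- tracks[[tx]]
    if (!isTRUE(track$normalized)) {
      stop("tracks must be normalized before metagene averaging (transcript ",
           tx, ")", call. = FALSE)
    }
    codons <- enumerate_codons(seq_by_tx[[tx]])
    nc <- length(codons)
    occ <- which(codons == codon)
    occ <- occ[occ > edge_exclude & occ <= nc - edge_exclude]
    if (length(occ) == 0L) next
    L <- 3L * nc
    vals <- track$values
    for (i in occ) {
      q <- 3L * (i - 1L)                 # 0-based first nt of the occurrence
      abs_pos <- q + positions           # 0-based CDS positions
      ok <- abs_pos >= 0L & abs_pos < L
      dsum[ok] <- dsum[ok] + vals[abs_pos[ok] + 1L]
      cnt[ok] <- cnt[ok] + 1L
      n_occ <- n_occ + 1L
    }
  }
  density <- ifelse(cnt > 0L, dsum / pmax(cnt, 1L), NA_real_)
  structure(
    list(
      codon = codon,
      positions = positions,
      density = density,
      n_occurrences = cnt,
      n_occurrences_total = n_occ
    ),
    class = "metagene_result"
  )
}

#' Condition delta of codon metagenes and pause score
#'
#' Per-position difference of two metagenes for the same codon and window
#' (deprived minus rich), with a scalar pause score: the mean delta over the
#' pause span, by default positions -15 ... +17, the footprint-sized span a
#' ~33-nt ribosome centred on the A site covers around the codon.
#'
#' @param deprived,rich `metagene_result`s for the same codon and window.
#' @param pause_span Length-2 integer vector `c(lo, hi)` of relative
#'   positions over which the pause score averages (default `c(-15, 17)`).
#' @return Object of class `delta_density`: list with `codon`, `positions`,
#'   `delta`, `pause_score`, `pause_span`.
#' @export
delta_density <- function(deprived, rich, pause_span = c(-15, 17)) {
  stopifnot(inherits(deprived, "metagene_result"), inherits(rich, "metagene_result"))
  if (!identical(deprived$codon, rich$codon)) {
    stop("codon mismatch: ", deprived$codon, " vs ", rich$codon, call. = FALSE)
  }
  if (!identical(deprived$positions, rich$positions)) {
    stop("window mismatch between the two metagenes", call. = FALSE)
  }
  delta <- deprived$density - rich$density
  in_span <- deprived$positions >= pause_span[1] & deprived$positions <= pause_span[2]
  structure(
    list(
      codon = deprived$codon,
      positions = deprived$positions,
      delta = delta,
      pause_score = mean(delta[in_span], na.rm = TRUE),
      pause_span = pause_span
    ),
    class = "delta_density"
  )
}

#' Rank codons by pause score
#'
#' @param deltas List of `delta_density` objects (one per codon).
#' @return `data.frame` with `codon`, `pause_score`, `rank`, sorted by
#'   descending pause score; exact ties broken alphabetically.
#' @export
pause_rank_table <- function(deltas) {
  if (length(deltas) == 0L) {
    stop("empty delta set", call. = FALSE)
  }
  stopifnot(all(vapply(deltas, inherits, logical(1), "delta_density")))
  tab <- data.frame(
    codon = vapply(deltas, function(d) d$codon, character(1)),
    pause_score = vapply(deltas, function(d) d$pause_score, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$pause_score, tab$codon), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Per-codon pause scores between two conditions
#'
#' Pipeline convenience: builds and normalizes coverage for both conditions,
#' computes the codon metagene for each requested codon in each condition,
#' and returns the ranked deprived-minus-rich pause-score table.
#'
#' @param aln_deprived,aln_rich Alignment tables (`transcript_id`, `start`,
#'   `end`) for the two conditions.
#' @param cds CDS set `data.frame`.
#' @param codons Codons to score (default all 61 sense codons).
#' @param half_window,edge_exclude,pause_span See [metagene_around_codon()]
#'   and [delta_density()].
#' @param min_footprints,min_mean Track filters, see [coverage_tracks()].
#' @return `data.frame` from [pause_rank_table()].
#' @export
codon_pause_scores <- function(aln_deprived, aln_rich, cds,
                               codons = sense_codons(),
                               half_window = 150, edge_exclude = 20,
                               pause_span = c(-15, 17),
                               min_footprints = 100, min_mean = 0.5) {
  tr_dep <- coverage_tracks(aln_deprived, cds, min_footprints, min_mean)
  tr_rich <- coverage_tracks(aln_rich, cds, min_footprints, min_mean)
  deltas <- lapply(codons, function(cdn) {
    mg_dep <- metagene_around_codon(tr_dep, cds, cdn, half_window, edge_exclude)
    mg_rich <- metagene_around_codon(tr_rich, cds, cdn, half_window, edge_exclude)
    delta_density(mg_dep, mg_rich, pause_span)
  })
  pause_rank_table(deltas)
}

#' Naive differential translation efficiency
#'
#' A deliberately simple, clearly-labelled double-ratio TE contrast (it is
#' not a statistical model): per condition,
#' `TE(g) = ((rpf_g + pc) / sum(rpf + pc)) / ((rna_g + pc) / sum(rna + pc))`,
#' and `delta_log2_te = log2(TE_deprived / TE_rich)`.
#'
#' @param rpf_rich,rpf_deprived,rna_rich,rna_deprived Non-negative count
#'   vectors named by gene, over identical gene sets.
#' @param pseudocount Added to every count (default 0.5) so zero counts stay
#'   finite.
#' @return `data.frame` with `gene_id`, `te_rich`, `te_deprived`,
#'   `delta_log2_te`; attribute `method = "naive_double_ratio"`.
#' @export
differential_te <- function(rpf_rich, rpf_deprived, rna_rich, rna_deprived,
                            pseudocount = 0.5) {
  genes <- names(rpf_rich)
  vecs <- list(rpf_rich = rpf_rich, rpf_deprived = rpf_deprived,
               rna_rich = rna_rich, rna_deprived = rna_deprived)
  if (is.null(genes)) {
    stop("count vectors must be named by gene", call. = FALSE)
  }
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (is.null(names(v)) || !setequal(names(v), genes)) {
      stop("gene sets differ between count vectors (", nm, ")", call. = FALSE)
    }
    if (any(v < 0)) {
      stop("negative counts in ", nm, call. = FALSE)
    }
    vecs[[nm]] <- v[genes]
  }
  te <- function(rpf, rna) {
    ((rpf + pseudocount) / sum(rpf + pseudocount)) /
      ((rna + pseudocount) / sum(rna + pseudocount))
  }
  te_rich <- te(vecs$rpf_rich, vecs$rna_rich)
  te_dep <- te(vecs$rpf_deprived, vecs$rna_deprived)
  out <- data.frame(
    gene_id = genes,
    te_rich = as.numeric(te_rich),
    te_deprived = as.numeric(te_dep),
    delta_log2_te = as.numeric(log2(te_dep / te_rich)),
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- "naive_double_ratio"
  out
}
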