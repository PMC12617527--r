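# Independent oracles and small fixture builders shared across tests.
# Every oracle is a deliberately naive re-derivation (explicit loops,
# direct slicing) kept separate from the implementation paths it checks.

# Brute-force double loop over transcripts and occurrences: the reference
# for the codon metagene. No edge-exclusion logic beyond the same rule.
oracle_metagene <- function(tracks, cds, codon, half_window = 150, edge_exclude = 20) {
  positions <- seq.int(-half_window, half_window + 2L)
  dsum <- numeric(length(positions))
  cnt <- integer(length(positions))
  for (k in seq_len(nrow(cds))) {
    tx <- cds$transcript_id[k]
    if (is.null(tracks[[tx]])) next
    vals <- tracks[[tx]]$values
    seqc <- cds$sequence[k]
    n <- nchar(seqc) / 3
    for (i in seq_len(n)) {
      if (substr(seqc, 3 * i - 2, 3 * i) != codon) next
      if (i <= edge_exclude || i > n - edge_exclude) next
      for (j in seq_along(positions)) {
        p <- 3 * (i - 1) + positions[j]
        if (p >= 0 && p < nchar(seqc)) {
          dsum[j] <- dsum[j] + vals[p + 1]
          cnt[j] <- cnt[j] + 1L
        }
      }
    }
  }
  list(density = ifelse(cnt > 0, dsum / pmax(cnt, 1L), NA_real_), n = cnt)
}

# Regex-free triplet scan counting serine codons one window at a time.
oracle_ser_total <- function(sequence) {
  sequence <- toupper(sequence)
  ser <- c("TCC", "TCT", "AGT", "AGC", "TCG", "TCA")
  n <- 0L
  for (i in seq(1, nchar(sequence), by = 3)) {
    if (substr(sequence, i, i + 2) %in% ser) n <- n + 1L
  }
  n
}

# Pearson product-moment correlation applied to ranks, written out from the
# definition (no stats::cor).
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- sum(rx) / length(rx)
  my <- sum(ry) / length(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Linear step-up (BH) adjusted p-values by explicit loop.
oracle_bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, ps[i] * m / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Two-stage step-up adjusted p-values: stage-one step-up at a/(1+a)
# estimates the null count (floored at 1), stage two rescales the step-up
# values.
oracle_bh_two_stage <- function(p, alpha = 0.05) {
  m <- length(p)
  adj1 <- oracle_bh_stepup(p)
  r1 <- sum(adj1 <= alpha / (1 + alpha))
  m0 <- max(m - r1, 1)
  pmin(1, adj1 * m0 / m)
}

# Small deterministic CDS set for coverage/metagene tests.
make_test_cds <- function(n = 3, n_codons = 40, seed = 11) {
  set.seed(seed)
  classes <- unlist(ser_codon_classes())
  non_ser <- setdiff(sense_codons(), classes)
  rows <- lapply(seq_len(n), function(i) {
    interior <- sample(c(classes, non_ser), n_codons - 2, replace = TRUE)
    data.frame(
      gene_id = paste0("g", i),
      transcript_id = paste0("t", i),
      sequence = paste0("ATG", paste(interior, collapse = ""), "TAA"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Random alignments uniform over a CDS.
make_test_alignments <- function(cds, reads_per_tx = 300, read_len = 30, seed = 12) {
  set.seed(seed)
  out <- lapply(seq_len(nrow(cds)), function(i) {
    L <- nchar(cds$sequence[i])
    start <- sample.int(L - read_len + 1, reads_per_tx, replace = TRUE) - 1L
    data.frame(transcript_id = cds$transcript_id[i], start = start,
               end = start + read_len, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
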