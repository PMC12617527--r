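test_that("coverage counts overlapping footprints per position", {
  one <- coverage_from_alignments(data.frame(start = 0, end = 30), 100)
  expect_equal(one$values, c(rep(1, 30), rep(0, 70)))
  none <- coverage_from_alignments(data.frame(start = integer(0), end = integer(0)), 50)
  expect_equal(none$values, rep(0, 50))
  two <- coverage_from_alignments(data.frame(start = c(0, 15), end = c(30, 45)), 100)
  expect_equal(two$values[16:30], rep(2, 15))
  expect_equal(two$values[1:15], rep(1, 15))
  expect_equal(two$values[31:45], rep(1, 15))
  expect_error(coverage_from_alignments(data.frame(start = 90, end = 120), 100),
               "out-of-bounds")
})

test_that("normalization divides by the mean, filters weak tracks, and refuses re-normalization", {
  const <- coverage_from_alignments(data.frame(start = 0, end = 10), 10)
  const$values <- rep(5, 10)
  norm <- normalize_track(const)
  expect_equal(norm$values, rep(1, 10))
  expect_equal(mean(norm$values), 1, tolerance = 1e-9)
  expect_error(normalize_track(norm), "already normalized")

  tr <- coverage_from_alignments(data.frame(start = 0, end = 1), 2)
  tr$values <- c(0, 2)
  expect_equal(normalize_track(tr)$values, c(0, 2))

  zero <- coverage_from_alignments(data.frame(start = integer(0), end = integer(0)), 10)
  expect_equal(normalize_track(zero)$status, "filtered")
  weak <- coverage_from_alignments(data.frame(start = 0, end = 3), 100)
  expect_equal(normalize_track(weak, min_mean = 0.5)$status, "filtered")
})

test_that("metagene equals the brute-force double loop exactly on small instances", {
  cds <- make_test_cds(n = 5, n_codons = 45, seed = 21)
  aln <- make_test_alignments(cds, reads_per_tx = 200, seed = 22)
  tracks <- coverage_tracks(aln, cds, min_footprints = 50, min_mean = 0.1)
  for (codon in c("TCC", "AGT", "GCA")) {
    mg <- metagene_around_codon(tracks, cds, codon, half_window = 40, edge_exclude = 3)
    oracle <- oracle_metagene(tracks, cds, codon, half_window = 40, edge_exclude = 3)
    expect_identical(mg$n_occurrences, oracle$n)
    expect_equal(mg$density, oracle$density, tolerance = 1e-12)
  }
})

test_that("metagene over uniform tracks is 1 everywhere and validates its inputs", {
  cds <- make_test_cds(n = 2, n_codons = 60, seed = 31)
  tracks <- lapply(seq_len(nrow(cds)), function(i) {
    tr <- coverage_from_alignments(data.frame(start = integer(0), end = integer(0)),
                                   nchar(cds$sequence[i]),
                                   transcript_id = cds$transcript_id[i])
    tr$values <- rep(2, nchar(cds$sequence[i]))
    normalize_track(tr)
  })
  names(tracks) <- cds$transcript_id
  mg <- metagene_around_codon(tracks, cds, "TCC", half_window = 30, edge_exclude = 2)
  covered <- mg$n_occurrences > 0
  expect_true(any(covered))
  expect_equal(mg$density[covered], rep(1, sum(covered)))
  expect_equal(length(mg$positions), 2 * 30 + 3)

  expect_error(metagene_around_codon(tracks, cds, "NNN"), "triplet")
  expect_error(metagene_around_codon(tracks, cds, "TCC", half_window = 0), ">= 1")
  raw <- tracks
  raw[[1]]$normalized <- FALSE
  expect_error(metagene_around_codon(raw, cds, "TCC"), "normalized")
})

test_that("single-occurrence metagene is the track re-indexed at the occurrence", {
  # one transcript with exactly one TGG, arbitrary normalized coverage
  seqc <- paste0("ATG", strrep("GCA", 10), "TGG", strrep("CTT", 10), "TAA")
  cds <- data.frame(gene_id = "g", transcript_id = "t", sequence = seqc,
                    stringsAsFactors = FALSE)
  L <- nchar(seqc)
  set.seed(9)
  tr <- coverage_from_alignments(data.frame(start = integer(0), end = integer(0)), L,
                                 transcript_id = "t")
  tr$values <- stats::runif(L, 0.5, 2)
  tr <- normalize_track(tr)
  tracks <- list(t = tr)
  W <- 12
  mg <- metagene_around_codon(tracks, cds, "TGG", half_window = W, edge_exclude = 2)
  q <- 3 * (12 - 1)  # 0-based first nt of the single occurrence (codon 12)
  expected <- tr$values[q + (-W:(W + 2)) + 1]
  expect_equal(mg$density, expected, tolerance = 1e-12)
  expect_equal(mg$n_occurrences_total, 1L)
})

test_that("delta density subtracts positionwise, is antisymmetric, and validates pairs", {
  cds <- make_test_cds(n = 3, n_codons = 45, seed = 51)
  aln <- make_test_alignments(cds, reads_per_tx = 150, seed = 52)
  tracks <- coverage_tracks(aln, cds, min_footprints = 50, min_mean = 0.1)
  mg <- metagene_around_codon(tracks, cds, "TCC", half_window = 30, edge_exclude = 3)

  same <- delta_density(mg, mg)
  expect_equal(same$delta[!is.na(same$delta)],
               rep(0, sum(!is.na(same$delta))))
  expect_equal(same$pause_score, 0)

  shifted <- mg
  shifted$density <- mg$density + 0.5
  d <- delta_density(shifted, mg)
  expect_equal(d$delta[!is.na(d$delta)], rep(0.5, sum(!is.na(d$delta))))
  expect_equal(d$pause_score, 0.5)

  ab <- delta_density(shifted, mg)
  ba <- delta_density(mg, shifted)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$pause_score, -ba$pause_score)

  other <- metagene_around_codon(tracks, cds, "AGT", half_window = 30, edge_exclude = 3)
  expect_error(delta_density(mg, other), "codon mismatch")
  wide <- metagene_around_codon(tracks, cds, "TCC", half_window = 20, edge_exclude = 3)
  expect_error(delta_density(mg, wide), "window mismatch")
})

test_that("pause ranking sorts descending with alphabetical tie-break", {
  mk <- function(codon, score) {
    structure(list(codon = codon, positions = 0L, delta = score,
                   pause_score = score, pause_span = c(0, 0)),
              class = "delta_density")
  }
  tab <- pause_rank_table(list(mk("AGT", 0.1), mk("TCC", 0.4)))
  expect_equal(tab$codon, c("TCC", "AGT"))
  zeros <- pause_rank_table(list(mk("TGG", 0), mk("AAA", 0), mk("CCC", 0)))
  expect_equal(zeros$codon, c("AAA", "CCC", "TGG"))
  tie <- pause_rank_table(list(mk("TTT", 0.2), mk("GGG", 0.2), mk("AAA", 0.9)))
  expect_equal(tie$codon, c("AAA", "GGG", "TTT"))
  expect_error(pause_rank_table(list()), "empty")
})

test_that("naive differential TE matches the hand-evaluated double ratio", {
  genes <- sprintf("g%03d", 1:100)
  base <- stats::setNames(rep(100, 100), genes)
  zero <- differential_te(base, base, base, base)
  expect_equal(zero$delta_log2_te, rep(0, 100))

  rpf_dep <- base
  rpf_dep["g001"] <- 200
  te <- differential_te(base, rpf_dep, base, base, pseudocount = 0.5)
  # spreadsheet-style oracle on the 100-gene table
  pc <- 0.5
  te_dep_g1 <- ((200 + pc) / (99 * (100 + pc) + 200 + pc)) / ((100 + pc) / (100 * (100 + pc)))
  te_rich_g1 <- 1
  expect_equal(te$delta_log2_te[te$gene_id == "g001"], log2(te_dep_g1 / te_rich_g1))

  zeros <- stats::setNames(rep(0, 3), c("a", "b", "c"))
  out <- differential_te(zeros, zeros, zeros, zeros, pseudocount = 0.5)
  expect_true(all(is.finite(out$delta_log2_te)))

  expect_error(differential_te(base, base[-1], base, base), "gene sets differ")
})

test_that("uniform dwell simulation flattens toward density 1 as depth grows", {
  flat <- list(rich = c("UC[C/U]" = 1, "AG[U/C]" = 1, "UC[G/A]" = 1, other = 1))
  interior_dev <- function(depth) {
    cfg <- sim_config(seed = 99, n_genes = 12, cds_length_range = c(100L, 120L),
                      dwell_multipliers = flat, reads_per_transcript = depth)
    tx <- gen_transcriptome(cfg)
    fp <- simulate_footprints(tx$cds, cfg)
    tracks <- coverage_tracks(fp$rich, tx$cds, min_footprints = 50, min_mean = 0.1)
    devs <- vapply(tracks, function(tr) {
      n <- length(tr$values)
      interior <- seq(31, n - 30)   # away from ramp caused by end truncation
      max(abs(tr$values[interior] - 1))
    }, numeric(1))
    mean(devs)
  }
  shallow <- interior_dev(500)
  deep <- interior_dev(8000)
  expect_lt(deep, shallow)
  expect_lt(deep, 0.25)
})

test_that("dwell-multiplier recovery: at-codon density ratio approaches k x background", {
  cfg <- sim_config(seed = 7, n_genes = 40, cds_length_range = c(150L, 250L),
                    reads_per_transcript = 2000L)
  tx <- gen_transcriptome(cfg)
  fp <- simulate_footprints(tx$cds, cfg)
  a_site_counts <- function(aln, cds) {
    counts <- list()
    for (tx_id in unique(aln$transcript_id)) {
      sub <- aln[aln$transcript_id == tx_id & aln$start > 0, ]
      idx <- (sub$start + cfg$a_site_offset) / 3 + 1
      counts[[tx_id]] <- idx
    }
    counts
  }
  ratio_for <- function(class_codons) {
    dep <- a_site_counts(fp$deprived, tx$cds)
    rich <- a_site_counts(fp$rich, tx$cds)
    tot_dep <- 0; tot_rich <- 0; bg_dep <- 0; bg_rich <- 0
    for (i in seq_len(nrow(tx$cds))) {
      codons <- enumerate_codons(tx$cds$sequence[i])
      tgt <- which(codons %in% class_codons)
      tx_id <- tx$cds$transcript_id[i]
      tot_dep <- tot_dep + sum(dep[[tx_id]] %in% tgt)
      tot_rich <- tot_rich + sum(rich[[tx_id]] %in% tgt)
      bg <- which(!(codons %in% unlist(ser_codon_classes())))
      bg_dep <- bg_dep + sum(dep[[tx_id]] %in% bg)
      bg_rich <- bg_rich + sum(rich[[tx_id]] %in% bg)
    }
    (tot_dep / tot_rich) / (bg_dep / bg_rich)
  }
  r <- ratio_for(c("TCC", "TCT"))
  expect_gt(r, 4 * 0.85)
  expect_lt(r, 4 * 1.15)
})
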