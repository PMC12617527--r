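# Seeded generators for every input the pipeline consumes, with recorded
# ground truth for recovery tests: transcriptomes with controlled serine
# codon composition, footprints with codon-class dwell multipliers, tRNA-seq
# counts with known charging, SILAC fold changes coupled to composition.

#' Simulation configuration
#'
#' One config object drives every generator; a fixed `seed` makes each
#' generator a pure function of its config. Defaults encode the simulated
#' study conditions exercised throughout the package: 200 genes, 10% serine
#' codons, equal class mix with between-gene Dirichlet spread, a 4x dwell
#' multiplier on UC\[C/U\] in the deprived condition only, 2000 footprints
#' of 30 nt per transcript (A site 15 nt from the 5' end), tRNA-seq depth
#' 1000 reads per isodecoder, and a SILAC coupling of -1 log2 units per
#' 100% UC\[C/U\] with Gaussian noise sd 0.3.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param cds_length_range Length-2 integer range of CDS lengths in codons
#'   (including start and stop).
#' @param ser_density Probability an interior codon is a serine codon.
#' @param class_mix Length-3 probability vector over the classes
#'   UC\[C/U\], AG\[U/C\], UC\[G/A\] (mean class usage across genes).
#' @param class_mix_spread Dirichlet concentration controlling between-gene
#'   variability of class usage around `class_mix`; `Inf` means every gene
#'   uses `class_mix` exactly (homogeneous multinomial sampling). The
#'   default (1.5) spreads genes across the whole 0-100% range, as real
#'   transcriptomes do.
#' @param dwell_multipliers Named list, condition -> named numeric vector
#'   of relative ribosome dwell times for the three classes plus `other`.
#' @param reads_per_transcript Footprints per transcript and condition.
#' @param read_length Footprint length (nt).
#' @param a_site_offset A-site position within the footprint, nt from the
#'   5' end.
#' @param trna_truth `data.frame` with columns `isodecoder_id`,
#'   `condition`, `level` (relative abundance), `charging` (fraction in
#'   \[0,1\]), `pre_frac` (fraction of reads from pre-tRNA).
#' @param trna_depth Mean mature+pre reads per isodecoder at `level = 1`.
#' @param trna_dispersion Negative-binomial size for overdispersed
#'   per-isodecoder totals; `NULL` (default) uses Poisson.
#' @param silac_beta Named numeric: log2 fold-change effect per 100% of
#'   each class.
#' @param silac_sigma Gaussian noise sd on the SILAC log2 fold change.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       cds_length_range = c(120L, 300L),
                       ser_density = 0.1,
                       class_mix = c("UC[C/U]" = 1 / 3, "AG[U/C]" = 1 / 3, "UC[G/A]" = 1 / 3),
                       class_mix_spread = 1.5,
                       dwell_multipliers = list(
                         rich = c("UC[C/U]" = 1, "AG[U/C]" = 1, "UC[G/A]" = 1, other = 1),
                         deprived = c("UC[C/U]" = 4, "AG[U/C]" = 1, "UC[G/A]" = 1, other = 1)
                       ),
                       reads_per_transcript = 2000L,
                       read_length = 30L,
                       a_site_offset = 15L,
                       trna_truth = default_trna_truth(),
                       trna_depth = 1000L,
                       trna_dispersion = NULL,
                       silac_beta = c("UC[C/U]" = -1, "AG[U/C]" = 0, "UC[G/A]" = 0),
                       silac_sigma = 0.3) {
  class_labels <- names(ser_codon_classes())
  stopifnot(length(cds_length_range) == 2L, cds_length_range[1] >= 3L,
            cds_length_range[1] <= cds_length_range[2])
  if (ser_density < 0 || ser_density > 1) {
    stop("ser_density must be in [0, 1]", call. = FALSE)
  }
  if (length(class_mix) != 3L || abs(sum(class_mix) - 1) > 1e-9 || any(class_mix < 0)) {
    stop("class_mix must be a 3-simplex (non-negative, summing to 1)", call. = FALSE)
  }
  names(class_mix) <- class_labels
  for (cond in names(dwell_multipliers)) {
    m <- dwell_multipliers[[cond]]
    if (!all(c(class_labels, "other") %in% names(m)) || any(m <= 0)) {
      stop("dwell_multipliers[['", cond, "']] needs positive entries for ",
           "the three classes and 'other'", call. = FALSE)
    }
  }
  if (ser_density > 0 && cds_length_range[1] < 3L) {
    stop("CDS too short to hold a serine codon", call. = FALSE)
  }
  stopifnot(is.data.frame(trna_truth),
            all(c("isodecoder_id", "condition", "level", "charging", "pre_frac")
                %in% names(trna_truth)))
  if (any(trna_truth$charging < 0 | trna_truth$charging > 1) ||
      any(trna_truth$pre_frac < 0 | trna_truth$pre_frac > 1)) {
    stop("trna_truth fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!all(names(ser_codon_classes()) %in% names(silac_beta))) {
    stop("silac_beta must name all three serine codon classes", call. = FALSE)
  }
  if (silac_sigma < 0) {
    stop("silac_sigma must be >= 0", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      n_genes = as.integer(n_genes),
      cds_length_range = as.integer(cds_length_range),
      ser_density = ser_density,
      class_mix = class_mix,
      class_mix_spread = class_mix_spread,
      dwell_multipliers = dwell_multipliers,
      reads_per_transcript = as.integer(reads_per_transcript),
      read_length = as.integer(read_length),
      a_site_offset = as.integer(a_site_offset),
      trna_truth = trna_truth,
      trna_depth = as.integer(trna_depth),
      trna_dispersion = trna_dispersion,
      silac_beta = silac_beta,
      silac_sigma = silac_sigma
    ),
    class = "sim_config"
  )
}

#' Default tRNA-seq simulation truth
#'
#' Serine isodecoder panel with relative levels, charging fractions, and
#' pre-tRNA read fractions for a rich and a deprived condition: charging is
#' high when serine is plentiful and drops under deprivation, pre-tRNA is a
#' small constant fraction.
#'
#' @return `data.frame` usable as `trna_truth` in [sim_config()].
#' @export
default_trna_truth <- function() {
  iso <- c("Ser-AGA-1" = 1.2, "Ser-AGA-2" = 0.8, "Ser-CGA-1" = 0.7,
           "Ser-UGA-1" = 0.9, "Ser-GCU-1" = 1.0, "Ser-GCU-2" = 0.6)
  rbind(
    data.frame(isodecoder_id = names(iso), condition = "rich",
               level = unname(iso), charging = 0.9, pre_frac = 0.05,
               stringsAsFactors = FALSE),
    data.frame(isodecoder_id = names(iso), condition = "deprived",
               level = unname(iso), charging = 0.4, pre_frac = 0.05,
               stringsAsFactors = FALSE)
  )
}

# Dirichlet draw via independent gammas; alpha entries of 0 give exact 0s.
rdirichlet1 <- function(alpha) {
  g <- vapply(alpha, function(a) if (a > 0) stats::rgamma(1, shape = a) else 0, numeric(1))
  if (sum(g) == 0) return(alpha / sum(alpha))
  g / sum(g)
}

#' Generate a synthetic transcriptome with controlled serine composition
#'
#' Each CDS starts with ATG, ends with a single stop codon, and has interior
#' codons that are serine with probability `ser_density`; serine codons are
#' drawn from the gene's class proportions (Dirichlet around `class_mix`,
#' see [sim_config()]) and then uniformly within the chosen class pair.
#' Non-serine interior codons are uniform over the 55 non-serine,
#' non-stop codons.
#'
#' @param cfg A [sim_config()].
#' @return List with `cds` (CDS set `data.frame`: `gene_id`,
#'   `transcript_id`, `sequence`) and `truth` (per-gene realized class
#'   counts and percentages plus the latent per-gene class proportions
#'   `p_ucc_ucu`, `p_agu_agc`, `p_ucg_uca`).
#' @export
gen_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 101L)
  classes <- ser_codon_classes()
  class_labels <- names(classes)
  stops <- c("TAA", "TAG", "TGA")
  non_ser <- setdiff(sense_codons(), unlist(classes))
  cds_rows <- vector("list", cfg$n_genes)
  truth_rows <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    rng <- cfg$cds_length_range
    n_codons <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    n_interior <- n_codons - 2L
    if (cfg$ser_density > 0 && n_interior < 1L) {
      stop("CDS of ", n_codons, " codons cannot hold a serine codon", call. = FALSE)
    }
    p_gene <- if (is.finite(cfg$class_mix_spread)) {
      rdirichlet1(cfg$class_mix_spread * cfg$class_mix)
    } else {
      cfg$class_mix
    }
    is_ser <- stats::runif(n_interior) < cfg$ser_density
    codons <- character(n_interior)
    n_ser <- sum(is_ser)
    if (n_ser > 0L) {
      cls <- sample(class_labels, n_ser, replace = TRUE, prob = p_gene)
      codons[is_ser] <- vapply(cls, function(cl) sample(classes[[cl]], 1L), character(1))
    }
    if (n_ser < n_interior) {
      codons[!is_ser] <- sample(non_ser, n_interior - n_ser, replace = TRUE)
    }
    gene_id <- sprintf("G%04d", g)
    cds_rows[[g]] <- data.frame(
      gene_id = gene_id,
      transcript_id = sprintf("T%04d.1", g),
      sequence = paste0("ATG", paste(codons, collapse = ""), sample(stops, 1L)),
      stringsAsFactors = FALSE
    )
    truth_rows[[g]] <- data.frame(
      gene_id = gene_id,
      p_ucc_ucu = p_gene[1], p_agu_agc = p_gene[2], p_ucg_uca = p_gene[3],
      stringsAsFactors = FALSE
    )
  }
  cds <- do.call(rbind, cds_rows)
  truth <- do.call(rbind, truth_rows)
  realized <- ser_codon_profile(cds, longest_only = FALSE)
  truth <- merge(truth,
                 realized[, c("gene_id", "n_ucc_ucu", "n_agu_agc", "n_ucg_uca",
                              "n_ser_total", "pct_ucc_ucu", "pct_agu_agc",
                              "pct_ucg_uca", "defined")],
                 by = "gene_id", sort = TRUE)
  list(cds = cds, truth = truth)
}

#' Simulate ribosome footprints with codon-class dwell multipliers
#'
#' For each transcript and condition, `reads_per_transcript` footprints are
#' placed by drawing the A-site codon with probability proportional to the
#' dwell multiplier of its serine class (or `other`), then laying a
#' `read_length`-nt read with the A site `a_site_offset` nt from its 5'
#' end, truncated at the CDS bounds. A-site-weighted sampling is a
#' deliberate simplification of elongation: it creates exactly the local
#' coverage enrichment the codon metagene measures.
#'
#' @param cds CDS set `data.frame` (e.g. from [gen_transcriptome()]).
#' @param cfg A [sim_config()].
#' @return Named list (one per condition in `cfg$dwell_multipliers`) of
#'   alignment `data.frame`s (`transcript_id`, `start`, `end`), plus an
#'   attribute `truth` recording the dwell multipliers used.
#' @export
simulate_footprints <- function(cds, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$read_length > min(nchar(cds$sequence))) {
    stop("read_length exceeds the shortest CDS", call. = FALSE)
  }
  set.seed(cfg$seed + 202L)
  classes <- ser_codon_classes()
  codon_class <- stats::setNames(rep("other", 64L),
                                 as.vector(outer(outer(c("A", "C", "G", "T"),
                                                       c("A", "C", "G", "T"), paste0),
                                                 c("A", "C", "G", "T"), paste0)))
  for (cl in names(classes)) codon_class[classes[[cl]]] <- cl
  out <- list()
  for (cond in names(cfg$dwell_multipliers)) {
    mult <- cfg$dwell_multipliers[[cond]]
    per_tx <- vector("list", nrow(cds))
    for (i in seq_len(nrow(cds))) {
      codons <- enumerate_codons(cds$sequence[i])
      L <- 3L * length(codons)
      w <- unname(mult[codon_class[codons]])
      a_idx <- sample.int(length(codons), cfg$reads_per_transcript,
                          replace = TRUE, prob = w)
      start <- pmax(0L, 3L * (a_idx - 1L) - cfg$a_site_offset)
      end <- pmin(L, start + cfg$read_length)
      start <- pmax(0L, pmin(start, end - 1L))
      per_tx[[i]] <- data.frame(
        transcript_id = cds$transcript_id[i],
        start = as.integer(start),
        end = as.integer(end),
        stringsAsFactors = FALSE
      )
    }
    out[[cond]] <- do.call(rbind, per_tx)
  }
  attr(out, "truth") <- cfg$dwell_multipliers
  out
}

#' Simulate charged tRNA-seq count tables
#'
#' Per isodecoder and condition, a total read count is drawn (Poisson with
#' mean `trna_depth * level`, or negative binomial when `trna_dispersion`
#' is set) and split multinomially into pre-tRNA reads (`pre_frac`) and
#' mature reads, the latter divided into ...CCA (charged) and ...CC
#' (uncharged) ends by the true charging fraction.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (`data.frame`: `isodecoder_id`, `condition`,
#'   `n_cca`, `n_cc`, `n_pre`, `library_size`) and `truth`
#'   (`cfg$trna_truth`).
#' @export
simulate_trna_seq <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 303L)
  tt <- cfg$trna_truth
  n <- nrow(tt)
  totals <- integer(n)
  for (i in seq_len(n)) {
    mu <- cfg$trna_depth * tt$level[i]
    totals[i] <- if (is.null(cfg$trna_dispersion)) {
      stats::rpois(1L, mu)
    } else {
      stats::rnbinom(1L, size = cfg$trna_dispersion, mu = mu)
    }
  }
  n_cca <- integer(n)
  n_cc <- integer(n)
  n_pre <- integer(n)
  for (i in seq_len(n)) {
    if (totals[i] == 0L) next
    probs <- c(
      pre = tt$pre_frac[i],
      cca = (1 - tt$pre_frac[i]) * tt$charging[i],
      cc = (1 - tt$pre_frac[i]) * (1 - tt$charging[i])
    )
    draw <- stats::rmultinom(1L, totals[i], probs)[, 1]
    n_pre[i] <- draw[["pre"]]
    n_cca[i] <- draw[["cca"]]
    n_cc[i] <- draw[["cc"]]
  }
  counts <- data.frame(
    isodecoder_id = tt$isodecoder_id,
    condition = tt$condition,
    n_cca = n_cca,
    n_cc = n_cc,
    n_pre = n_pre,
    stringsAsFactors = FALSE
  )
  lib <- stats::aggregate(totals, by = list(condition = tt$condition), FUN = sum)
  counts$library_size <- lib$x[match(counts$condition, lib$condition)]
  list(counts = counts, truth = tt)
}

#' Simulate SILAC newly-synthesized-protein fold changes
#'
#' Couples the log2 fold change of each gene's newly synthesized protein to
#' its serine codon class percentages:
#' `log2_fc = sum_class beta_class * pct_class / 100 + eps`,
#' `eps ~ N(0, silac_sigma^2)`. Genes without a defined profile (no serine
#' codons) are omitted. Heavy-channel intensities consistent with the fold
#' change are emitted so the table round-trips through
#' [silac_fold_change()].
#'
#' @param truth_profiles `data.frame` with `gene_id`, `pct_ucc_ucu`,
#'   `pct_agu_agc`, `pct_ucg_uca`, `defined` (e.g. the `truth` of
#'   [gen_transcriptome()] or a [ser_codon_profile()]).
#' @param cfg A [sim_config()].
#' @return `data.frame` with `gene_id`, `heavy_a`, `heavy_b`, `log2_fc`;
#'   attribute `truth` holds `silac_beta` and `silac_sigma`.
#' @export
simulate_silac <- function(truth_profiles, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  need <- c("gene_id", "pct_ucc_ucu", "pct_agu_agc", "pct_ucg_uca", "defined")
  stopifnot(all(need %in% names(truth_profiles)))
  set.seed(cfg$seed + 404L)
  prof <- truth_profiles[truth_profiles$defined, , drop = FALSE]
  beta <- cfg$silac_beta
  fc <- beta[["UC[C/U]"]] * prof$pct_ucc_ucu / 100 +
    beta[["AG[U/C]"]] * prof$pct_agu_agc / 100 +
    beta[["UC[G/A]"]] * prof$pct_ucg_uca / 100
  if (cfg$silac_sigma > 0) {
    fc <- fc + stats::rnorm(nrow(prof), 0, cfg$silac_sigma)
  }
  heavy_b <- exp(stats::rnorm(nrow(prof), log(1e6), 0.5))
  out <- data.frame(
    gene_id = prof$gene_id,
    heavy_a = heavy_b * 2^fc,
    heavy_b = heavy_b,
    log2_fc = as.numeric(fc),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "truth") <- list(silac_beta = beta, silac_sigma = cfg$silac_sigma)
  out
}
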