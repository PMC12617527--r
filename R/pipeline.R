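# Pipeline driver: one configuration object, named stages, deterministic
# TSV outputs plus a parameter/filter-count log.

#' Pipeline configuration
#'
#' Collects every tunable the staged pipeline uses. Unknown keys are
#' rejected. All defaults are recorded in the run log.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed forwarded to the simulation config.
#' @param sim Named list of [sim_config()] overrides (e.g.
#'   `list(n_genes = 50)`).
#' @param codons Codons scored by the ribosome-density stage (default all
#'   61 sense codons).
#' @param half_window,edge_exclude,pause_span Metagene parameters, see
#'   [metagene_around_codon()] and [delta_density()].
#' @param min_footprints,min_mean Coverage-track filters, see
#'   [coverage_tracks()].
#' @param pseudocount Pseudocount for [differential_te()].
#' @param bin_on Class percentage driving bins/correlation, see
#'   [ser_codon_profile()].
#' @param trend_exclude Bin labels excluded from the quadratic trend fit.
#' @param beta_tables Optional named list of two TSV paths (columns `gene`,
#'   `beta`) enabling the screen-reporter stage.
#' @param beta_threshold Selection threshold for [beta_diff_rank()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            sim = list(),
                            codons = sense_codons(),
                            half_window = 150L,
                            edge_exclude = 20L,
                            pause_span = c(-15L, 17L),
                            min_footprints = 100L,
                            min_mean = 0.5,
                            pseudocount = 0.5,
                            bin_on = "pct_ucc_ucu",
                            trend_exclude = "91-100",
                            beta_tables = NULL,
                            beta_threshold = 0.25) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim, codons = codons,
         half_window = half_window, edge_exclude = edge_exclude,
         pause_span = pause_span, min_footprints = min_footprints,
         min_mean = min_mean, pseudocount = pseudocount, bin_on = bin_on,
         trend_exclude = trend_exclude, beta_tables = beta_tables,
         beta_threshold = beta_threshold),
    class = "pipeline_config"
  )
}

pipeline_paths <- function(config) {
  d <- config$out_dir
  list(
    cds = file.path(d, "cds.fa"),
    truth = file.path(d, "transcriptome_truth.tsv"),
    aln_rich = file.path(d, "alignments_rich.tsv"),
    aln_deprived = file.path(d, "alignments_deprived.tsv"),
    trna = file.path(d, "trna_counts.tsv"),
    silac = file.path(d, "silac.tsv"),
    profile = file.path(d, "ser_codon_profile.tsv"),
    pause = file.path(d, "pause_scores.tsv"),
    charging = file.path(d, "charging_table.tsv"),
    bins = file.path(d, "bin_summary.tsv"),
    corr = file.path(d, "correlation.tsv"),
    trend = file.path(d, "trend_coefficients.tsv"),
    beta = file.path(d, "beta_diff.tsv"),
    log = file.path(d, "run_log.txt")
  )
}

log_line <- function(con, ...) writeLines(paste0(...), con)

#' Run the staged pipeline
#'
#' Stages: `"simulate"` writes a seeded synthetic dataset (CDS FASTA,
#' per-condition alignments, tRNA counts, SILAC table, truth);
#' `"codon-metrics"` the per-gene serine codon profile;
#' `"ribo-density"` the ranked deprived-vs-rich pause-score table;
#' `"trna-quant"` the charging table; `"proteome-link"` bin summaries,
#' binned/individual correlations, and trend coefficients;
#' `"screen-reporter"` (requires `beta_tables`) the beta-difference
#' ranking. `"all"` runs every stage with available inputs. Identical
#' config and inputs produce identical outputs; every run appends its
#' parameters and filter counts to `run_log.txt`.
#'
#' @param config A [pipeline_config()].
#' @param step Stage name (see above).
#' @return Named list of paths to the files the invoked stage(s) wrote,
#'   invisibly.
#' @export
run_pipeline <- function(config,
                         step = c("all", "simulate", "codon-metrics", "ribo-density",
                                  "trna-quant", "proteome-link", "screen-reporter")) {
  stopifnot(inherits(config, "pipeline_config"))
  step <- match.arg(step)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_paths(config)
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  logcon <- file(paths$log, open = "at")
  on.exit(close(logcon))
  log_line(logcon, "run step=", step, " hash=", hash)
  for (key in setdiff(names(config), "out_dir")) {
    log_line(logcon, "  param ", key, " = ",
             paste(deparse(config[[key]]), collapse = " "))
  }
  written <- list()
  steps <- if (step == "all") {
    c("simulate", "codon-metrics", "ribo-density", "trna-quant", "proteome-link",
      if (!is.null(config$beta_tables)) "screen-reporter")
  } else {
    step
  }
  for (s in steps) {
    written <- c(written, switch(
      s,
      "simulate" = {
        cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
        tx <- gen_transcriptome(cfg)
        write_cds_fasta(tx$cds, paths$cds)
        write_tsv(tx$truth, paths$truth, schema = "transcriptome_truth", hash = hash)
        fp <- simulate_footprints(tx$cds, cfg)
        write_tsv(fp$rich, paths$aln_rich, schema = "alignments", hash = hash)
        write_tsv(fp$deprived, paths$aln_deprived, schema = "alignments", hash = hash)
        tr <- simulate_trna_seq(cfg)
        write_tsv(tr$counts, paths$trna, schema = "trna_counts", hash = hash)
        si <- simulate_silac(tx$truth, cfg)
        write_tsv(si, paths$silac, schema = "silac", hash = hash)
        log_line(logcon, "  simulate: ", nrow(tx$cds), " genes, ",
                 nrow(fp$rich), "+", nrow(fp$deprived), " footprints")
        paths[c("cds", "truth", "aln_rich", "aln_deprived", "trna", "silac")]
      },
      "codon-metrics" = {
        cds <- read_cds_fasta(paths$cds)
        prof <- ser_codon_profile(cds, bin_on = config$bin_on)
        write_tsv(prof, paths$profile, schema = "ser_codon_profile", hash = hash)
        log_line(logcon, "  codon-metrics: ", nrow(prof), " genes, ",
                 sum(!prof$defined), " without serine codons")
        paths["profile"]
      },
      "ribo-density" = {
        cds <- read_cds_fasta(paths$cds)
        aln_dep <- read_alignments_tsv(paths$aln_deprived)
        aln_rich <- read_alignments_tsv(paths$aln_rich)
        pause <- codon_pause_scores(
          aln_dep, aln_rich, cds, codons = config$codons,
          half_window = config$half_window, edge_exclude = config$edge_exclude,
          pause_span = config$pause_span,
          min_footprints = config$min_footprints, min_mean = config$min_mean
        )
        write_tsv(pause, paths$pause, schema = "pause_scores", hash = hash)
        log_line(logcon, "  ribo-density: ", nrow(pause), " codons scored")
        paths["pause"]
      },
      "trna-quant" = {
        counts <- read_trna_counts_tsv(paths$trna)
        ct <- charging_table(counts)
        write_tsv(ct, paths$charging, schema = "charging_table", hash = hash)
        log_line(logcon, "  trna-quant: ", nrow(ct), " isoacceptor x condition rows")
        paths["charging"]
      },
      "proteome-link" = {
        prof <- read_tsv(paths$profile,
                         required_cols = c("gene_id", config$bin_on, "defined"))
        silac <- read_tsv(paths$silac, required_cols = c("gene_id", "log2_fc"))
        prof <- prof[prof$defined, , drop = FALSE]
        fc <- stats::setNames(silac$log2_fc, silac$gene_id)
        pct <- stats::setNames(prof[[config$bin_on]], prof$gene_id)
        shared <- intersect(names(fc), names(pct))
        scheme <- ser_bin_scheme("fine")
        res <- binned_spearman(fc[shared], pct[shared], scheme = scheme)
        indiv <- spearman_r(pct[shared], fc[shared], basis = "individual")
        write_tsv(res$bin_summary, paths$bins, schema = "bin_summary", hash = hash)
        corr <- data.frame(basis = c("binned", "individual"),
                           r = c(res$r, indiv$r), n = c(res$n, indiv$n))
        write_tsv(corr, paths$corr, schema = "correlation", hash = hash)
        use <- res$bin_summary$n > 0L
        trend <- fit_trend(
          stats::setNames(bin_midpoints(scheme)[res$bin_summary$bin[use]],
                          res$bin_summary$bin[use]),
          res$bin_summary$mean_fc[use],
          exclude_bins = intersect(config$trend_exclude, res$bin_summary$bin[use])
        )
        write_tsv(
          data.frame(term = names(trend$coefficients),
                     estimate = as.numeric(trend$coefficients)),
          paths$trend, schema = "trend_coefficients", hash = hash
        )
        log_line(logcon, "  proteome-link: ", length(shared), " genes joined, ",
                 "binned r=", format(res$r, digits = 4))
        paths[c("bins", "corr", "trend")]
      },
      "screen-reporter" = {
        if (is.null(config$beta_tables) || length(config$beta_tables) != 2L) {
          stop("screen-reporter stage needs config$beta_tables = list of two TSV paths",
               call. = FALSE)
        }
        read_beta <- function(p) {
          df <- read_tsv(p, required_cols = c("gene", "beta"))
          stats::setNames(df$beta, df$gene)
        }
        tab <- beta_diff_rank(read_beta(config$beta_tables[[1]]),
                              read_beta(config$beta_tables[[2]]),
                              threshold = config$beta_threshold)
        write_tsv(tab, paths$beta, schema = "beta_diff", hash = hash)
        log_line(logcon, "  screen-reporter: ", nrow(tab), " shared genes, ",
                 sum(tab$selected), " selected, ", attr(tab, "n_dropped"), " dropped")
        paths["beta"]
      }
    ))
  }
  invisible(written)
}
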