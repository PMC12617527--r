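# Reporter-fluorescence correction arithmetic and CRISPR screen beta-score
# differencing/ranking (beta scores are consumed, never re-estimated).

#' Geometric mean
#'
#' `exp(mean(log(values)))` for strictly positive values, the summary used
#' for per-cell fluorescence intensities.
#'
#' @param values Positive numeric vector.
#' @return Geometric mean.
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0L) {
    stop("empty value vector", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("geometric mean requires finite values > 0", call. = FALSE)
  }
  exp(mean(log(values)))
}

#' Reporter measurement
#'
#' Per-cell dual-channel fluorescence for one sample: destabilized GFP
#' (GFPd2, the codon-usage reporter) and mCherry (the internal control).
#'
#' @param gfp_values,mcherry_values Positive per-cell intensities
#'   (zero/negative events are assumed filtered upstream).
#' @param condition One of `"rich"`, `"deprived"`, `"chx"`.
#' @param sample_id Optional label.
#' @return Object of class `reporter_measurement`.
#' @export
reporter_measurement <- function(gfp_values, mcherry_values,
                                 condition = c("rich", "deprived", "chx"),
                                 sample_id = NA_character_) {
  condition <- match.arg(condition)
  if (length(gfp_values) == 0L || length(mcherry_values) == 0L) {
    stop("fluorescence value lists must be non-empty", call. = FALSE)
  }
  if (any(gfp_values <= 0) || any(mcherry_values <= 0)) {
    stop("fluorescence values must be positive (filter zero/negative events upstream)",
         call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, condition = condition,
         gfp_values = as.numeric(gfp_values),
         mcherry_values = as.numeric(mcherry_values)),
    class = "reporter_measurement"
  )
}

normalized_reporter_value <- function(m) {
  stopifnot(inherits(m, "reporter_measurement"))
  geometric_mean(m$gfp_values) / geometric_mean(m$mcherry_values)
}

#' Background-corrected -SG/+SG reporter ratio
#'
#' For each condition the reporter value is the geometric-mean GFPd2
#' normalized to geometric-mean mCherry; the cycloheximide (CHX) value, in
#' which no translation occurs, is then subtracted as background, and the
#' ratio contrasts deprivation against the rich condition:
#' `(v_deprived - v_chx) / (v_rich - v_chx)`.
#'
#' Negative corrected values are reported as-is with `flag =
#' "negative_corrected_value"` rather than clipped; when the rich signal
#' does not exceed background the ratio is `NA` with
#' `flag = "background_exceeds_signal"`.
#'
#' @param rich,deprived,chx [reporter_measurement()]s for the three
#'   conditions.
#' @return List with `ratio`, per-condition values `v_rich`, `v_deprived`,
#'   `v_chx`, and `flag` (`NA` when clean).
#' @export
corrected_ratio <- function(rich, deprived, chx) {
  v_rich <- normalized_reporter_value(rich)
  v_dep <- normalized_reporter_value(deprived)
  v_chx <- normalized_reporter_value(chx)
  flag <- NA_character_
  if (v_rich <= v_chx) {
    return(list(ratio = NA_real_, v_rich = v_rich, v_deprived = v_dep,
                v_chx = v_chx, flag = "background_exceeds_signal"))
  }
  ratio <- (v_dep - v_chx) / (v_rich - v_chx)
  if (ratio < 0) flag <- "negative_corrected_value"
  list(ratio = ratio, v_rich = v_rich, v_deprived = v_dep, v_chx = v_chx,
       flag = flag)
}

#' Beta-score differencing and ranking between two screens
#'
#' Contrasts gene-level CRISPR screen effect sizes (beta scores, computed
#' externally, e.g. by MAGeCK MLE) between two screens:
#' `beta_diff = beta_A - beta_B`, ranked descending, with genes selected by
#' a strict `beta_diff > threshold`. Genes absent from either screen are
#' dropped and their count recorded.
#'
#' @param beta_a,beta_b Named numeric vectors, gene -> beta score.
#' @param threshold Selection threshold on the difference (default 0.25).
#' @return `data.frame` with `gene_id`, `beta_a`, `beta_b`, `beta_diff`,
#'   `rank`, `selected`, sorted by descending `beta_diff` (alphabetical tie
#'   break); attribute `n_dropped` counts non-overlapping genes.
#' @export
beta_diff_rank <- function(beta_a, beta_b, threshold = 0.25) {
  if (is.null(names(beta_a)) || is.null(names(beta_b))) {
    stop("beta vectors must be named by gene", call. = FALSE)
  }
  shared <- intersect(names(beta_a), names(beta_b))
  if (length(shared) == 0L) {
    stop("no genes shared between the two screens", call. = FALSE)
  }
  n_dropped <- (length(beta_a) - length(shared)) + (length(beta_b) - length(shared))
  diff <- beta_a[shared] - beta_b[shared]
  out <- data.frame(
    gene_id = shared,
    beta_a = as.numeric(beta_a[shared]),
    beta_b = as.numeric(beta_b[shared]),
    beta_diff = as.numeric(diff),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$beta_diff, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$beta_diff > threshold
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
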